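#' Dominance model over S-alleles
#'
#' Sporophytic SI expresses specificities subject to dominance interactions
#' among the two S-alleles of the diploid parent. The model is a partial
#' order: pairs listed in `pairs` are ordered (dominant masks recessive), the
#' allele named in `recessive_to_all` is recessive to every other allele
#' (S1's documented behaviour), and all remaining pairs are codominant.
#'
#' @param pairs optional data frame with columns `dominant` and `recessive`
#'   giving explicitly ordered allele pairs.
#' @param recessive_to_all label of an allele recessive to all others, or
#'   `NULL`. Default `"S1"`.
#' @return object of class `dominance_model`.
#' @export
dominance_model <- function(pairs = NULL, recessive_to_all = "S1") {
  if (is.null(pairs)) {
    pairs <- data.frame(dominant = character(0), recessive = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("dominant", "recessive") %in% names(pairs)))
  if (any(pairs$dominant == pairs$recessive))
    stop("dominance relation must be irreflexive")
  assert_acyclic(pairs)
  structure(list(pairs = pairs, recessive_to_all = recessive_to_all),
            class = "dominance_model")
}

## cycle check over the explicit pairs by iterative source removal
assert_acyclic <- function(pairs) {
  edges <- unique(pairs[c("dominant", "recessive")])
  while (nrow(edges) > 0L) {
    sources <- setdiff(edges$dominant, edges$recessive)
    if (length(sources) == 0L) stop("dominance relation contains a cycle")
    edges <- edges[!(edges$dominant %in% sources), , drop = FALSE]
  }
  invisible(TRUE)
}

## is allele a dominant over allele b?
dominant_over <- function(a, b, dominance) {
  if (a == b) return(FALSE)
  if (any(dominance$pairs$dominant == a & dominance$pairs$recessive == b))
    return(TRUE)
  rec <- dominance$recessive_to_all
  !is.null(rec) && b == rec && a != rec
}

#' Plant genotype at the S-locus and the unlinked modifier locus
#'
#' @param s character vector of 2 S-allele labels (unordered).
#' @param modifier character vector of 2 modifier alleles over `c("M", "m")`;
#'   `m` is the recessive self-compatibility allele.
#' @param viability_weight optional positive survival weight.
#' @return object of class `plant_genotype`.
#' @export
plant_genotype <- function(s, modifier = c("M", "M"), viability_weight = 1) {
  stopifnot(length(s) == 2L, length(modifier) == 2L,
            all(modifier %in% c("M", "m")), viability_weight > 0)
  structure(list(s = s, modifier = modifier,
                 viability_weight = viability_weight),
            class = "plant_genotype")
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat(sprintf("%s/%s ; %s\n", x$s[1], x$s[2],
              paste(sort(x$modifier, decreasing = TRUE), collapse = "/")))
  invisible(x)
}

as_s_pair <- function(genotype) {
  if (inherits(genotype, "plant_genotype")) genotype$s else genotype
}

#' Specificities expressed by a genotype
#'
#' Under sporophytic SI, both pistil and pollen expression are determined by
#' the diploid genotype of the parent plant: an ordered pair expresses only
#' the dominant allele, an unordered (codominant) pair expresses both, and a
#' homozygote expresses its single allele. The same rule applies to both
#' sides; `side` is kept so side-specific dominance could be layered on.
#'
#' @param genotype a [plant_genotype()] or a character pair of S-alleles.
#' @param dominance a [dominance_model()].
#' @param side `"pistil"` or `"pollen"`.
#' @return character vector of expressed specificity labels.
#' @export
expressed_specificities <- function(genotype, dominance = dominance_model(),
                                    side = c("pistil", "pollen")) {
  side <- match.arg(side)
  s <- as_s_pair(genotype)
  stopifnot(length(s) == 2L)
  if (s[1] == s[2]) return(s[1])
  if (dominant_over(s[1], s[2], dominance)) return(s[1])
  if (dominant_over(s[2], s[1], dominance)) return(s[2])
  sort(s)
}

## SI functionality under the recessive-modifier model (scenario A): SI is
## lost only in S1 homozygotes that are also homozygous for the recessive
## modifier allele m.
si_functional <- function(genotype, model = "scenarioA",
                          recessive_allele = "S1") {
  stopifnot(inherits(genotype, "plant_genotype"))
  if (!identical(model, "scenarioA")) stop("unknown model: ", model)
  !(all(genotype$s == recessive_allele) && all(genotype$modifier == "m"))
}

#' Cross compatibility under sporophytic SI
#'
#' A pollination is incompatible when any specificity expressed by the pollen
#' donor (sporophytically, by the father plant) matches a specificity
#' expressed by the mother's pistil. A mother without functional SI (an SC
#' plant under the modifier model) accepts all pollen.
#'
#' @param mother,father [plant_genotype()] objects (a bare character pair is
#'   accepted and treated as having functional SI).
#' @param dominance a [dominance_model()].
#' @return logical.
#' @export
is_compatible <- function(mother, father, dominance = dominance_model()) {
  if (inherits(mother, "plant_genotype") && !si_functional(mother))
    return(TRUE)
  pistil <- expressed_specificities(mother, dominance, "pistil")
  pollen <- expressed_specificities(father, dominance, "pollen")
  length(intersect(pistil, pollen)) == 0L
}

#' Simulate offspring of a cross at the S-locus and modifier locus
#'
#' Each offspring draws one allele per parent per locus uniformly and
#' independently; the modifier locus is unlinked to the S-locus (free
#' recombination). Optional viability distortion against carriers of a named
#' S-allele is applied either to gametes (transmission bias) or to zygotes
#' (survival bias) via rejection sampling; the observed
#' deficit of recessive-allele carriers is agnostic between the two, so both
#' are exposed and neither is the default.
#'
#' @param mother,father [plant_genotype()] objects.
#' @param n_offspring number of offspring to draw.
#' @param seed integer seed; all randomness in the call flows from it.
#' @param dominance a [dominance_model()] used for the compatibility check.
#' @param override set `TRUE` to force an SI-incompatible cross.
#' @param viability optional list `list(allele =, s =, mode =)` with selection
#'   coefficient `s` in \[0, 1) against carriers of `allele`, `mode` one of
#'   `"zygote"` (survival weight `(1-s)^copies`) or `"gamete"` (each gamete
#'   carrying the allele accepted with probability `1-s`).
#' @return data frame of class `plant_cohort` with columns `s1`, `s2`
#'   (maternal / paternal S-allele) and `mod1`, `mod2`.
#' @export
simulate_cross <- function(mother, father, n_offspring, seed,
                           dominance = dominance_model(), override = FALSE,
                           viability = NULL) {
  stopifnot(inherits(mother, "plant_genotype"),
            inherits(father, "plant_genotype"), n_offspring >= 1)
  if (!override && !is_compatible(mother, father, dominance))
    stop("cross rejected by SI")
  set.seed(as.integer(seed))
  draw_gamete <- function(parent, n) {
    cbind(s = parent$s[sample.int(2L, n, replace = TRUE)],
          m = parent$modifier[sample.int(2L, n, replace = TRUE)])
  }
  keep_gamete <- function(g) {
    if (is.null(viability) || viability$mode != "gamete") return(g)
    carrier <- g[, "s"] == viability$allele
    ok <- !carrier | stats::runif(nrow(g)) >= viability$s
    g[ok, , drop = FALSE]
  }
  out <- NULL
  for (iter in 1:1000) {
    need <- n_offspring - NROW(out)
    if (need <= 0L) break
    n_draw <- max(need, 16L)
    gm <- keep_gamete(draw_gamete(mother, n_draw))
    gf <- keep_gamete(draw_gamete(father, n_draw))
    k <- min(nrow(gm), nrow(gf))
    if (k == 0L) next
    zyg <- data.frame(s1 = gm[seq_len(k), "s"], s2 = gf[seq_len(k), "s"],
                      mod1 = gm[seq_len(k), "m"], mod2 = gf[seq_len(k), "m"],
                      stringsAsFactors = FALSE)
    if (!is.null(viability) && viability$mode == "zygote") {
      copies <- (zyg$s1 == viability$allele) + (zyg$s2 == viability$allele)
      zyg <- zyg[stats::runif(k) < (1 - viability$s)^copies, , drop = FALSE]
    }
    out <- rbind(out, zyg)
  }
  if (NROW(out) < n_offspring)
    stop("viability rejection failed to produce requested offspring")
  out <- out[seq_len(n_offspring), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("plant_cohort", "data.frame")
  out
}

#' Unordered S-genotype labels for a cohort
#'
#' @param cohort a `plant_cohort` data frame (or any frame with `s1`, `s2`).
#' @return character vector like `"S1/S23"` with alleles sorted within pair.
#' @export
s_genotype_label <- function(cohort) {
  paste(pmin(cohort$s1, cohort$s2), pmax(cohort$s1, cohort$s2), sep = "/")
}

modifier_label <- function(cohort) {
  paste(pmax(cohort$mod1, cohort$mod2), pmin(cohort$mod1, cohort$mod2), sep = "/")
}

#' Selfing phenotype from genotype under the recessive-modifier model
#'
#' Scenario A: self-compatibility requires homozygosity for the recessive
#' S-allele (S1) at the S-locus *and* homozygosity for the recessive allele
#' `m` at the unlinked modifier locus; every other genotype is SI. Male
#' sterility, which masks the selfing phenotype, is overlaid as an
#' independent per-plant probability (no genetic model for it is asserted).
#'
#' @param cohort `plant_cohort` data frame, or a single [plant_genotype()].
#' @param model currently only `"scenarioA"`.
#' @param male_sterility_rate per-plant masking probability (default 0).
#' @param seed integer seed used when `male_sterility_rate > 0`.
#' @param recessive_allele label of the S-allele whose homozygotes can be SC.
#' @return character vector over `c("SC", "SI", "male_sterile")`.
#' @export
phenotype_from_genotype <- function(cohort, model = "scenarioA",
                                    male_sterility_rate = 0, seed = NULL,
                                    recessive_allele = "S1") {
  if (!identical(model, "scenarioA")) stop("unknown model: ", model)
  if (inherits(cohort, "plant_genotype"))
    cohort <- data.frame(s1 = cohort$s[1], s2 = cohort$s[2],
                         mod1 = cohort$modifier[1], mod2 = cohort$modifier[2])
  sc <- cohort$s1 == recessive_allele & cohort$s2 == recessive_allele &
    cohort$mod1 == "m" & cohort$mod2 == "m"
  phen <- ifelse(sc, "SC", "SI")
  if (male_sterility_rate > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    phen[stats::runif(length(phen)) < male_sterility_rate] <- "male_sterile"
  }
  phen
}

#' Classify the selfing phenotype from silique counts
#'
#' Self-pollinations are scored as full, partially developed or empty
#' siliques. With at least six pollinations per plant: SC when at least 5/6
#' of the pollinations set full siliques, SI when at least 5/6 are empty,
#' leaky SI when two or more siliques show partial development and neither
#' prior rule fires; anything else (including a conflicting full+partial
#' pattern) is ambiguous. The 5-of-6 rule generalises proportionally
#' (`ceiling(5/6 * total)`) for more than six pollinations.
#'
#' @param full,partial,empty integer vectors of per-plant counts.
#' @return character vector over `c("SC", "SI", "leaky", "ambiguous")`.
#' @export
classify_selfing_phenotype <- function(full, partial, empty) {
  stopifnot(length(full) == length(partial), length(full) == length(empty))
  if (any(full < 0 | partial < 0 | empty < 0)) stop("negative silique count")
  total <- full + partial + empty
  if (any(total < 6)) stop("insufficient pollinations: at least 6 required")
  need <- ceiling(5 / 6 * total)
  sc <- full >= need
  si <- empty >= need
  out <- rep("ambiguous", length(total))
  out[sc & !si] <- "SC"
  out[si & !sc] <- "SI"
  out[!sc & !si & partial >= 2] <- "leaky"
  out
}

#' Exact F2 segregation distribution for a cross
#'
#' Exhaustively enumerates the 4 x 4 gamete combinations at each of the two
#' unlinked loci (16 equiprobable zygotes over S-locus x modifier) for a
#' compatible parent pair, assigns phenotypes under the recessive-modifier
#' model, and aggregates to a distribution over
#' (S-genotype, modifier genotype, phenotype).
#'
#' @inheritParams simulate_cross
#' @param model passed to [phenotype_from_genotype()].
#' @return data frame with columns `s_genotype`, `modifier_genotype`,
#'   `phenotype`, `prob`; probabilities sum to 1.
#' @export
expected_f2_segregation <- function(mother, father,
                                    dominance = dominance_model(),
                                    model = "scenarioA") {
  stopifnot(inherits(mother, "plant_genotype"),
            inherits(father, "plant_genotype"))
  if (!is_compatible(mother, father, dominance))
    stop("cross rejected by SI")
  grid <- expand.grid(ms = 1:2, mm = 1:2, fs = 1:2, fm = 1:2)
  zyg <- data.frame(
    s1 = mother$s[grid$ms], s2 = father$s[grid$fs],
    mod1 = mother$modifier[grid$mm], mod2 = father$modifier[grid$fm],
    stringsAsFactors = FALSE
  )
  zyg$s_genotype <- s_genotype_label(zyg)
  zyg$modifier_genotype <- modifier_label(zyg)
  zyg$phenotype <- phenotype_from_genotype(zyg, model = model)
  agg <- stats::aggregate(
    list(prob = rep(1 / nrow(zyg), nrow(zyg))),
    by = zyg[c("s_genotype", "modifier_genotype", "phenotype")], FUN = sum)
  agg <- agg[order(agg$s_genotype, agg$modifier_genotype), ]
  rownames(agg) <- NULL
  stopifnot(abs(sum(agg$prob) - 1) < 1e-9)
  agg
}

#' Pearson chi-square test of Mendelian segregation
#'
#' Goodness-of-fit of observed class counts against expected Mendelian
#' proportions, with `df = classes - 1` and an upper-tail p-value from the
#' chi-square distribution.
#'
#' @param observed named integer vector of class counts.
#' @param expected_proportions named numeric vector of expected proportions
#'   over the same classes (must sum to 1).
#' @return object of class `segregation_result`: list with `observed`,
#'   `expected_proportions`, `expected_counts`, `chi_square`, `df`, `p_value`.
#' @examples
#' segregation_chi_square(c(A = 30, B = 10), c(A = 0.5, B = 0.5))
#' @export
segregation_chi_square <- function(observed, expected_proportions) {
  cls <- names(observed)
  if (is.null(cls) || is.null(names(expected_proportions)) ||
      !setequal(cls, names(expected_proportions)))
    stop("observed and expected classes must match")
  p <- expected_proportions[cls]
  if (abs(sum(p) - 1) > 1e-9) stop("expected proportions must sum to 1")
  if (any(observed < 0)) stop("negative observed count")
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  if (any(p == 0 & observed > 0))
    stop("expected proportion 0 with nonzero observed count")
  keep <- p > 0
  e <- n * p[keep]
  chi2 <- sum((observed[keep] - e)^2 / e)
  df <- length(cls) - 1L
  structure(list(
    observed = observed, expected_proportions = p, expected_counts = n * p,
    chi_square = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE)
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation chi-square = %.4g, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
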