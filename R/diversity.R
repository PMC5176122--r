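#' Round half away from zero
#'
#' Nearest-integer rounding with ties going up, the convention used for the
#' reported allele-number estimates (8.4 -> 8, 6.5 -> 7). Base R `round()`
#' rounds half to even, which would disagree on exact .5 ties.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

unknown_marker <- "?"

## split a comma-joined allele field into its tokens; NA / "" -> character(0)
split_alleles <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

join_alleles <- function(x) paste(x, collapse = ",")

#' Tally S-allele observations for one population
#'
#' Counts identified SRK allele copies, unknown (unidentified) copies, the
#' fraction of predicted heterozygotes and the alleles observed homozygous in
#' a sample of diploid individuals from a single population. A homozygote
#' contributes two copies of its allele; each unknown marker `?` contributes
#' one unidentified copy. An individual counts as heterozygous when its two
#' gene copies are not the same identified allele, i.e. either two distinct
#' identified alleles or one identified allele plus a predicted (unknown)
#' second allele inferred from marker heterozygosity.
#'
#' @param genotypes data frame with columns `individual`, `population`,
#'   `srk_alleles` (comma-joined, `?` marks an unidentified copy),
#'   `b80_alleles`, `phenotype`, as returned by [read_genotype_table()].
#'   Genotypes are expected to have been through [infer_missing_alleles()]
#'   already so that single-amplified homozygotes are resolved.
#' @param exclude character vector of allele labels excluded from the tally
#'   (alleles known to be unlinked to the SI phenotype, e.g. `"S45"`). An
#'   excluded token is dropped and, when fewer than two copies remain, the
#'   genotype is re-padded with an unknown marker.
#' @return object of class `allele_tally`: a list with `population`,
#'   `n_individuals`, `n_identified`, `m` (gene copies = 2 x individuals),
#'   `copies_per_allele` (named integer), `missing_copies`, `het_fraction`
#'   and `homozygous_alleles`.
#' @seealso [bound_allele_number()], [repeatability_estimate()]
#' @export
tally_population <- function(genotypes, exclude = character()) {
  if (is.null(genotypes) || nrow(genotypes) == 0L) stop("no individuals")
  pop <- unique(genotypes$population)
  if (length(pop) != 1L)
    stop("tally_population() expects a single population, got: ",
         paste(pop, collapse = ", "))
  slots <- lapply(genotypes$srk_alleles, function(x)
    pad_genotype(setdiff_keep(split_alleles(x), exclude)))
  bad <- vapply(slots, length, 1L) > 2L
  if (any(bad))
    stop("ploidy violation: individual ",
         paste(genotypes$individual[bad], collapse = ", "),
         " has more than 2 allele copies")
  n_ind <- length(slots)
  all_tokens <- unlist(slots)
  identified <- all_tokens[all_tokens != unknown_marker]
  copies <- if (length(identified)) {
    tab <- table(identified)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  is_het <- vapply(slots, function(s)
    !(s[1] == s[2] && s[1] != unknown_marker), logical(1))
  homo <- sort(unique(unlist(lapply(slots, function(s)
    if (s[1] == s[2] && s[1] != unknown_marker) s[1] else character(0)))))
  structure(list(
    population = pop,
    n_individuals = n_ind,
    n_identified = length(copies),
    m = 2L * n_ind,
    copies_per_allele = copies,
    missing_copies = sum(all_tokens == unknown_marker),
    het_fraction = mean(is_het),
    homozygous_alleles = homo
  ), class = "allele_tally")
}

## drop excluded tokens, never touching the unknown marker
setdiff_keep <- function(tokens, exclude) {
  tokens[!(tokens %in% setdiff(exclude, unknown_marker))]
}

## pad a genotype to two copies with unknown markers
pad_genotype <- function(tokens) {
  if (length(tokens) >= 2L) return(tokens)
  c(tokens, rep(unknown_marker, 2L - length(tokens)))
}

#' @export
print.allele_tally <- function(x, ...) {
  cat("S-allele tally for population", x$population, "\n")
  cat("  individuals:", x$n_individuals, " gene copies (m):", x$m, "\n")
  cat("  identified alleles (n):", x$n_identified, "\n")
  if (x$n_identified)
    cat("  copies:", paste(names(x$copies_per_allele),
                           x$copies_per_allele, sep = "=", collapse = " "), "\n")
  cat("  unidentified copies:", x$missing_copies, "\n")
  cat(sprintf("  het fraction: %.2f\n", x$het_fraction))
  cat("  homozygous:", if (length(x$homozygous_alleles))
    paste(x$homozygous_alleles, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Infer unidentified S-alleles from the linked B80 marker
#'
#' B80 flanks the S-locus and is in strong linkage disequilibrium with SRK, so
#' heterozygosity at B80 predicts when an SRK allele was missed by
#' allele-specific genotyping. For an individual with exactly one identified
#' SRK allele and one unknown copy:
#'
#' * B80 homozygous -> the individual is resolved as an SRK homozygote;
#' * both B80 haplotypes known to associate only with the identified allele
#'   (same allele, two genetic backgrounds) -> homozygote under the default
#'   mode, unknown copy retained under `same_allele = "two_alleles"`;
#' * otherwise (a B80 haplotype pointing to a different or ambiguous allele)
#'   the unknown copy is retained: an unidentified allele is predicted.
#'
#' Individuals whose B80 haplotype is absent from the link map are carried
#' through unchanged and recorded in the `warnings` attribute.
#'
#' @param genotypes genotype data frame (see [read_genotype_table()]).
#' @param linkmap data frame with columns `b80_hap` and `srk_alleles`
#'   (comma-joined set of SRK alleles the haplotype associates with), as read
#'   by [read_linkmap()].
#' @param same_allele how to treat one identified allele with two different
#'   B80 haplotypes that both associate only with that allele:
#'   `"homozygous"` (default, the study's treatment) or `"two_alleles"`.
#' @return the genotype data frame with resolved `srk_alleles`; attribute
#'   `warnings` holds a character vector describing unmapped B80 haplotypes.
#' @export
infer_missing_alleles <- function(genotypes, linkmap,
                                  same_allele = c("homozygous", "two_alleles")) {
  same_allele <- match.arg(same_allele)
  map <- stats::setNames(lapply(linkmap$srk_alleles, split_alleles),
                         linkmap$b80_hap)
  if (any(vapply(map, length, 1L) == 0L))
    stop("link map entry with empty SRK allele set")
  warnings <- character(0)
  out <- genotypes
  for (i in seq_len(nrow(genotypes))) {
    srk <- pad_genotype(split_alleles(genotypes$srk_alleles[i]))
    ids <- srk[srk != unknown_marker]
    if (length(ids) != 1L || sum(srk == unknown_marker) != 1L) next
    b80 <- split_alleles(genotypes$b80_alleles[i])
    if (length(b80) != 2L) next
    unmapped <- setdiff(b80, names(map))
    if (length(unmapped)) {
      warnings <- c(warnings, sprintf(
        "individual %s: B80 haplotype(s) %s absent from link map; genotype unchanged",
        genotypes$individual[i], paste(unmapped, collapse = ", ")))
      next
    }
    a <- ids
    if (b80[1] == b80[2]) {
      out$srk_alleles[i] <- join_alleles(c(a, a))
    } else {
      sets <- map[b80]
      only_a <- vapply(sets, function(s) identical(s, a), logical(1))
      if (all(only_a) && same_allele == "homozygous") {
        out$srk_alleles[i] <- join_alleles(c(a, a))
      } else {
        out$srk_alleles[i] <- join_alleles(c(a, unknown_marker))
      }
    }
  }
  if (length(warnings)) warning(paste(warnings, collapse = "\n"))
  attr(out, "warnings") <- warnings
  out
}

#' Repeatability-index estimate of the number of S-alleles
#'
#' Estimates the number of S-haplotypes segregating in a population from the
#' pattern of repeated alleles in a finite sample: `n` distinct alleles
#' identified among `m` sampled gene copies give
#' \deqn{\hat N = \frac{n}{1 - (n-2)/(m-2)}.}
#' The fewer the repeats (the closer `n` is to `m`), the larger the estimate;
#' with `n = m` every copy is distinct and the estimate is unbounded
#' (returned as `Inf`, reported downstream as an explicit flag, never as a
#' number). With `n = 2` the estimate is exactly 2 for any `m`.
#'
#' `literal = TRUE` evaluates the algebra `1 - (n-2)/(m-2)` on its own (the
#' denominator above). That form is documented for audit only: it is bounded
#' by ~1 and cannot serve as an allele-number estimate.
#'
#' @param n integer, number of distinct alleles identified in the sample.
#' @param m integer, number of gene copies sampled (2 per diploid individual).
#' @param literal return the bare denominator form instead of the estimator.
#' @return numeric estimate (`Inf` when `n == m`).
#' @examples
#' repeatability_estimate(5, 16)   # 70/11 ~ 6.36
#' repeatability_estimate(1, 16)   # 14/15 ~ 0.93
#' repeatability_estimate(16, 16)  # Inf: no repeats observed
#' @export
repeatability_estimate <- function(n, m, literal = FALSE) {
  stopifnot(length(n) == length(m) || length(n) == 1L || length(m) == 1L)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(m < 4)) stop("m must be >= 4")
  if (any(n > m)) stop("n exceeds m: cannot identify more alleles than copies sampled")
  denom <- 1 - (n - 2) / (m - 2)
  if (literal) return(denom)
  ifelse(n == m, Inf, n / denom)
}

#' Minimum/maximum allele-number bounds for a tally with unidentified copies
#'
#' Unidentified gene copies (predicted from B80 heterozygosity but not typed)
#' leave the true allele count uncertain. The minimum bound assumes all
#' unidentified copies are one shared novel allele (`n_min = n_identified + 1`
#' when any copy is missing); the maximum assumes every unidentified copy is a
#' distinct novel allele (`n_max = n_identified + missing_copies`; in the
#' study each unidentified copy sat in a different individual). Each bound is
#' run through [repeatability_estimate()] and rounded half-up.
#'
#' @param tally an `allele_tally` from [tally_population()].
#' @return object of class `diversity_estimate`: list with `population`,
#'   `n_min`, `n_max`, `raw_min`, `raw_max`, `rounded_min`, `rounded_max`,
#'   and logical flags `min_unbounded` / `max_unbounded` (when a bound hits
#'   `n = m` the estimate has no upper limit; the rounded value is `NA` and
#'   the flag is set rather than reporting infinity as a number).
#' @export
bound_allele_number <- function(tally) {
  stopifnot(inherits(tally, "allele_tally"))
  n_min <- tally$n_identified + as.integer(tally$missing_copies > 0)
  n_max <- tally$n_identified + tally$missing_copies
  raw_min <- repeatability_estimate(n_min, tally$m)
  raw_max <- repeatability_estimate(n_max, tally$m)
  structure(list(
    population = tally$population,
    n_min = n_min, n_max = n_max,
    raw_min = raw_min, raw_max = raw_max,
    min_unbounded = is.infinite(raw_min),
    max_unbounded = is.infinite(raw_max),
    rounded_min = if (is.infinite(raw_min)) NA_real_ else round_half_up(raw_min),
    rounded_max = if (is.infinite(raw_max)) NA_real_ else round_half_up(raw_max)
  ), class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  fmt <- function(r, u) if (u) "unbounded" else format(r)
  cat(sprintf("Population %s: estimated S-alleles min %s, max %s (n_min=%d, n_max=%d)\n",
              x$population, fmt(x$rounded_min, x$min_unbounded),
              fmt(x$rounded_max, x$max_unbounded), x$n_min, x$n_max))
  invisible(x)
}

#' Per-population report with mating-class group means
#'
#' Combines per-population tallies and allele-number estimates with population
#' metadata (outcrossing rate Tm, genetic cluster, mating class) into a
#' report, appending group means for the inbreeding and outcrossing classes:
#' allele-number means are arithmetic means of the rounded per-population
#' values; Tm means exclude populations flagged `tm_excluded` in the metadata
#' (outcrossing-rate estimates deemed unreliable); mixed-mating populations
#' belong to neither group. Group means are rounded to 2 decimals.
#'
#' @param tallies list of `allele_tally` objects, one per population.
#' @param estimates list of `diversity_estimate` objects, parallel to
#'   `tallies` (computed with [bound_allele_number()] when `NULL`).
#' @param meta data frame with columns `population`, `tm`, `cluster`,
#'   `mating_class` (`"inbreeding"`, `"outcrossing"` or `"mixed"`) and
#'   optionally logical `tm_excluded`.
#' @return list with `populations` (one row per population) and `groups`
#'   (one row per mating class present, with `mean_tm`, `mean_het`,
#'   `mean_min_alleles`, `mean_max_alleles`, `n_populations`).
#' @export
summarize_populations <- function(tallies, estimates = NULL, meta) {
  stopifnot(is.list(tallies), length(tallies) > 0L)
  if (is.null(estimates)) estimates <- lapply(tallies, bound_allele_number)
  pops <- vapply(tallies, `[[`, "", "population")
  if (anyDuplicated(pops)) stop("one tally per population required")
  missing_meta <- setdiff(pops, meta$population)
  if (length(missing_meta))
    stop("population(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  if (is.null(meta$tm_excluded)) meta$tm_excluded <- FALSE
  mrow <- meta[match(pops, meta$population), ]
  df <- data.frame(
    population = pops,
    tm = mrow$tm,
    cluster = as.character(mrow$cluster),
    mating_class = as.character(mrow$mating_class),
    tm_excluded = mrow$tm_excluded,
    n_identified = vapply(tallies, `[[`, 1L, "n_identified"),
    missing_copies = vapply(tallies, function(t) as.integer(t$missing_copies), 1L),
    het_fraction = vapply(tallies, `[[`, 1, "het_fraction"),
    min_alleles = vapply(estimates, `[[`, 1, "rounded_min"),
    max_alleles = vapply(estimates, `[[`, 1, "rounded_max"),
    min_unbounded = vapply(estimates, `[[`, TRUE, "min_unbounded"),
    max_unbounded = vapply(estimates, `[[`, TRUE, "max_unbounded"),
    stringsAsFactors = FALSE
  )
  groups <- do.call(rbind, lapply(c("inbreeding", "outcrossing"), function(cls) {
    sub <- df[df$mating_class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(
      mating_class = cls,
      n_populations = nrow(sub),
      mean_tm = round(mean(sub$tm[!sub$tm_excluded]), 2),
      mean_het = round(mean(sub$het_fraction), 2),
      mean_min_alleles = round(mean(sub$min_alleles), 2),
      mean_max_alleles = round(mean(sub$max_alleles), 2),
      stringsAsFactors = FALSE
    )
  }))
  list(populations = df, groups = groups)
}

#' Full S-allele diversity pipeline for a multi-population genotype table
#'
#' Convenience wrapper chaining [infer_missing_alleles()],
#' [tally_population()] (with the allele exclusion list),
#' [bound_allele_number()] and [summarize_populations()].
#'
#' @param genotypes multi-population genotype data frame.
#' @param linkmap B80 link map (see [read_linkmap()]).
#' @param meta population metadata (see [read_population_meta()]).
#' @param exclude alleles excluded from tallies (default `"S45"`).
#' @param same_allele passed to [infer_missing_alleles()].
#' @return list with `tallies`, `estimates`, `populations`, `groups`.
#' @export
diversity_report <- function(genotypes, linkmap, meta,
                             exclude = "S45",
                             same_allele = "homozygous") {
  inferred <- infer_missing_alleles(genotypes, linkmap,
                                    same_allele = same_allele)
  pops <- unique(inferred$population)
  tallies <- lapply(pops, function(p)
    tally_population(inferred[inferred$population == p, , drop = FALSE],
                     exclude = exclude))
  estimates <- lapply(tallies, bound_allele_number)
  summary <- summarize_populations(tallies, estimates, meta)
  list(tallies = stats::setNames(tallies, pops),
       estimates = stats::setNames(estimates, pops),
       populations = summary$populations, groups = summary$groups)
}
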