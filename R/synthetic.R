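#' Specification for simulating an SI population sample
#'
#' Defaults emulate the study's sampling design: 8 individuals per
#' population, one S-allele (S1) recessive to all others, remaining alleles
#' codominant. Default allele frequencies approximate the sporophytic-SI
#' equilibrium shape, where recessive specificities segregate at higher
#' frequency than codominant ones: the recessive allele gets twice the weight
#' of each codominant allele, then frequencies are normalised.
#'
#' @param alleles character vector of at least 3 S-allele labels.
#' @param freqs allele frequencies summing to 1; `NULL` for the default.
#' @param dominance a [dominance_model()].
#' @param n_individuals sample size (default 8).
#' @param selfing_prob probability a sampled individual is produced by
#'   selfing with SI ignored (default 0: strict SI).
#' @param seed integer seed.
#' @return list of class `population_sim_spec`.
#' @export
population_sim_spec <- function(alleles, freqs = NULL,
                                dominance = dominance_model(),
                                n_individuals = 8, selfing_prob = 0,
                                seed = 1) {
  stopifnot(length(alleles) >= 3, n_individuals >= 1,
            selfing_prob >= 0, selfing_prob <= 1)
  if (is.null(freqs)) {
    w <- rep(1, length(alleles))
    if (!is.null(dominance$recessive_to_all))
      w[alleles == dominance$recessive_to_all] <- 2
    freqs <- w / sum(w)
  }
  stopifnot(length(freqs) == length(alleles), abs(sum(freqs) - 1) < 1e-9)
  structure(list(alleles = alleles, freqs = freqs, dominance = dominance,
                 n_individuals = n_individuals, selfing_prob = selfing_prob,
                 seed = as.integer(seed)),
            class = "population_sim_spec")
}

#' Simulate a population sample under compatibility-constrained SI mating
#'
#' Each sampled individual is the offspring of a random mating drawn by
#' rejection: mother and father genotypes are drawn from Hardy-Weinberg
#' proportions at the specified allele frequencies and the pair is accepted
#' only if the pollination is SI-compatible under the dominance model (with
#' probability `selfing_prob` the individual is instead selfed, bypassing
#' SI). One gamete per parent forms the offspring. Under strict SI no
#' offspring can be homozygous for an allele dominant over all others, since
#' both parents would express it and be cross-incompatible.
#'
#' @param spec a [population_sim_spec()].
#' @param population label written into the genotype table.
#' @return list with `genotypes` (data frame in the genotype-table layout,
#'   with both true allele copies identified) and `truth` (list with the true
#'   allele number `K`, `alleles`, `freqs`, and the raw allele pairs).
#' @export
simulate_si_population <- function(spec, population = "SIM") {
  stopifnot(inherits(spec, "population_sim_spec"))
  set.seed(spec$seed)
  draw_parent <- function() sample(spec$alleles, 2, replace = TRUE,
                                   prob = spec$freqs)
  a1 <- character(spec$n_individuals)
  a2 <- character(spec$n_individuals)
  for (i in seq_len(spec$n_individuals)) {
    if (spec$selfing_prob > 0 && stats::runif(1) < spec$selfing_prob) {
      par <- draw_parent()
      a1[i] <- sample(par, 1); a2[i] <- sample(par, 1)
      next
    }
    ok <- FALSE
    for (iter in 1:1000) {
      mother <- draw_parent(); father <- draw_parent()
      if (is_compatible(plant_genotype(mother), plant_genotype(father),
                        spec$dominance)) { ok <- TRUE; break }
    }
    if (!ok) stop("population not viable: rejection sampling cap exceeded")
    a1[i] <- sample(mother, 1); a2[i] <- sample(father, 1)
  }
  genotypes <- data.frame(
    individual = sprintf("%s_%02d", population, seq_len(spec$n_individuals)),
    population = population,
    srk_alleles = paste(a1, a2, sep = ","),
    b80_alleles = NA_character_,
    phenotype = "unknown",
    stringsAsFactors = FALSE
  )
  list(genotypes = genotypes,
       truth = list(K = length(spec$alleles), alleles = spec$alleles,
                    freqs = spec$freqs, a1 = a1, a2 = a2))
}

#' Default one-haplotype-per-allele B80 link map for simulations
#'
#' @param alleles S-allele labels.
#' @return link-map data frame (`b80_hap`, `srk_alleles`).
#' @export
synthetic_linkmap <- function(alleles) {
  data.frame(b80_hap = paste0("hap_", alleles), srk_alleles = alleles,
             stringsAsFactors = FALSE)
}

#' Degrade a true genotype table to panel-limited observations
#'
#' Emulates allele-specific PCR genotyping: only alleles in the detection
#' panel are observable. A homozygote for a panel allele amplifies a single
#' allele; copies outside the panel become unknown markers. B80 genotypes are
#' emitted for every true copy via the allele-to-haplotype link map, so that
#' [infer_missing_alleles()] can subsequently resolve homozygotes (B80
#' homozygous) and predict missed alleles (B80 heterozygous).
#'
#' @param truth the `truth` element of [simulate_si_population()] output (or
#'   any list with `a1`, `a2` allele vectors).
#' @param genotypes the matching genotype table (identities and population).
#' @param panel character vector of detectable alleles.
#' @param linkmap link map; default one haplotype per true allele.
#' @return genotype data frame with observed `srk_alleles` (detected alleles,
#'   `?` for each undetected copy; a panel homozygote is reported as the
#'   single amplified allele plus `?`) and full `b80_alleles`.
#' @export
simulate_partial_genotyping <- function(truth, genotypes, panel,
                                        linkmap = NULL) {
  stopifnot(length(panel) >= 1)
  if (is.null(linkmap)) linkmap <- synthetic_linkmap(truth$alleles)
  hap_of <- stats::setNames(linkmap$b80_hap,
                            vapply(linkmap$srk_alleles, function(s)
                              split_alleles(s)[1], ""))
  obs <- genotypes
  for (i in seq_along(truth$a1)) {
    pair <- c(truth$a1[i], truth$a2[i])
    detected <- unique(pair[pair %in% panel])
    if (length(detected) == 2L) {
      obs$srk_alleles[i] <- join_alleles(detected)
    } else if (length(detected) == 1L) {
      obs$srk_alleles[i] <- join_alleles(c(detected, unknown_marker))
    } else {
      obs$srk_alleles[i] <- join_alleles(c(unknown_marker, unknown_marker))
    }
    obs$b80_alleles[i] <- join_alleles(unname(hap_of[pair]))
  }
  obs
}

#' Specification for simulating an F2 bulked-segregant experiment
#'
#' Defaults reproduce the study design: F2 progeny of an F1 sib cross
#' whose grandparents are an AL4-like self-compatible background (S1/S1,
#' modifier m/m) and an MN47-like self-incompatible background (S23/Sx,
#' M/M); pools of 10 SC and 10 SI plants; the causal S-locus at 9.5 Mb on a
#' 20 Mb "chromosome 7"; the unlinked modifier on "chromosome 5"; ~50
#' SNPs/Mb of fixed background divergence; mean read depth 50x. With both F1
#' parents heterozygous at the modifier the SC class is 1/16 of the F2, so
#' the default family size is 500 plants, which keeps the 10-plant SC pool
#' available in essentially every simulated family; the real 97-plant family
#' can be requested explicitly (and errors when it yields fewer than 10 SC
#' plants, mirroring the study's design constraint).
#'
#' Grandparental backgrounds are modelled as fully homozygous and divergent
#' at every marker site (a deliberate simplification of the real outbred
#' parents). Meiosis places a Poisson(`xo_mean`) number of uniform crossovers
#' per chromosome.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param snp_per_bp marker density (default 5e-5 = 50 SNPs/Mb).
#' @param s_locus_chrom,s_locus_pos location of the S-locus.
#' @param modifier_chrom,modifier_pos location of the unlinked modifier.
#' @param n_f2 F2 family size (default 500).
#' @param pool_size plants per phenotype pool (default 10).
#' @param depth mean per-site read depth per pool (Poisson; default 50).
#' @param error_rate per-read probability of reporting the other allele
#'   (default 0.001, post-filter short-read quality).
#' @param indel_rate fraction of sites flagged as indels (default 0.02).
#' @param xo_mean expected crossovers per chromosome per meiosis (default 1).
#' @param seed integer seed.
#' @return list of class `bsa_sim_spec`.
#' @export
bsa_sim_spec <- function(chrom_lengths = c("5" = 20e6, "7" = 20e6),
                         snp_per_bp = 5e-5,
                         s_locus_chrom = "7", s_locus_pos = 9.5e6,
                         modifier_chrom = "5", modifier_pos = 10e6,
                         n_f2 = 500, pool_size = 10, depth = 50,
                         error_rate = 0.001, indel_rate = 0.02,
                         xo_mean = 1, seed = 1) {
  stopifnot(s_locus_chrom %in% names(chrom_lengths),
            modifier_chrom %in% names(chrom_lengths),
            s_locus_pos >= 1, s_locus_pos <= chrom_lengths[[s_locus_chrom]],
            modifier_pos >= 1,
            modifier_pos <= chrom_lengths[[modifier_chrom]],
            pool_size <= n_f2, depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(chrom_lengths = chrom_lengths, snp_per_bp = snp_per_bp,
                 s_locus_chrom = s_locus_chrom, s_locus_pos = s_locus_pos,
                 modifier_chrom = modifier_chrom, modifier_pos = modifier_pos,
                 n_f2 = n_f2, pool_size = pool_size, depth = depth,
                 error_rate = error_rate, indel_rate = indel_rate,
                 xo_mean = xo_mean, seed = as.integer(seed)),
            class = "bsa_sim_spec")
}

## one meiotic gamete of an everywhere-heterozygous F1: phase at position 1
## plus sorted crossover breakpoints; background at pos is
## (phase + #breaks below pos) mod 2, 0 = AL4-like (A), 1 = MN47-like (B)
draw_gamete_mosaic <- function(len, xo_mean) {
  list(phase = sample(0:1, 1),
       breaks = sort(stats::runif(stats::rpois(1, xo_mean), 0, len)))
}

gamete_background <- function(gamete, pos) {
  (gamete$phase + findInterval(pos, gamete$breaks)) %% 2
}

#' Simulate pooled SNP calls for an F2 bulked-segregant experiment
#'
#' Simulates the study cross end to end: F1 sib pair S1/Sx;M/m x S1/S23;M/m
#' (grandparental backgrounds fully divergent, AL4-like carrying S1 and the
#' recessive modifier allele m), F2 meioses with Poisson crossovers,
#' phenotype assignment under the recessive-modifier model, selection of SC
#' and SI pools, and per-site pooled read counts drawn binomially from the
#' pool allele fractions with symmetric sequencing error. Reads are oriented
#' to the MN47-like background (the mapping reference), so each site's `ref`
#' base is the MN47 allele and `al4` the AL4 allele.
#'
#' @param spec a [bsa_sim_spec()].
#' @return list with `calls` (SNP-call data frame across all chromosomes),
#'   and `truth`: causal positions, per-F2 S-locus/modifier genotypes and
#'   phenotypes, pool membership, and per-site true pool allele fractions
#'   (`p_sc`, `p_si`, fractions of the MN47-like allele).
#' @export
simulate_f2_bsa <- function(spec) {
  stopifnot(inherits(spec, "bsa_sim_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$chrom_lengths)
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    len <- spec$chrom_lengths[[ch]]
    n <- max(1L, round(len * spec$snp_per_bp))
    data.frame(chrom = ch, pos = sort(sample.int(len, n)),
               stringsAsFactors = FALSE)
  }))
  n_sites <- nrow(sites)
  ref <- sample(BASES, n_sites, replace = TRUE)                # MN47 allele
  al4 <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
  is_indel <- stats::runif(n_sites) < spec$indel_rate

  # F2 gametes: one maternal + one paternal mosaic per chromosome per plant
  gametes <- lapply(seq_len(spec$n_f2), function(k)
    lapply(stats::setNames(chroms, chroms), function(ch)
      list(mat = draw_gamete_mosaic(spec$chrom_lengths[[ch]], spec$xo_mean),
           pat = draw_gamete_mosaic(spec$chrom_lengths[[ch]], spec$xo_mean))))

  # S-locus and modifier genotypes from the causal-position backgrounds;
  # mother F1 is S1/Sx, father F1 is S1/S23, both M/m with m on background A
  s_bg <- t(vapply(gametes, function(g) c(
    mat = gamete_background(g[[spec$s_locus_chrom]]$mat, spec$s_locus_pos),
    pat = gamete_background(g[[spec$s_locus_chrom]]$pat, spec$s_locus_pos)),
    c(mat = 0, pat = 0)))
  m_bg <- t(vapply(gametes, function(g) c(
    mat = gamete_background(g[[spec$modifier_chrom]]$mat, spec$modifier_pos),
    pat = gamete_background(g[[spec$modifier_chrom]]$pat, spec$modifier_pos)),
    c(mat = 0, pat = 0)))
  f2 <- data.frame(
    s1 = ifelse(s_bg[, "mat"] == 0, "S1", "Sx"),
    s2 = ifelse(s_bg[, "pat"] == 0, "S1", "S23"),
    mod1 = ifelse(m_bg[, "mat"] == 0, "m", "M"),
    mod2 = ifelse(m_bg[, "pat"] == 0, "m", "M"),
    stringsAsFactors = FALSE
  )
  f2$phenotype <- phenotype_from_genotype(f2)

  sc_idx <- which(f2$phenotype == "SC")
  si_idx <- which(f2$phenotype == "SI")
  if (length(sc_idx) < spec$pool_size)
    stop("insufficient SC plants: ", length(sc_idx), " < pool size ",
         spec$pool_size)
  if (length(si_idx) < spec$pool_size)
    stop("insufficient SI plants: ", length(si_idx), " < pool size ",
         spec$pool_size)
  sc_pool <- sort(sample(sc_idx, spec$pool_size))
  si_pool <- sort(sample(si_idx, spec$pool_size))

  # B-allele (MN47-like) dosage at every site for pooled plants only
  dosage_for <- function(plants) {
    d <- matrix(0L, n_sites, length(plants))
    for (j in seq_along(plants)) {
      g <- gametes[[plants[j]]]
      for (ch in chroms) {
        rows <- sites$chrom == ch
        d[rows, j] <- gamete_background(g[[ch]]$mat, sites$pos[rows]) +
          gamete_background(g[[ch]]$pat, sites$pos[rows])
      }
    }
    d
  }
  p_sc <- rowSums(dosage_for(sc_pool)) / (2 * spec$pool_size)
  p_si <- rowSums(dosage_for(si_pool)) / (2 * spec$pool_size)

  sample_pool_reads <- function(p) {
    depth <- stats::rpois(n_sites, spec$depth)
    p_obs <- p * (1 - spec$error_rate) + (1 - p) * spec$error_rate
    b <- stats::rbinom(n_sites, depth, p_obs)
    list(depth = depth, b = b, a = depth - b)
  }
  sc <- sample_pool_reads(p_sc)
  si <- sample_pool_reads(p_si)

  counts <- function(reads) {
    m <- matrix(0L, n_sites, 4, dimnames = list(NULL, BASES))
    m[cbind(seq_len(n_sites), match(ref, BASES))] <- reads$b
    m[cbind(seq_len(n_sites), match(al4, BASES))] <-
      m[cbind(seq_len(n_sites), match(al4, BASES))] + reads$a
    m
  }
  sc_m <- counts(sc); si_m <- counts(si)
  score <- function() pmax(30, round(stats::rnorm(n_sites, 40, 3), 1))
  calls <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = ref, al4 = al4,
    sc_A = sc_m[, "A"], sc_C = sc_m[, "C"], sc_G = sc_m[, "G"],
    sc_T = sc_m[, "T"], sc_depth = sc$depth, sc_score = score(),
    si_A = si_m[, "A"], si_C = si_m[, "C"], si_G = si_m[, "G"],
    si_T = si_m[, "T"], si_depth = si$depth, si_score = score(),
    is_indel = is_indel,
    stringsAsFactors = FALSE
  )
  list(calls = calls,
       truth = list(s_locus = list(chrom = spec$s_locus_chrom,
                                   pos = spec$s_locus_pos),
                    modifier = list(chrom = spec$modifier_chrom,
                                    pos = spec$modifier_pos),
                    f2 = f2, sc_pool = sc_pool, si_pool = si_pool,
                    p_sc = p_sc, p_si = p_si,
                    sites = sites))
}
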