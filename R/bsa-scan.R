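BASES <- c("A", "C", "G", "T")

pool_count_matrix <- function(calls, pool) {
  m <- as.matrix(calls[paste0(pool, "_", BASES)])
  colnames(m) <- BASES
  m
}

pool_major_allele <- function(calls, pool) {
  m <- pool_count_matrix(calls, pool)
  out <- BASES[max.col(m, ties.method = "first")]
  out[calls[[paste0(pool, "_depth")]] == 0] <- NA_character_
  out
}

## minor-allele read fraction per site for a pool (NA at zero depth); with
## only the major-vs-rest split this is 1 - max(count)/depth
pool_minor_fraction <- function(calls, pool) {
  m <- pool_count_matrix(calls, pool)
  depth <- calls[[paste0(pool, "_depth")]]
  mf <- 1 - apply(m, 1, max) / depth
  mf[depth == 0] <- NA_real_
  mf
}

## a pool is "fixed"/homozygous when its minor-allele fraction is at or below
## the fixation threshold (defined on read fractions: pools have no diploid
## genotype call)
pool_fixed <- function(calls, pool, fixation_threshold = 0.001) {
  mf <- pool_minor_fraction(calls, pool)
  !is.na(mf) & mf <= fixation_threshold
}

#' Filter pooled SNP calls on allele frequency and score
#'
#' An alternative allele (any base differing from the MN47 reference base) is
#' reported for a pool when its read fraction in that pool is at least
#' `min_freq` and the pool's site score is at least `min_score` (both
#' thresholds inclusive). Sites with no qualifying alternative allele in
#' either pool are dropped.
#'
#' @param calls SNP-call data frame (see [read_snp_calls()] for the layout).
#' @param min_freq minimum within-pool alternative-allele read fraction
#'   (default 0.10).
#' @param min_score minimum site score per pool (default 25, a phred-like
#'   quality supplied by the caller or the simulator; its internal
#'   computation is not modelled).
#' @return the qualifying subset of `calls`, with added columns `sc_alt` and
#'   `si_alt` (comma-joined qualifying alternative alleles per pool, `""`
#'   when none).
#' @export
call_variants <- function(calls, min_freq = 0.10, min_score = 25) {
  cnt <- as.matrix(calls[c(paste0("sc_", BASES), paste0("si_", BASES))])
  if (any(cnt < 0)) stop("negative read count")
  alt_for_pool <- function(pool) {
    m <- pool_count_matrix(calls, pool)
    depth <- calls[[paste0(pool, "_depth")]]
    score <- calls[[paste0(pool, "_score")]]
    frac <- m / ifelse(depth == 0, NA, depth)
    qual <- !is.na(frac) & frac >= min_freq & score >= min_score &
      outer(calls$ref, BASES, "!=")
    apply(qual, 1, function(row) paste(BASES[row], collapse = ","))
  }
  sc_alt <- alt_for_pool("sc")
  si_alt <- alt_for_pool("si")
  keep <- nzchar(sc_alt) | nzchar(si_alt)
  out <- calls[keep, , drop = FALSE]
  out$sc_alt <- sc_alt[keep]
  out$si_alt <- si_alt[keep]
  rownames(out) <- NULL
  out
}

#' Per-site divergence of a pool from a reference allele
#'
#' Fraction of a pool's reads at each site that differ from the allele of the
#' chosen reference genotype (AL4, the self-compatible reference, or MN47,
#' the assembly reference). 0 means the pool is fixed for the reference
#' allele; 0.5 is the expectation for a fully heterozygous F2 pool. Missing
#' (`NA`) when the pool has no coverage or the reference allele is unknown.
#'
#' @param calls SNP-call data frame.
#' @param pool `"SC"` or `"SI"`.
#' @param reference `"AL4"` (uses the `al4` column) or `"MN47"` (uses `ref`).
#' @return numeric vector in \[0, 1\] with `NA` for missing.
#' @export
divergence_frequency <- function(calls, pool = c("SC", "SI"),
                                 reference = c("AL4", "MN47")) {
  pool <- tolower(match.arg(pool))
  reference <- match.arg(reference)
  ref_allele <- if (reference == "AL4") calls$al4 else calls$ref
  m <- pool_count_matrix(calls, pool)
  depth <- calls[[paste0(pool, "_depth")]]
  idx <- match(ref_allele, BASES)
  ref_count <- m[cbind(seq_len(nrow(m)), ifelse(is.na(idx), 1L, idx))]
  out <- 1 - ref_count / depth
  out[depth == 0 | is.na(idx)] <- NA_real_
  out
}

#' Sliding-window divergence profile
#'
#' Averages per-site pool divergence from a reference in sliding windows
#' along each chromosome: windows are half-open `[start, start + window_size)`
#' anchored at position 1 and advancing by `step_size` while the start does
#' not exceed the last SNP position on the chromosome; partial terminal
#' windows are retained. A window's mean is over the non-missing site
#' divergences it contains; windows holding no SNPs carry missing means.
#'
#' @param calls SNP-call data frame.
#' @param window_size window width in bp (default 200000).
#' @param step_size step between window starts in bp (default 10000).
#' @param reference reference genotype for [divergence_frequency()].
#' @return data frame with `chrom`, `start`, `end` (inclusive), `sc_mean`,
#'   `si_mean`, `n_snps`; attributes `window_size` and `step_size`.
#' @export
sliding_window_profile <- function(calls, window_size = 200000,
                                   step_size = 10000, reference = "AL4") {
  if (window_size <= 0) stop("window_size must be positive")
  if (step_size <= 0) stop("step_size must be positive")
  div_sc <- divergence_frequency(calls, "SC", reference)
  div_si <- divergence_frequency(calls, "SI", reference)
  ord <- order(calls$chrom, calls$pos)
  chrom <- calls$chrom[ord]; pos <- calls$pos[ord]
  div_sc <- div_sc[ord]; div_si <- div_si[ord]
  profiles <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    p <- pos[sel]
    starts <- seq(1, max(p), by = step_size)
    sum_in_windows <- function(values) {
      cs <- c(0, cumsum(values))
      lo <- findInterval(starts - 0.5, p)
      hi <- findInterval(starts + window_size - 0.5, p)
      cs[hi + 1] - cs[lo + 1]
    }
    n_all <- sum_in_windows(rep(1, length(p)))
    mean_of <- function(v) {
      ok <- !is.na(v)
      tot <- sum_in_windows(ifelse(ok, v, 0))
      n_ok <- sum_in_windows(as.numeric(ok))
      ifelse(n_ok > 0, tot / n_ok, NA_real_)
    }
    data.frame(chrom = ch, start = starts,
               end = starts + window_size - 1,
               sc_mean = mean_of(div_sc[sel]),
               si_mean = mean_of(div_si[sel]),
               n_snps = as.integer(n_all),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, profiles)
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  attr(out, "step_size") <- step_size
  out
}

#' Seven-category SNP-sharing classification
#'
#' Classifies each pooled SNP call against the two reference genotypes (AL4,
#' from the self-compatible background, and MN47, the assembly reference)
#' into seven non-exclusive categories:
#'
#' 1. `homo_sc` — the SC pool is homozygous (fixed; minor-allele read
#'    fraction at most `fixation_threshold`);
#' 2. `al4_sc_homo_si_het` — SC pool and AL4 both homozygous while the SI
#'    pool is polymorphic;
#' 3. `sc_ne_si_both_homo` — SC and SI pools fixed for different alleles;
#' 4. `sc_eq_al4_si_het` — as 2, and the SC allele equals the AL4 allele;
#' 5. `sc_eq_mn47_homo` — SC pool fixed for the MN47 reference base;
#' 6. `missing_in_sc` — no read coverage in the SC pool (suppresses 1-5);
#' 7. `indel` — the site is an indel.
#'
#' Category implications 4 => 2 => 1 and 6 => not 1 hold by construction.
#'
#' @param calls SNP-call data frame.
#' @param fixation_threshold maximum minor-allele read fraction for a pool to
#'   count as homozygous/fixed (default 0.001, i.e. 0.1% polymorphism).
#' @return `calls` with seven added logical columns as above, plus helper
#'   columns `sc_major` and `si_major` (pool consensus alleles, `NA` at zero
#'   depth).
#' @export
classify_snp <- function(calls, fixation_threshold = 0.001) {
  sc_major <- pool_major_allele(calls, "sc")
  si_major <- pool_major_allele(calls, "si")
  sc_fixed <- pool_fixed(calls, "sc", fixation_threshold)
  si_fixed <- pool_fixed(calls, "si", fixation_threshold)
  sc_missing <- calls$sc_depth == 0
  si_covered <- calls$si_depth > 0
  al4_known <- !is.na(calls$al4) & calls$al4 %in% BASES
  f1 <- sc_fixed & !sc_missing
  f2 <- f1 & al4_known & si_covered & !si_fixed
  f3 <- f1 & si_fixed & !is.na(si_major) & si_major != sc_major
  f4 <- f2 & sc_major == calls$al4
  f5 <- f1 & sc_major == calls$ref
  calls$homo_sc <- f1
  calls$al4_sc_homo_si_het <- f2
  calls$sc_ne_si_both_homo <- f3
  calls$sc_eq_al4_si_het <- f4
  calls$sc_eq_mn47_homo <- f5
  calls$missing_in_sc <- sc_missing
  calls$indel <- as.logical(calls$is_indel)
  calls$sc_major <- sc_major
  calls$si_major <- si_major
  calls
}

#' Candidate modifier-SNP filter
#'
#' Retains non-indel SNPs where the SC pool is fixed for the AL4 allele, that
#' allele differs from the MN47 reference base, and the SI pool is either
#' polymorphic or fixed for a different allele — the sharing pattern expected
#' of variants linked to the self-compatibility factor. The filter is
#' idempotent and monotone (a subset of the input always maps to a subset of
#' the output).
#'
#' @param calls SNP-call data frame.
#' @param fixation_threshold as in [classify_snp()].
#' @return the qualifying subset of `calls`.
#' @export
candidate_snp_filter <- function(calls, fixation_threshold = 0.001) {
  if (nrow(calls) == 0L) return(calls)
  sc_major <- pool_major_allele(calls, "sc")
  sc_fixed <- pool_fixed(calls, "sc", fixation_threshold)
  si_fixed <- pool_fixed(calls, "si", fixation_threshold)
  si_major <- pool_major_allele(calls, "si")
  si_covered <- calls$si_depth > 0
  keep <- !as.logical(calls$is_indel) &
    sc_fixed & !is.na(calls$al4) &
    !is.na(sc_major) & sc_major == calls$al4 & sc_major != calls$ref &
    si_covered & (!si_fixed | (si_fixed & si_major != sc_major))
  out <- calls[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect candidate regions from a window profile
#'
#' Scans an AL4-referenced window profile for maximal runs of at least
#' `min_windows` consecutive non-empty windows in which the SC pool mean
#' divergence is at most `sc_max` (homozygous for the AL4-like background)
#' while the SI pool mean is at least `si_min` (still segregating). Because
#' windows overlap (the step is smaller than the window), qualifying runs
#' whose window extents overlap are merged into a single region; regions are
#' ranked by the number of qualifying windows they contain, then by
#' ascending SC mean, then by (chrom, start).
#'
#' Default thresholds `sc_max = 0.05`, `si_min = 0.35` encode the qualitative
#' signal of a dip towards fixation in the SC pool against ~50%
#' heterozygosity in the SI pool.
#'
#' @param profile output of [sliding_window_profile()].
#' @param sc_max maximum SC-pool window mean.
#' @param si_min minimum SI-pool window mean.
#' @param min_windows minimum run length in windows (default 10).
#' @param step_size window step; taken from the profile attribute when absent.
#' @return data frame with `chrom`, `start`, `end`, `n_windows`, `sc_mean`,
#'   `si_mean`, `rank` (1 = top candidate), ordered by rank.
#' @export
detect_regions <- function(profile, sc_max = 0.05, si_min = 0.35,
                           min_windows = 10, step_size = NULL) {
  if (is.null(step_size)) step_size <- attr(profile, "step_size")
  if (is.null(step_size)) stop("step_size not given and absent from profile")
  qual <- !is.na(profile$sc_mean) & !is.na(profile$si_mean) &
    profile$sc_mean <= sc_max & profile$si_mean >= si_min
  regions <- NULL
  for (ch in unique(profile$chrom)) {
    sub <- profile[profile$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    q <- qual[profile$chrom == ch][order(profile$start[profile$chrom == ch])]
    if (!any(q)) next
    # runs of consecutive qualifying windows (start gap = one step) ...
    idx <- which(q)
    brk <- c(TRUE, diff(sub$start[idx]) > step_size)
    run_id <- cumsum(brk)
    runs <- do.call(rbind, lapply(unique(run_id), function(r) {
      w <- idx[run_id == r]
      data.frame(start = sub$start[w[1]], end = sub$end[w[length(w)]],
                 n_windows = length(w),
                 sc_sum = sum(sub$sc_mean[w]), si_sum = sum(sub$si_mean[w]))
    }))
    # ... merged wherever their window extents overlap (step < window size)
    runs <- runs[order(runs$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, runs$start[-1] > cummax(runs$end)[-nrow(runs)]))
    for (g in unique(grp)) {
      m <- runs[grp == g, , drop = FALSE]
      nw <- sum(m$n_windows)
      if (nw < min_windows) next
      regions <- rbind(regions, data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        n_windows = nw,
        sc_mean = sum(m$sc_sum) / nw, si_mean = sum(m$si_sum) / nw,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(regions))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      sc_mean = numeric(0), si_mean = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  ord <- order(-regions$n_windows, regions$sc_mean, regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  regions
}

#' Per-gene summary of SNP categories
#'
#' Assigns classified SNPs to gene intervals (a SNP overlapped by several
#' genes goes to the gene with the longest span) and reports, per gene, the
#' number of SNPs, the number falling in coding sub-intervals, and the
#' proportion of assigned SNPs in each of the seven sharing categories.
#' Genes with no assigned SNPs get count 0 and `NA` proportions.
#'
#' @param calls output of [classify_snp()].
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive); see [read_gene_annotations()].
#' @param cds optional data frame of coding sub-intervals with the same
#'   columns; when `NULL` the coding count is `NA`.
#' @return data frame, one row per gene in input order, with `n_snps`,
#'   `n_coding` and columns `p_homo_sc` ... `p_indel`.
#' @export
gene_summary <- function(calls, genes, cds = NULL) {
  flag_cols <- c("homo_sc", "al4_sc_homo_si_het", "sc_ne_si_both_homo",
                 "sc_eq_al4_si_het", "sc_eq_mn47_homo", "missing_in_sc",
                 "indel")
  stopifnot(all(flag_cols %in% names(calls)))
  if (nrow(genes) == 0L)
    return(data.frame(gene = character(0), n_snps = integer(0),
                      n_coding = integer(0), stringsAsFactors = FALSE))
  assign_gene <- rep(NA_integer_, nrow(calls))
  span <- genes$end - genes$start
  for (j in order(span)) {  # longer genes assigned later win
    hit <- calls$chrom == genes$chrom[j] &
      calls$pos >= genes$start[j] & calls$pos <= genes$end[j]
    assign_gene[hit] <- j
  }
  rows <- lapply(seq_len(nrow(genes)), function(j) {
    sub <- calls[!is.na(assign_gene) & assign_gene == j, , drop = FALSE]
    n <- nrow(sub)
    n_coding <- if (is.null(cds)) NA_integer_ else {
      cs <- cds[cds$gene == genes$gene[j], , drop = FALSE]
      if (nrow(cs) == 0L) 0L else sum(vapply(seq_len(n), function(i)
        any(sub$chrom[i] == cs$chrom & sub$pos[i] >= cs$start &
              sub$pos[i] <= cs$end), logical(1)))
    }
    props <- if (n > 0) vapply(flag_cols, function(f) mean(sub[[f]]), 1)
    else stats::setNames(rep(NA_real_, length(flag_cols)), flag_cols)
    cbind(data.frame(gene = genes$gene[j], n_snps = n, n_coding = n_coding,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(props,
                                                paste0("p_", flag_cols)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
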