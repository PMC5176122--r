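# Shared fixture builders and independent oracles.

extdata <- function(name) system.file("extdata", name, package = "silocus")

load_survey_fixtures <- function() {
  list(
    genotypes = read_genotype_table(extdata("population_survey_genotypes.tsv")),
    linkmap = read_linkmap(extdata("b80_linkmap.tsv")),
    meta = read_population_meta(extdata("population_meta.tsv"))
  )
}

# random pooled SNP-call table (single chromosome unless told otherwise)
random_snp_calls <- function(n, chrom = "1", max_pos = 3e5,
                             depth_mean = 60, p_zero_depth = 0.02,
                             p_unknown_al4 = 0.05) {
  pos <- sort(sample.int(max_pos, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  al4 <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  al4[runif(n) < p_unknown_al4] <- NA
  pool_counts <- function() {
    depth <- rpois(n, depth_mean)
    depth[runif(n) < p_zero_depth] <- 0L
    p <- runif(n)
    b <- rbinom(n, depth, p)
    list(depth = depth, b = b, a = depth - b)
  }
  build <- function(cnt) {
    m <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_len(n), match(ref, colnames(m)))] <- cnt$b
    ai <- match(ifelse(is.na(al4), "A", al4), colnames(m))
    m[cbind(seq_len(n), ai)] <- m[cbind(seq_len(n), ai)] + cnt$a
    m
  }
  sc <- pool_counts(); si <- pool_counts()
  sc_m <- build(sc); si_m <- build(si)
  data.frame(chrom = chrom, pos = pos, ref = ref, al4 = al4,
             sc_A = sc_m[, 1], sc_C = sc_m[, 2], sc_G = sc_m[, 3],
             sc_T = sc_m[, 4], sc_depth = sc$depth,
             sc_score = round(runif(n, 26, 45), 1),
             si_A = si_m[, 1], si_C = si_m[, 2], si_G = si_m[, 3],
             si_T = si_m[, 4], si_depth = si$depth,
             si_score = round(runif(n, 26, 45), 1),
             is_indel = runif(n) < 0.05,
             stringsAsFactors = FALSE)
}

# brute-force window oracle: loops over every window and every SNP, no
# cumulative sums, shared with the acceptance suite
brute_force_windows <- function(calls, window_size, step_size,
                                reference = "AL4") {
  div <- list(sc = divergence_frequency(calls, "SC", reference),
              si = divergence_frequency(calls, "SI", reference))
  out <- NULL
  for (ch in unique(calls$chrom)) {
    sel <- which(calls$chrom == ch)
    starts <- seq(1, max(calls$pos[sel]), by = step_size)
    for (s in starts) {
      inw <- sel[calls$pos[sel] >= s & calls$pos[sel] < s + window_size]
      mean_or_na <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE)
        else NA_real_
      out <- rbind(out, data.frame(
        chrom = ch, start = s, end = s + window_size - 1,
        sc_mean = if (length(inw)) mean_or_na(div$sc[inw]) else NA_real_,
        si_mean = if (length(inw)) mean_or_na(div$si[inw]) else NA_real_,
        n_snps = length(inw), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# independent enumeration oracle for a two-locus cross: loops over the 16
# parental gamete combinations explicitly
enumerate_cross <- function(mother, father) {
  rows <- list()
  for (ms in 1:2) for (mm in 1:2) for (fs in 1:2) for (fm in 1:2) {
    s <- sort(c(mother$s[ms], father$s[fs]))
    md <- sort(c(mother$modifier[mm], father$modifier[fm]),
               decreasing = TRUE)
    sc <- all(s == "S1") && all(md == "m")
    key <- paste(paste(s, collapse = "/"), paste(md, collapse = "/"),
                 if (sc) "SC" else "SI", sep = "|")
    rows[[key]] <- (rows[[key]] %||% 0) + 1 / 16
  }
  data.frame(key = names(rows), prob = unlist(rows), row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
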