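make_site <- function(chrom = "1", pos = 100, ref = "A", al4 = "C",
                      sc = c(A = 0, C = 0, G = 0, T = 0), sc_score = 40,
                      si = c(A = 0, C = 0, G = 0, T = 0), si_score = 40,
                      is_indel = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, al4 = al4,
             sc_A = sc[["A"]], sc_C = sc[["C"]], sc_G = sc[["G"]],
             sc_T = sc[["T"]], sc_depth = sum(sc), sc_score = sc_score,
             si_A = si[["A"]], si_C = si[["C"]], si_G = si[["G"]],
             si_T = si[["T"]], si_depth = sum(si), si_score = si_score,
             is_indel = is_indel, stringsAsFactors = FALSE)
}

test_that("variant calling applies inclusive frequency and score thresholds", {
  calls <- rbind(
    make_site(pos = 1, sc = c(A = 92, C = 8, G = 0, T = 0), sc_score = 30),
    make_site(pos = 2, sc = c(A = 90, C = 10, G = 0, T = 0), sc_score = 25),
    make_site(pos = 3, sc = c(A = 50, C = 50, G = 0, T = 0), sc_score = 24),
    make_site(pos = 4, si = c(A = 40, C = 60, G = 0, T = 0), si_score = 26))
  out <- call_variants(calls)
  expect_equal(out$pos, c(2L, 4L))               # 8% and score-24 sites drop
  expect_equal(out$sc_alt[out$pos == 2], "C")    # boundary site is called
  expect_equal(out$sc_alt[out$pos == 4], "")
  expect_equal(out$si_alt[out$pos == 4], "C")
  bad <- calls; bad$sc_A[1] <- -1
  expect_error(call_variants(bad), "negative read count")
})

test_that("divergence frequency measures reads differing from the reference", {
  calls <- rbind(
    make_site(pos = 1, sc = c(A = 0, C = 80, G = 0, T = 0)),   # all AL4
    make_site(pos = 2, sc = c(A = 50, C = 50, G = 0, T = 0)),  # half AL4
    make_site(pos = 3, sc = c(A = 0, C = 0, G = 0, T = 0)),    # no coverage
    make_site(pos = 4, al4 = NA, sc = c(A = 9, C = 1, G = 0, T = 0)))
  d_al4 <- divergence_frequency(calls, "SC", "AL4")
  expect_equal(d_al4, c(0, 0.5, NA, NA))
  d_ref <- divergence_frequency(calls, "SC", "MN47")
  expect_equal(d_ref[1:2], c(1, 0.5))
  expect_equal(d_ref[4], 0.1)  # MN47 base known even when AL4 is not
})

test_that("window starts tile from position 1 by the step size", {
  calls <- do.call(rbind, lapply(seq(1, 300000, by = 2500), function(p)
    make_site(pos = p, sc = c(A = 30, C = 30, G = 0, T = 0),
              si = c(A = 30, C = 30, G = 0, T = 0))))
  prof <- sliding_window_profile(calls, 200000, 10000)
  expect_equal(prof$start, seq(1, 300000, by = 10000))
  expect_true(all(abs(prof$sc_mean - 0.5) < 1e-12))
  expect_true(all(abs(prof$si_mean - 0.5) < 1e-12))
  expect_error(sliding_window_profile(calls, 0, 10000), "positive")
})

test_that("window means equal the brute-force oracle on random fixtures", {
  set.seed(402)
  for (rep in 1:8) {
    calls <- random_snp_calls(400, chrom = sample(c("1", "2"), 1),
                              max_pos = 2e5)
    ws <- sample(c(20000, 50000), 1); st <- sample(c(4000, 9000), 1)
    prof <- sliding_window_profile(calls, ws, st)
    oracle <- brute_force_windows(calls, ws, st)
    expect_equal(prof$start, oracle$start)
    expect_equal(prof$sc_mean, oracle$sc_mean)
    expect_equal(prof$si_mean, oracle$si_mean)
    expect_equal(prof$n_snps, oracle$n_snps)
  }
})

test_that("profiles are invariant to the input order of SNPs", {
  set.seed(11)
  calls <- random_snp_calls(300, max_pos = 1e5)
  shuffled <- calls[sample.int(nrow(calls)), ]
  expect_equal(sliding_window_profile(calls, 30000, 5000),
               sliding_window_profile(shuffled, 30000, 5000),
               ignore_attr = TRUE)
})

test_that("the seven sharing categories follow the published definitions", {
  # SC fixed on AL4 allele != MN47, SI polymorphic: categories 1, 2, 4
  s1 <- classify_snp(make_site(sc = c(A = 0, C = 70, G = 0, T = 0),
                               si = c(A = 40, C = 60, G = 0, T = 0)))
  expect_true(s1$homo_sc && s1$al4_sc_homo_si_het && s1$sc_eq_al4_si_het)
  expect_false(s1$sc_ne_si_both_homo || s1$sc_eq_mn47_homo ||
                 s1$missing_in_sc || s1$indel)
  # SC has no coverage: category 6 only
  s6 <- classify_snp(make_site(sc = c(A = 0, C = 0, G = 0, T = 0),
                               si = c(A = 30, C = 0, G = 0, T = 0)))
  expect_true(s6$missing_in_sc)
  expect_false(s6$homo_sc || s6$al4_sc_homo_si_het || s6$sc_eq_al4_si_het)
  # both pools fixed on the same allele = MN47 = AL4: categories 1 and 5
  s5 <- classify_snp(make_site(al4 = "A",
                               sc = c(A = 70, C = 0, G = 0, T = 0),
                               si = c(A = 66, C = 0, G = 0, T = 0)))
  expect_true(s5$homo_sc && s5$sc_eq_mn47_homo)
  expect_false(s5$al4_sc_homo_si_het || s5$sc_ne_si_both_homo ||
                 s5$sc_eq_al4_si_het)
  # pools fixed on different alleles: category 3
  s3 <- classify_snp(make_site(sc = c(A = 0, C = 70, G = 0, T = 0),
                               si = c(A = 50, C = 0, G = 0, T = 0)))
  expect_true(s3$sc_ne_si_both_homo)
})

test_that("flag implications hold on large random SNP sets", {
  set.seed(12021)
  calls <- classify_snp(random_snp_calls(20000, max_pos = 5e6))
  expect_true(all(!calls$sc_eq_al4_si_het | calls$al4_sc_homo_si_het))
  expect_true(all(!calls$al4_sc_homo_si_het | calls$homo_sc))
  expect_true(all(!calls$missing_in_sc | !calls$homo_sc))
})

test_that("candidate filter returns the planted set and is idempotent", {
  set.seed(77)
  noise <- random_snp_calls(500, max_pos = 1e6)
  planted <- do.call(rbind, lapply(1:7, function(i)
    make_site(pos = 1e6 + i, ref = "A", al4 = "C",
              sc = c(A = 0, C = 60, G = 0, T = 0),
              si = c(A = 25, C = 35, G = 0, T = 0))))
  # make the noise ineligible: SC allele equals MN47 wherever SC is fixed
  noise$al4 <- noise$ref
  calls <- rbind(noise, planted)
  out <- candidate_snp_filter(calls)
  expect_equal(sort(out$pos), 1e6 + 1:7)
  expect_equal(candidate_snp_filter(out), out)            # idempotent
  # monotone: filtering a subset yields a subset of the survivors
  sub <- calls[sample.int(nrow(calls), 200), ]
  out_sub <- candidate_snp_filter(sub)
  expect_true(all(paste(out_sub$chrom, out_sub$pos) %in%
                    paste(out$chrom, out$pos)))
  # exclusions: SC fixed on the MN47 base, and indels
  mn47 <- make_site(pos = 5, ref = "C", al4 = "C",
                    sc = c(A = 0, C = 60, G = 0, T = 0),
                    si = c(A = 25, C = 35, G = 0, T = 0))
  expect_equal(nrow(candidate_snp_filter(mn47)), 0L)
  indel <- planted[1, ]; indel$is_indel <- TRUE
  expect_equal(nrow(candidate_snp_filter(indel)), 0L)
})

test_that("region detection finds implanted runs and applies tie-breaks", {
  mk_prof <- function(chrom, starts, sc, si) {
    data.frame(chrom = chrom, start = starts, end = starts + 19999,
               sc_mean = sc, si_mean = si,
               n_snps = 5L, stringsAsFactors = FALSE)
  }
  starts <- seq(1, by = 5000, length.out = 100)
  sc <- rep(0.5, 100); si <- rep(0.5, 100)
  sc[30:59] <- 0.01                      # 30 qualifying windows
  prof <- mk_prof("7", starts, sc, si)
  regs <- detect_regions(prof, sc_max = 0.05, si_min = 0.35,
                         min_windows = 10, step_size = 5000)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start, starts[30])
  expect_equal(regs$end, starts[59] + 19999)
  expect_equal(regs$n_windows, 30L)

  none <- detect_regions(mk_prof("7", starts, rep(0.5, 100), si),
                         step_size = 5000)
  expect_equal(nrow(none), 0L)

  # two equal-length runs rank by SC mean, then coordinates
  sc2 <- rep(0.5, 100); sc2[10:19] <- 0.04; sc2[60:69] <- 0.01
  regs2 <- detect_regions(mk_prof("7", starts, sc2, si), min_windows = 10,
                          step_size = 5000)
  expect_equal(regs2$start[1], starts[60])   # lower SC mean wins
  expect_equal(regs2$rank, 1:2)
})

test_that("gene summaries count SNPs and preserve flag-proportion order", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "1",
                      start = c(100, 1000), end = c(500, 1200),
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene = "g1", chrom = "1", start = 150, end = 300,
                    stringsAsFactors = FALSE)
  calls <- classify_snp(rbind(
    make_site(pos = 120, sc = c(A = 0, C = 60, G = 0, T = 0),
              si = c(A = 30, C = 30, G = 0, T = 0)),
    make_site(pos = 200, sc = c(A = 0, C = 60, G = 0, T = 0),
              si = c(A = 30, C = 30, G = 0, T = 0)),
    make_site(pos = 300, sc = c(A = 30, C = 30, G = 0, T = 0),
              si = c(A = 30, C = 30, G = 0, T = 0)),
    make_site(pos = 400, sc = c(A = 30, C = 30, G = 0, T = 0),
              si = c(A = 30, C = 30, G = 0, T = 0))))
  out <- gene_summary(calls, genes, cds)
  expect_equal(out$n_snps, c(4L, 0L))
  expect_equal(out$p_al4_sc_homo_si_het[1], 0.5)
  expect_equal(out$n_coding[1], 2L)
  expect_true(is.na(out$p_homo_sc[2]))        # zero-SNP gene reports NA
  expect_true(out$p_sc_eq_al4_si_het[1] <= out$p_al4_sc_homo_si_het[1])
  expect_true(out$p_al4_sc_homo_si_het[1] <= out$p_homo_sc[1])
  expect_equal(nrow(gene_summary(calls, genes[0, ])), 0L)
})
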