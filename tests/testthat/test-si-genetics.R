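test_that("dominance controls which specificities are expressed", {
  d <- dominance_model()
  expect_equal(expressed_specificities(c("S1", "S19"), d), "S19")
  expect_equal(expressed_specificities(c("S1", "S1"), d), "S1")
  expect_equal(expressed_specificities(c("S3", "S23"), d), c("S23", "S3"))
  # user-supplied order overrides codominance
  d2 <- dominance_model(data.frame(dominant = "S19", recessive = "S3"))
  expect_equal(expressed_specificities(c("S3", "S19"), d2), "S19")
  expect_error(dominance_model(data.frame(dominant = "S3", recessive = "S3")),
               "irreflexive")
  expect_error(dominance_model(data.frame(dominant = c("S3", "S19"),
                                          recessive = c("S19", "S3"))),
               "cycle")
})

test_that("compatibility follows expressed-specificity overlap", {
  d <- dominance_model()
  mo <- plant_genotype(c("S1", "S23"))
  fa <- plant_genotype(c("S1", "Sx"))
  expect_true(is_compatible(mo, fa, d))      # S23 vs Sx: disjoint
  expect_false(is_compatible(mo, mo, d))     # self-pollination
  expect_false(is_compatible(plant_genotype(c("S3", "S23")),
                             plant_genotype(c("S23", "S39")), d))
  # an SC mother (S1/S1 m/m) accepts everything, even self
  sc <- plant_genotype(c("S1", "S1"), c("m", "m"))
  expect_true(is_compatible(sc, sc, d))
})

test_that("self-pollination is incompatible for every SI-functional genotype", {
  d <- dominance_model()
  alleles <- c("S1", "S3", "S19", "S23")
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    g <- plant_genotype(c(alleles[i], alleles[j]), c("M", "m"))
    expect_false(is_compatible(g, g, d))
  }
})

test_that("simulate_cross is seed-reproducible and Mendelian", {
  mo <- plant_genotype(c("S1", "Sx"), c("M", "m"))
  fa <- plant_genotype(c("S1", "S23"), c("M", "m"))
  a <- simulate_cross(mo, fa, 200, seed = 9)
  b <- simulate_cross(mo, fa, 200, seed = 9)
  expect_identical(a, b)

  fixed <- plant_genotype(c("S1", "S1"), c("m", "m"))
  off <- simulate_cross(fixed, fixed, 50, seed = 1)
  expect_true(all(off$s1 == "S1" & off$s2 == "S1" &
                    off$mod1 == "m" & off$mod2 == "m"))

  # S-genotype quarters within 3 binomial sigmas at n = 4000
  big <- simulate_cross(mo, fa, 4000, seed = 5)
  freq <- table(s_genotype_label(big)) / 4000
  expect_equal(sort(names(freq)), c("S1/S1", "S1/S23", "S1/Sx", "S23/Sx"))
  sigma <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))

  expect_error(simulate_cross(mo, mo, 10, seed = 1), "rejected by SI")
  expect_s3_class(simulate_cross(mo, mo, 10, seed = 1, override = TRUE),
                  "plant_cohort")
})

test_that("scenario-A phenotypes require S1/S1 plus homozygous modifier", {
  expect_equal(phenotype_from_genotype(
    plant_genotype(c("S1", "S1"), c("m", "m"))), "SC")
  expect_equal(phenotype_from_genotype(
    plant_genotype(c("S1", "S1"), c("M", "m"))), "SI")
  expect_equal(phenotype_from_genotype(
    plant_genotype(c("S1", "S23"), c("m", "m"))), "SI")
  expect_error(phenotype_from_genotype(
    plant_genotype(c("S1", "S1")), model = "scenarioB"), "unknown model")
  # male sterility masks phenotypes at the given rate, reproducibly
  cohort <- data.frame(s1 = "S1", s2 = "S23", mod1 = "m", mod2 = "m")[rep(1, 500), ]
  ph <- phenotype_from_genotype(cohort, male_sterility_rate = 0.2, seed = 3)
  expect_identical(ph, phenotype_from_genotype(cohort,
                                               male_sterility_rate = 0.2,
                                               seed = 3))
  expect_gt(mean(ph == "male_sterile"), 0.1)
  expect_lt(mean(ph == "male_sterile"), 0.3)
})

test_that("silique counts classify into SC / SI / leaky / ambiguous", {
  expect_equal(classify_selfing_phenotype(6, 0, 0), "SC")
  expect_equal(classify_selfing_phenotype(0, 0, 6), "SI")
  expect_equal(classify_selfing_phenotype(0, 2, 4), "leaky")
  expect_equal(classify_selfing_phenotype(4, 1, 1), "ambiguous")
  expect_equal(classify_selfing_phenotype(5, 0, 1), "SC")
  # proportional generalisation beyond six pollinations
  expect_equal(classify_selfing_phenotype(10, 0, 2), "SC")
  expect_equal(classify_selfing_phenotype(9, 0, 3), "ambiguous")
  expect_error(classify_selfing_phenotype(3, 1, 1), "insufficient")
  expect_error(classify_selfing_phenotype(6, -1, 1), "negative")
})

test_that("expected F2 segregation matches the independent enumeration", {
  d <- dominance_model()
  mo <- plant_genotype(c("S1", "Sx"), c("M", "m"))
  fa <- plant_genotype(c("S1", "S23"), c("M", "m"))
  dist <- expected_f2_segregation(mo, fa, d)
  expect_equal(sum(dist$prob), 1)
  expect_equal(sum(dist$prob[dist$phenotype == "SC"]), 1 / 16)
  squart <- tapply(dist$prob, dist$s_genotype, sum)
  expect_true(all(abs(squart - 0.25) < 1e-12))

  oracle <- enumerate_cross(mo, fa)
  key <- paste(dist$s_genotype, dist$modifier_genotype, dist$phenotype,
               sep = "|")
  expect_setequal(key, oracle$key)
  expect_equal(dist$prob[match(oracle$key, key)], oracle$prob)

  # edge designs
  mm <- expected_f2_segregation(
    plant_genotype(c("S1", "Sx"), c("M", "M")),
    plant_genotype(c("S1", "S23"), c("M", "M")), d)
  expect_equal(sum(mm$prob[mm$phenotype == "SC"]), 0)
  rr <- expected_f2_segregation(
    plant_genotype(c("S1", "Sx"), c("m", "m")),
    plant_genotype(c("S1", "S23"), c("m", "m")), d)
  expect_equal(sum(rr$prob[rr$phenotype == "SC"]), 1 / 4)
  expect_error(expected_f2_segregation(mo, mo, d), "rejected by SI")
})

test_that("enumeration matches simulation over all crossable 4-allele pairs", {
  d <- dominance_model()
  alleles <- c("S1", "S3", "S19", "S23")
  genos <- rbind(t(combn(alleles, 2)), cbind(alleles, alleles))
  for (a in seq_len(nrow(genos))) for (b in seq_len(nrow(genos))) {
    mo <- plant_genotype(genos[a, ], c("M", "m"))
    fa <- plant_genotype(genos[b, ], c("M", "m"))
    if (!is_compatible(mo, fa, d)) next
    dist <- expected_f2_segregation(mo, fa, d)
    expect_equal(sum(dist$prob), 1)
    oracle <- enumerate_cross(mo, fa)
    key <- paste(dist$s_genotype, dist$modifier_genotype, dist$phenotype,
                 sep = "|")
    expect_setequal(key, oracle$key)
    expect_equal(dist$prob[match(oracle$key, key)], oracle$prob)
  }
})

test_that("chi-square statistic, df and errors follow the Pearson recipe", {
  res <- segregation_chi_square(c(A = 30, B = 10), c(A = 0.5, B = 0.5))
  expect_equal(res$chi_square, 10)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, stats::pchisq(10, 1, lower.tail = FALSE))

  exact <- segregation_chi_square(c(A = 25, B = 25, C = 50),
                                  c(A = 0.25, B = 0.25, C = 0.5))
  expect_equal(exact$chi_square, 0)
  expect_equal(exact$p_value, 1)

  expect_error(segregation_chi_square(c(A = 5, B = 5), c(A = 1, B = 0)),
               "expected proportion 0")
  expect_error(segregation_chi_square(c(A = 5), c(B = 1)), "must match")
  expect_error(segregation_chi_square(c(A = 1, B = 1), c(A = 0.6, B = 0.6)),
               "sum to 1")
})

test_that("viability distortion removes S1 carriers monotonically", {
  mo <- plant_genotype(c("S1", "Sx"), c("M", "m"))
  fa <- plant_genotype(c("S1", "S23"), c("M", "m"))
  s1_count <- function(s, mode) {
    off <- simulate_cross(mo, fa, 2000, seed = 11,
                          viability = list(allele = "S1", s = s, mode = mode))
    sum(off$s1 == "S1") + sum(off$s2 == "S1")
  }
  for (mode in c("zygote", "gamete")) {
    counts <- vapply(c(0, 0.3, 0.6, 0.9), s1_count, 1, mode = mode)
    expect_true(all(diff(counts) < 0))
  }
})
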