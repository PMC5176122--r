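#!/usr/bin/env Rscript
# Stage 3: parameter recovery of the allele-number estimator.
#
# Simulates SI populations with known allele number K, degrades them to the
# seven-allele detection panel, runs B80 inference and the bounded
# repeatability estimator, and reports how often [min, max] brackets K.
# With samples of 8 individuals (16 gene copies) the estimator is strongly
# biased upward once half the copies are distinct, so coverage is low; the
# table quantifies that honestly.

library(silocus)

panel <- c("S1", "S3", "S13", "S19", "S20", "S23", "S39")
labels <- c(panel, "S2", "S4", "S5")
n_rep <- 200

rows <- lapply(4:10, function(K) {
  alleles <- labels[1:K]
  hits <- 0; lo_sum <- 0; hi_sum <- 0; unbounded <- 0
  for (r in seq_len(n_rep)) {
    spec <- population_sim_spec(alleles, seed = 1000 * K + r)
    sim <- simulate_si_population(spec)
    obs <- simulate_partial_genotyping(sim$truth, sim$genotypes,
                                       panel = intersect(alleles, panel))
    inf <- infer_missing_alleles(obs, synthetic_linkmap(alleles))
    est <- bound_allele_number(tally_population(inf))
    lo <- est$rounded_min
    hi <- if (est$max_unbounded) NA else est$rounded_max
    if (is.na(hi)) unbounded <- unbounded + 1
    if (!est$min_unbounded && lo <= K && (is.na(hi) || K <= hi))
      hits <- hits + 1
    lo_sum <- lo_sum + lo; hi_sum <- hi_sum + ifelse(is.na(hi), lo, hi)
  }
  data.frame(K = K, coverage = hits / n_rep, mean_min = lo_sum / n_rep,
             mean_max = hi_sum / n_rep, unbounded = unbounded)
})
out <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.table(out, "results/estimator_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Bracketing coverage of [min, max] for true K (", n_rep,
    "replicates each):\n")
print(out, row.names = FALSE)
cat("\nThe repeatability index overestimates K whenever most sampled",
    "copies are distinct (n close to m), so 16-copy samples rarely bracket",
    "the truth; the bounds are a rough field instrument, not a calibrated",
    "interval estimator.\n")
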