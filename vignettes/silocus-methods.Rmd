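---
title: "Methods: S-allele diversity, SI genetics and bulked-segregant scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-allele diversity, SI genetics and bulked-segregant scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silocus)
```

silocus implements the analytical chain of an intraspecific study of
self-incompatibility (SI) breakdown in *Arabidopsis lyrata*: estimating how
many S-haplotypes segregate in each population, modelling the sporophytic
genetics of the loss of SI, and localizing the causal factors with a
bulked-segregant pooled-sequencing scan. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made where
the design was genuinely open.

## 1. Estimating the number of S-haplotypes per population

Samples are 8 diploid individuals per population (m = 16 gene copies).
Allele-specific PCR identifies a panel of known SRK alleles; cloning and
amplicon sequencing add a few more. An individual in which only one allele
amplifies is either a homozygote or carries an unidentified allele. The
flanking gene B80 sits in strong linkage disequilibrium with SRK, so its
genotype disambiguates: B80 homozygosity implies an SRK homozygote; B80
heterozygosity predicts a missed allele (`infer_missing_alleles()`). When
both B80 haplotypes are known to associate only with the single identified
allele, the individual is treated as a homozygote from two genetic
backgrounds (the study's default; `same_allele = "two_alleles"` keeps the
conservative alternative).

The number of alleles in the population is estimated from the repeatability
of alleles in the sample. With `n` distinct alleles among `m` copies we use

$$\hat N = \frac{n}{1 - \dfrac{n-2}{m-2}},$$

which is exact at the fixed point n = 2 (two alleles, all copies repeated),
grows as repeats disappear, and is undefined at n = m (no repeats: the
estimate is unbounded and is reported as an explicit flag, never as a
number). The bare denominator form is retained behind
`repeatability_estimate(..., literal = TRUE)` for audit; it is bounded by
~1 and cannot serve as an allele count. Estimates are rounded to the
nearest integer, ties upward.

Unidentified copies bound the truth rather than pin it:
the minimum assumes all unidentified copies are one shared novel allele,
the maximum that every one is distinct (`bound_allele_number()`). Group
summaries average the rounded per-population integers and round to two
decimals; outcrossing-rate (Tm) means exclude populations whose Tm
estimate is flagged unreliable in the metadata, and mixed-mating
populations belong to neither group.

Two conventions merit a note. An individual counts as heterozygous when its
two copies are not the same identified allele — a predicted (unknown)
second copy counts as heterozygous, which is the only reading consistent
with the published per-population heterozygosity values. And alleles known
to be unlinked to the SI phenotype (the S45 amplicon) are dropped from
tallies via an exclusion list before ploidy is enforced, re-padding the
genotype with an unknown marker when fewer than two copies remain.

### How trustworthy are the bounds?

`analysis/03_estimator_recovery.R` simulates SI populations with known K,
degrades them to a seven-allele detection panel, and measures how often
[min, max] brackets K. Coverage is poor (0–0.34 for K in 4..10 at 200
replicates per K): with only 16 copies the estimator inflates steeply once
more than half the copies are distinct — true K = 4 nearly always yields
n = 4 and an estimate of 5; K = 7 yields estimates of 8–11. The bounds
reproduce the published table exactly, but they are a rough field
instrument, not a calibrated interval estimator, and the package reports
the coverage table rather than pretending otherwise.

## 2. Sporophytic SI genetics and the recessive modifier

Under sporophytic SI both pollen and pistil express specificities
determined by the diploid parent, subject to dominance. The dominance model
is a partial order: by default only "S1 recessive to every other allele" is
asserted (the one relation the crossing data support); all other pairs are
codominant, and a user-supplied order can override
(`dominance_model()`). A pollination is incompatible when the pollen
donor's expressed set intersects the mother's (`is_compatible()`); a plant
without functional SI accepts all pollen, including self.

Self-compatibility follows the recessive-modifier model: SC requires
homozygosity for S1 at the S-locus *and* homozygosity for a recessive
allele m at an unlinked modifier locus; every other genotype is SI
(`phenotype_from_genotype()`). The study's F1 design — S1/Sx × S1/S23,
both Mm — gives exactly P(SC) = 1/16 with the four S-genotypes in equal
quarters (`expected_f2_segregation()`, verified against an independent
gamete enumeration in the tests). Male sterility, observed in real F2
families but without a stated genetic model, is overlaid as an independent
per-plant masking probability (default 0). Leaky SI is never generated by
the genetic model — no mechanism is asserted for it — and arises only when
classifying silique data.

Selfing phenotypes from self-pollination records follow the 5-of-6 rule:
SC when at least ⌈5/6·total⌉ pollinations set full siliques, SI when that
many are empty, leaky when two or more are partial and neither rule fires,
otherwise ambiguous; the rule generalizes proportionally beyond six
pollinations and conflicts resolve to ambiguous
(`classify_selfing_phenotype()`).

Segregation is tested with the Pearson chi-square against Mendelian
proportions (df = classes − 1, upper tail); its size at α = 0.05 is
verified at 0.052 over 1000 simulated 97-plant families. Because it is
unresolved whether the observed bias against S1 acts on gametes or
zygotes, `simulate_cross()` exposes a viability-distortion option in both
modes (selection coefficient against carriers of a named allele, applied
to gametes or to zygotes) and defaults to none; the S1 allele count
decreases monotonically in the selection coefficient in either mode. The
modifier locus is fully unlinked (free recombination), per the study's
conclusion. All randomness flows from one integer seed per call.

## 3. The bulked-segregant scan

Pooled SNP calls carry, per site and pool (SC and SI), read counts over
the four nucleotides, a depth, an opaque phred-like site score (its
internal computation is not modelled), an indel flag, the mapping
reference allele (MN47) and where known the allele of AL4, a
self-compatible reference genotype from the same population as the SC
parent. Thresholds are inclusive throughout and default to the study's
values, centralized in `run_config()`: alternative alleles require a
within-pool frequency ≥ 10% and score ≥ 25 (`call_variants()`); a pool is
"homozygous/fixed" when its minor-allele read fraction is ≤ 0.001 — pools
have no diploid genotype, so fixation is defined on read fractions.

`divergence_frequency()` is the fraction of a pool's reads differing from
the chosen reference allele (0 = fixed for the reference; missing when
depth is 0 or the reference allele unknown; missing propagates, never
imputed). `sliding_window_profile()` averages it in windows of 200000 bp
advancing by 10000 bp, anchored at position 1 (the anchoring is not
dictated by the source material; position 1 with half-open windows
[start, start + size) and retained partial terminal windows is this
package's convention), per chromosome while the window start does not pass
the last SNP.

Candidate regions are maximal stretches where the SC pool mean divergence
from AL4 is at most `sc_max` while the SI pool stays at least `si_min` —
the "dip toward fixation against persistent heterozygosity" signal. The
defaults 0.05/0.35 quantify a pattern the source material shows only
graphically; both are configurable. Because windows overlap (step <
window), qualifying runs whose extents overlap merge into one region;
regions rank by qualifying-window count, then ascending SC mean, then
coordinates, with deterministic tie-breaks. `min_windows` (default 10,
i.e. ~290 kb of support) suppresses single-window noise.

The seven-category SNP classification against both references
(`classify_snp()`) encodes: (1) SC pool fixed; (2) SC and AL4 both
homozygous, SI polymorphic; (3) SC and SI fixed for different alleles;
(4) as 2 with the SC allele equal to AL4's; (5) SC fixed for the MN47
base; (6) no SC coverage (suppresses 1–5); (7) indel. The implications
(4)⇒(2)⇒(1) and (6)⇒¬(1) hold by construction and are property-tested on
10^5 random sites. `candidate_snp_filter()` keeps non-indel sites fixed in
SC for the AL4 allele, differing from MN47, with the SI pool polymorphic
or fixed elsewhere — it is idempotent and monotone. `gene_summary()`
reports per-gene category proportions, assigning a SNP overlapped by
several genes to the longest.

## 4. What the synthetic data emulate — and what they do not

`simulate_si_population()` draws each sampled individual from a
compatibility-constrained random mating (rejection sampling of
Hardy–Weinberg parents under the dominance model), so alleles dominant
over all others never appear homozygous, matching the field observation.
Default allele frequencies give the recessive allele twice the weight of
each codominant one — a one-parameter nod to the sporophytic-SI
equilibrium, at which recessive specificities segregate at higher
frequency; the generator does not iterate to a true equilibrium.
`simulate_partial_genotyping()` then hides off-panel alleles and emits B80
genotypes so the inference step can be tested against known truth.

`simulate_f2_bsa()` models the mapping cross with fully homozygous,
everywhere-divergent grandparental backgrounds: AL4-like (carrying S1 and
the recessive modifier allele m) and MN47-like (S23/Sx, M). Each meiosis
places a Poisson(1) number of uniform crossovers per chromosome — enough
recombination structure for window-scale signal, not a calibrated genetic
map. Pool read counts are binomial at Poisson depth with a symmetric
per-read error (default 0.001, post-filter short-read quality); scores
are drawn high (mean 40) so threshold behaviour is controlled explicitly;
2% of sites are flagged as indels. Ground truth (causal positions,
genotypes, per-site analytic pool fractions) accompanies every dataset,
and every generator is bit-reproducible under its seed.

Defaults: 20 Mb "chromosome 7" with the S-locus at 9.5 Mb, the modifier on
"chromosome 5", 50 SNPs/Mb, pools of 10 at mean depth 50×. The F2 family
defaults to 500 plants: with both F1 parents Mm the SC class is 1/16, and
500 keeps the 10-plant SC pool available in essentially every family; a
97-plant family can be requested and raises an "insufficient SC plants"
error when it yields fewer SC plants than the pool needs.

What the simulation does not capture: real heterozygous outbred parents
(backgrounds are fully divergent, so every marker is maximally
informative), family structure in the pools, reference-mapping artifacts
(the real S-locus itself fails to map and yields no SNP calls), indel
alleles (indels are flags on point sites), and base-composition or error
profiles. Passing tests therefore demonstrate correctness of the
*procedure* under idealized marker data, not performance on real pools.

## 5. Measured operating characteristics

Two full-scale checks in the test suite report honest statistics rather
than comfortable ones, at sizes chosen to characterize the procedures
(100 scan replicates; 200 population replicates per K):

* **Scan localization.** Over 100 simulated default families, the
  top-ranked region on the S-locus chromosome contains the causal position
  94 times. The shortfall has two causes: an SI pool of 10 plants has an
  MN47-allele fraction distributed ~N(0.53, 0.11) at the causal locus, so
  ~3% of pools fall below the 0.35 window threshold right where it
  matters; and under ~1 crossover per chromosome, megabase-scale SC-fixed
  linkage blocks occasionally produce a longer qualifying run away from
  the causal position. The companion signal — the SC pool fixed for the
  AL4 background at the unlinked modifier — held in 100/100 replicates.
  Larger pools, not different thresholds, are the remedy.
* **Estimator recovery.** As described in section 1, the [min, max]
  allele-number bounds bracket the true K in a minority of replicates at
  the study's sample size; the per-K coverage table ships in
  `results/estimator_recovery.tsv` when the analysis driver is run.

## 6. Numerical and degenerate-input conventions

Rounding of estimates is half-up (8.4→8, 6.5→7). Unbounded estimates are
flags, never infinities in reports. Windows with no SNPs carry missing
means; zero-depth pools yield missing divergence; genes with no assigned
SNPs report NA proportions. Probability distributions must sum to 1 within
1e−9 (asserted). Chi-square classes with zero expected proportion and
nonzero observation are an error rather than a silent drop. Readers reject
malformed files with the offending column, line or site coordinate named;
writers are deterministic, and write→read is the identity on canonical
tables for both the TSV and VCF dialects.
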