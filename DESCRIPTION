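Package: silocus
Title: Sporophytic Self-Incompatibility Genetics and Bulked Segregant Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical chain for studying the intraspecific breakdown of
    sporophytic self-incompatibility (SI) in Arabidopsis lyrata: estimation of
    per-population S-allele numbers with a repeatability index and
    missing-allele bounds inferred from the linked B80 marker; a genetic model
    of sporophytic SI with a dominance hierarchy, crossing-design simulation
    and an unlinked recessive modifier of self-compatibility; selfing-phenotype
    classification from silique counts and Mendelian segregation tests; and a
    bulked-segregant pooled-SNP scan with sliding-window allele-frequency
    profiles, candidate-region detection and a seven-category SNP-sharing
    classification against two reference genotypes. Synthetic-data generators
    emulate every input with known ground truth so all stages are testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    rtracklayer,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
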