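Package: svclades
Title: Phylogenetically Informed Structural Variant Filtering and Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of structural variation (SV)
    segregating in cohorts sampled across deeply diverged clades. Implements
    multi-caller consensus merging of SV call sets with read-support and length
    filters, phylogenetically informed genotype filtering under the infinite
    sites model with per-clade genotyping-error tolerances, folded allele
    frequency spectra by repeat class, per-variant Weir-Cockerham F_ST with
    percentile outlier scans and chromosomal enrichment, best-overlap repeat
    family assignment, LTR retrotransposon insertion dating from terminal
    repeat divergence, and additive/dominance genotype-phenotype association
    with AICc/BIC model comparison. Ships a synthetic two-clade diploid cohort
    generator with ground-truth labels for end-to-end validation of every
    stage, and a deterministic pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    IRanges,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
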