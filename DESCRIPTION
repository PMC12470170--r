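Package: mixdeconv
Title: Probabilistic Deconvolution of Sequenced Microhaplotype and STR Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and probabilistic interpretation of forensic DNA
    mixtures typed by massively parallel sequencing. Generates synthetic
    microhaplotype (MH) and short tandem repeat (STR) amplicon panels,
    Hardy-Weinberg cohorts and FASTQ read sets with locus-efficiency
    variation, heterozygote imbalance, STR stutter and noise; constructs
    two- and three-person mixtures by seeded read subsampling; calls
    alleles by exact amplicon matching with an analytical read threshold;
    calibrates per-locus efficiency, stutter and noise models from
    single-source samples; deconvolutes mixtures by maximum-likelihood
    fitting of contributor proportions under a negative binomial read-count
    model with drop-out, and reports per-contributor genotype posteriors
    and likelihood ratios for suspect hypotheses; and scores deconvolutions
    against known profiles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
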