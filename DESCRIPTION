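Package: clonemix
Title: Clonal Evolution of Paired Diagnosis-Relapse Tumours from Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tumour clonal architecture and its evolution between
    diagnosis and relapse from deep-sequencing mutant-allele read counts.
    Provides coverage-aware binomial mixture clustering of mutant allele
    fractions with EM fitting and AIC model selection, tumour purity
    estimation, greedy clonal lineage reconstruction with population-size
    accounting and relapse-founder mapping, biological resolution of lineage
    ambiguity (driver mutual exclusivity and mutation-spectrum tests),
    compound binomial tests for mutation-cluster distinctness, detection-power
    calculations for low-frequency mutations, site-specific screening of
    low-frequency mutant read evidence, and a synthetic clonal-architecture
    generator with ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
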