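Package: msdaflp
Title: Methylated Site Display AFLP: Virtual Digests, Peak-Chart Simulation
    and CpG Methylation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for methylated site display amplified fragment length
    polymorphism (MSD-AFLP) profiling of CpG methylation. Builds the virtual
    SbfI-to-HpaII fragment database used to predict loci from electropherogram
    peaks, reports fragment size-uniqueness statistics, forward-simulates the
    methylation-dependent library chemistry into noisy capillary peak charts
    (including the fully methylated SssI reference), calibrates signal ratios
    to percent methylation with a Hill response curve, quantifies
    methylation-sensitive restriction enzyme (MSRE) PCR measurements, and runs
    the differential-methylation pipeline: per-CpG one-way ANOVA with
    Benjamini-Hochberg false discovery rate control, Tukey HSD post hoc tests,
    subtle-effect filters, z-score normalization, PCA and UPGMA clustering. A
    synthetic-data module generates genomes, methylomes and complete studies
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
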