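Package: vafqc
Title: Quality Control of Allele-Specific Copy Number Calls via VAF Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates clonal and subclonal allele-specific copy number
    calls, tumor purity and ploidy from bulk tumor sequencing by comparing
    theoretical variant-allele-frequency (VAF) peaks against peaks detected
    in somatic mutation data. Predicts peak positions for simple, complex
    and two-subclone copy states (including enumeration of linear and
    branching evolution models), scores purity/ploidy solutions with a
    signed, mutation-weighted purity-correction score, computes per-mutation
    cancer cell fractions with entropy-based multiplicity phasing, tests
    chromosome arms for copy-number over-fragmentation, and ships a
    synthetic-tumor simulator plus simulation-based calibration of the
    purity tolerance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    pracma,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
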