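Package: fragcnv
Title: Fragmentomic Copy-Number Profiling and Classification of Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for liquid-biopsy fragmentomics: size-gated fragment-length
    profiling of cell-free DNA, uniform-window counting of short and medium
    fragments over a target region (chromosome 18q in colorectal cancer),
    batch-wise correlation filtering of region features, shrinkage linear
    discriminant classification of cancer versus control plasma samples, and
    GC-stratified coverage regression to quantify conversion-chemistry bias
    (bisulfite versus enzymatic methyl conversion). Includes a synthetic
    cfDNA cohort simulator with nucleosome-periodic fragment lengths,
    tumor-fraction-scaled copy-number alteration, and chemistry-dependent
    fragment degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    MASS,
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
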