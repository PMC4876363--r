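Package: cfseedling
Title: Seedling Diagnosis from Chlorophyll-Fluorescence Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput seedling diagnosis from panel chlorophyll-
    fluorescence (CF) image stacks, as used in plant factories with
    artificial lighting. Segments seedlings from sponge-block background
    with a discriminant-analysis (Otsu-style) threshold computed per
    block, quantifies a plateau-normalized integrated CF index per
    seedling, fits fixed-period (24 h) cosinor rhythms to the daily CF
    time course, assembles single- and multi-index feature sets, and runs
    a repeated neural-network growth-prediction protocol reporting mean
    |R| with standard errors. Includes a ground-truthed synthetic panel
    simulator that renders 16-bit multi-page TIFF stacks so every
    pipeline stage is testable without factory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
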