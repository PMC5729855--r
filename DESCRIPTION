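Package: radscreen
Title: Gene-Expression Screens for Radiation Biodosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens RNA-seq count data from irradiated organisms for genes
    whose expression tracks radiation dose, so that gene expression can be
    used as a biological dosimeter. Implements median-of-ratios count
    normalization, fold changes against unirradiated controls with a
    bottom-quartile present/absent cutoff, per-gene linear dose-response
    selection by R-squared, detection of single-dose expression "spikes"
    (largest fold change at least five times the second largest), and
    cross-timepoint overlap reporting. A synthetic-data module generates
    negative-binomial count matrices with planted dose-linear, spike, and
    null genes so the full screen can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
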