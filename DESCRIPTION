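Package: napequant
Title: Targeted SRM Analysis of Intact N-Acylphosphatidylethanolamine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted liquid chromatography tandem mass spectrometry
    of intact N-acylphosphatidylethanolamine (NAPE) molecular species:
    shorthand nomenclature parsing and formatting, elemental composition and
    monoisotopic mass arithmetic, in-silico candidate enumeration, N-acyl
    specific selected reaction monitoring (SRM) transition design with
    retention-time scheduling and isobar resolution, equivalent-carbon-number
    retention modelling, a synthetic chromatogram simulator with known ground
    truth, and internal-standard quantification with assay validation
    statistics (linearity, accuracy, precision, lower limit of
    quantification).
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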