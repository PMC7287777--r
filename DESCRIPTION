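Package: aiflipid
Title: All-Ion-Fragmentation Lipidomics for HILIC-ESI-MS Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of phospholipids from hydrophilic-interaction
    chromatography (HILIC) electrospray high-resolution mass spectrometry
    runs acquired with interleaved full-MS and all-ion-fragmentation (AIF)
    scans. Provides exact-mass lipid shorthand chemistry (elemental
    formulas, adduct and fatty-acyl carboxylate m/z), class-diagnostic
    fragment rules, mzML reading and writing of interleaved MS1/AIF runs,
    extracted-ion-chromatogram peak detection and spectrum averaging,
    retention-band class localization, accurate-mass species annotation,
    precursor-product trace alignment, per-class fatty-acyl profiling with
    replicate filtering, and a deterministic run simulator with ground
    truth for end-to-end validation.
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
    mzR,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
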