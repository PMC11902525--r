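Package: secstream
Title: Multi-Detector Size-Exclusion Chromatography Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-detector size-exclusion chromatography
    (md-SEC) runs recorded with a concentration detector (differential
    refractometer), dual-angle static light scattering (low-angle and
    right-angle) and a capillary-bridge differential viscometer. Takes raw
    detector traces in mV from baseline estimation and elution-region
    selection through detector-constant calibration to per-slice molecular
    weights, intrinsic viscosities and radii of gyration, molecular weight
    distributions and averages (Mn, Mw, Mz, PDI), bulk intrinsic viscosity,
    and Mark-Houwink-Sakurada conformation analysis. Includes classic
    column calibration, universal-calibration coordinates, an export
    interface for downstream structural fitting, and a forward instrument
    simulator so every stage of the pipeline can be validated against
    known ground truth without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
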