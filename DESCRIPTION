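Package: hybriddia
Title: In Silico Hybrid PRM/DIA Acquisition Simulation and Heavy/Light
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale in silico LC-MS/MS instrument for studying
    internal-standard-triggered hybrid acquisition. Simulates
    data-independent acquisition (DIA) cycles interleaved with multiplexed
    parallel reaction monitoring (MSxPRM) scans triggered in real time by
    detection of spiked stable-isotope-labelled reference peptides, with an
    Orbitrap-like duty-cycle model (automatic gain control, injection time,
    resolution-dependent transients). Provides synthetic sample generation
    (heavy/light peptide pairs, dilution series, complex background
    matrices), trigger-target list handling with retention-time-window
    concurrency profiling, and downstream heavy/light quantification:
    extracted ion chromatograms, peak integration, calibration curves with
    limit-of-detection estimation, replicate coefficients of variation,
    protein rollup, and clinical-style data matrices that distinguish
    below-LOD from technically missing values. Runs and spectra export to
    mzML and plain-text scan logs.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    mzR,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
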