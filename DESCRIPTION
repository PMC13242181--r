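Package: mzforge
Title: Targeted and Untargeted LC-MS/MS Peak-List Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data structures and algorithms for targeted and untargeted
    LC-MS/MS analysis: peakmaps holding centroided spectra and MRM/SRM
    chromatograms with mzML input and output, extracted-ion-chromatogram
    extraction and 2D binning, a typed relational table engine over an
    embedded SQLite store with in-memory and out-of-core modes,
    molecular-formula chemistry with isotope-pattern convolution and
    adduct arithmetic, chromatographic peak integrators (trapezoid,
    Savitzky-Golay, exponentially modified Gaussian), retention-time
    alignment and m/z recalibration, isotope and adduct grouping, a
    reference-based retention-time-shift correction workflow for
    co-eluting mass isomers, and a seeded synthetic-run generator with
    exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    mzR,
    DBI,
    RSQLite,
    base64enc,
    signal,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
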