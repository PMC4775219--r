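Package: rascycle
Title: Kinetic Modeling and Analysis of Reconstituted Ras GTPase Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic models of the Ras GTPase activation cycle
    with competing effectors and GTPase-activating proteins (GAPs), including
    a three-state model with a GEF-refractory post-hydrolysis state and two
    GTPase-to-GEF positive-feedback architectures (recruitment-based and
    allosteric). Provides scalar output features of effector-recruitment
    timecourses (integrated signal, initial rate, transient score, mutant
    distortion and feedback gain), factorial GEF x GAP x Ras-density scans
    with interpolated phase diagrams and isoclines, fluorescence-to-surface-
    density calibration with canonical density binning, a synthetic
    bead-timecourse generator with a calibrated noise model, and the
    downstream bead-trace processing pipeline (macro-log parsing, perimeter
    normalization, density binning and averaging, particle detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    igraph,
    pracma,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    tiff
Config/testthat/edition: 3
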