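Package: ivtk
Title: Intravital Microscopy Cell-Track and Video Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing intravital-microscopy cell tracks and videos:
    track import/export (native CSV, TrackMate-style CSV, JSON), resampling,
    fragmenting and tracklet extraction; per-track motility metrics (speed,
    directionality, arrest coefficient, mean squared displacement, velocity
    autocovariance, turning angles) with control-based residual-speed
    correction and exponential sampling-rate decay fits; windowed multivariate
    feature series compared by dependent multivariate dynamic time warping,
    embedded in 2D and clustered by density peaks with graph-based assignment;
    five-index video quality scoring on 8-bit rendered maximum-intensity
    projections; z-coordinate recovery for 2D tracks from 3D+time stacks; and
    a synthetic generator of archetypal motility tracks and blob movies with
    acquisition artifacts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
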