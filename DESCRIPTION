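Package: polyfinger
Title: Minutia-Polygon Fingerprint Matching
Version: 0.1.0
Authors@R: person("polyfinger", "developers", role = c("aut", "cre"),
    email = "devs@polyfinger.invalid")
Description: Minutia-by-minutia fingerprint matching with
    rotation/translation-invariant polygon descriptors. Provides oriented
    Gabor ridge enhancement and skeletonization, Crossing-Numbers minutiae
    extraction with convex-hull region-of-interest validation and
    minutiae-cloud averaging, per-minutia n-vertex polygon feature vectors,
    absolute/relative-error polygon matching with a total-matched-minutiae
    decision rule, biometric error-rate evaluation (FMR/FNMR/EER sweeps),
    and a seeded synthetic-data generator so every stage can be exercised
    without external fingerprint databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
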