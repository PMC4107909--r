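Package: vnoca
Title: Response Profiling of Vomeronasal Sensory Neuron Calcium Imaging
Version: 0.1.0
Authors@R:
    person("VNO Imaging", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for GCaMP calcium imaging of
    vomeronasal organ (VNO) slices: rigid registration of time-lapse
    movies, signal-to-noise based detection of responding-cell regions of
    interest (ROIs), photobleaching-corrected delta-F-over-F response
    calls at a 30 percent threshold, population summaries
    (stimulus-overlap Venn statistics, percent responding with optional
    co-label gating, normalized tuning panels, dose-response curves with
    Hill fits), and nonparametric behavior statistics (exact Mann-Whitney
    and Kruskal-Wallis tests).  A forward simulator generates slice
    movies with known ground truth so that every stage is testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
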