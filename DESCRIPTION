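Package: lamellar
Title: Cross-Species Vibrotactile Tuning of Lamellar Corpuscles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates mechano-to-neural transduction in Pacinian and Herbst
    (lamellar) corpuscles as a three-stage pipeline: a quasi-static
    concentric-shell / squeeze-film model of the layered outer core, an
    analytic strain-to-channel-current surrogate for the inner core, and a
    conductance-based point-neuron model of the afferent neurite. From a
    corpuscle's outer radius, lamella count and lamellar thickness it predicts
    the vibrotactile tuning curve (threshold displacement for 1:1 spike
    entrainment versus frequency), the peak frequency and the bandwidth. Ships
    a transcription of a published 19-species corpuscle morphometry table and
    reproduces the cross-species structural regressions; includes seeded
    synthetic-population generators for testing the statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
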