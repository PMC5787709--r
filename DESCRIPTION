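Package: rootzone
Title: Stochastic Cell-File Models and Trait Inference for Root
    Developmental Zonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven stochastic simulation of single elongating root
    cell files under four cell-elongation-termination rules (Ruler, Timer,
    Sizer, and a dilution-with-degradation rule), closed-form stationary
    traits, automated piecewise-exponential fitting of per-root cell-length
    profiles, algebraic inference of dynamical traits (meristematic
    activity, cell elongation rate, elongation-zone transit time), a
    correlation-signature engine that discriminates between the
    termination mechanisms, and decorrelation/scenario analyses of the
    meristem-elongation coupling. Includes a synthetic-cohort generator
    with ground-truth manifests so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
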