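Package: edqueue
Title: Coupled Emergency Department and Inpatient Unit Queueing Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic and simulation tools for planning emergency department
    (ED) bed capacity when admitted patients can be blocked by a full
    downstream inpatient unit (IU). Models the ED as a multi-priority
    preemptive-resume M/G/c queue whose service time is inflated by boarding
    delay, the IU as a G/GI/c/c loss system with a diffusion blocking
    approximation, and couples the two through a fixed-point equation for the
    effective ED service rate. Includes steady-state feasibility analysis, a
    fast-track (split-flow) variant, capacity estimation against per-acuity
    wait-time targets, and a discrete-event simulator for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
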