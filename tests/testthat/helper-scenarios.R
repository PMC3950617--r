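# Shared fixtures, built in code.

# hourly arrival rates by acuity level and the direct-admission stream of
# the bundled baseline
baseline_rates <- c(0.075, 0.662, 3.749, 2.86, 0.226)
baseline_direct <- 0.267
baseline_x <- 0.479 / 7.572

baseline_scenario <- function(c1 = 20L, c2 = 125L, ...) {
  scenario(baseline_rates, lambda_direct = baseline_direct,
           transfer_fraction = baseline_x,
           ed_service = tri_dist(0.1, 0.5, 1),
           iu_los = tri_dist(1, 4, 7, unit = "days"),
           c1 = c1, c2 = c2, ...)
}

baseline_path <- function() {
  system.file("extdata", "table2_baseline.yaml", package = "edqueue")
}

# Congested scenario embodying the fast-track premise: the two lowest-acuity
# classes have much shorter treatment times than the acute classes. The
# transfer load is kept well inside the IU capacity so the ED congestion is
# the binding constraint.
fast_track_premise_scenario <- function(scale, c1 = 20L) {
  svc <- c(rep(list(tri_dist(0.2, 0.8, 1.6)), 3),
           rep(list(tri_dist(0.05, 0.15, 0.4)), 2))
  scenario(scale * baseline_rates, lambda_direct = baseline_direct,
           transfer_fraction = 0.02, ed_service = svc,
           iu_los = tri_dist(1, 4, 7, unit = "days"), c1 = c1, c2 = 200L)
}
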