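test_that("bed split and routing follow the 20% example", {
  scn <- baseline_scenario(c1 = 25L)
  sp <- split_scenario(scn, fast_track_config(0.2))
  expect_equal(sum(sp$fast$arrival_rates), 3.086)     # CTAS IV-V
  expect_equal(sum(sp$regular$arrival_rates), 4.486)  # CTAS I-III
  expect_equal(sp$fast$c1, 5L)
  expect_equal(sp$regular$c1, 20L)
  expect_equal(sp$fast$c2, scn$c2)

  sol <- solve_fast_track(scn, fast_track_config(0.2))
  expect_equal(sol$p_regular, 4.486 / 7.572, tolerance = 1e-12)
  expect_equal(sol$p_fast, 3.086 / 7.572, tolerance = 1e-12)
  expect_equal(sol$p_regular + sol$p_fast, 1, tolerance = 1e-12)
})

test_that("a split leaving a line without beds is refused", {
  scn <- baseline_scenario(c1 = 25L)
  expect_error(split_scenario(scn, fast_track_config(0.01)), "no beds")
  expect_error(fast_track_config(0), "strictly")
  expect_error(fast_track_config(1), "strictly")
})

test_that("a single line holding everything reproduces the base solve", {
  scn <- baseline_scenario(c1 = 10L)
  joint <- solve_split(scn, class_sets = list(1:5), beds = scn$c1)
  base <- solve_scenario(scn, find_roots = FALSE)
  expect_equal(joint$p_b$p_b, base$p_b$p_b, tolerance = 1e-12)
  expect_equal(joint$mu_hat, base$mu_hat, tolerance = 1e-12)
  expect_equal(joint$reports[[1]]$waits$queueing_delay,
               base$waits$queueing_delay, tolerance = 1e-12)
})

test_that("the shared blocking equals blocking of the pooled transfer flow", {
  scn <- baseline_scenario(c1 = 25L)
  sol <- solve_fast_track(scn, fast_track_config(0.2))
  rd <- sum(pmin(c(sol$regular_line$lambda, sol$fast_line$lambda),
                 c(sol$regular_line$beds * sol$mu_regular,
                   sol$fast_line$beds * sol$mu_fast)))
  direct <- blocking_probability(
    iu_load(scn$c2, 1 / 96, scn$transfer_fraction * rd, scn$lambda_direct,
            0.09375))
  expect_equal(sol$p_b$p_b, direct$p_b, tolerance = 1e-12)
})

test_that("under light load each line matches its own uncoupled solve", {
  scn <- baseline_scenario(c1 = 25L)
  scn$transfer_fraction <- 0; scn$lambda_direct <- 0
  sol <- solve_fast_track(scn, fast_track_config(0.2))
  expect_identical(sol$status, "ok")
  for (line in list(sol$fast_line, sol$regular_line)) {
    un <- w_mgc_priority(line$beds, line$modified_moments)
    expect_equal(line$waits$queueing_delay, un$queueing_delay,
                 tolerance = 1e-12)
  }
  # aggregate is a convex combination of the two line averages
  avg <- c(attr(sol$regular_line$waits, "aggregate_queueing_delay"),
           attr(sol$fast_line$waits, "aggregate_queueing_delay"))
  expect_gte(sol$aggregate_wait, min(avg) - 1e-15)
  expect_lte(sol$aggregate_wait, max(avg) + 1e-15)
})

test_that("an unstable line is named in the status", {
  scn <- baseline_scenario(c1 = 10L)
  scn$arrival_rates <- scn$arrival_rates * 2.3   # fast line overloads first
  sol <- solve_fast_track(scn, fast_track_config(0.2))
  expect_match(sol$status, "unstable")
})

test_that("express service for minor cases lowers the average and raises CTAS III", {
  # congested EDs where the fast-track classes genuinely have short
  # treatments; bed share 0.15 is close to the fast work share
  for (scale in c(4.0, 4.1)) {
    scn <- fast_track_premise_scenario(scale)
    base <- solve_scenario(scn, find_roots = FALSE)
    ft <- solve_fast_track(scn, fast_track_config(0.15))
    expect_identical(base$status, "ok")
    expect_identical(ft$status, "ok")
    expect_lt(ft$aggregate_wait, attr(base$waits, "aggregate_queueing_delay"))
    expect_gt(ft$regular_line$waits$queueing_delay[3],
              base$waits$queueing_delay[3])
    # the fast classes benefit dramatically
    expect_lt(ft$fast_line$waits$queueing_delay[2],
              base$waits$queueing_delay[5])
  }
})

test_that("the literal service-rate sum constraint slows both lines", {
  scn <- baseline_scenario(c1 = 25L)
  lit <- split_scenario(scn, fast_track_config(0.2,
                                               literal_sum_constraint = TRUE))
  # each line's uncoupled service time is the base one divided by bed share
  expect_equal(dist_moments(lit$fast$ed_service[[1]])$mean,
               (1.6 / 3) / (5 / 25), tolerance = 1e-12)
  expect_equal(dist_moments(lit$regular$ed_service[[1]])$mean,
               (1.6 / 3) / (20 / 25), tolerance = 1e-12)
})
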