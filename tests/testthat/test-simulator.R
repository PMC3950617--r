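quick_cfg <- function(reps = 30, seed = 5)
  sim_config(horizon = 1500, warmup = 150, replications = reps, seed = seed)

test_that("no arrivals means empty statistics", {
  z <- scenario(c(0, 0), transfer_fraction = 0,
                ed_service = tri_dist(0.1, 0.5, 1),
                iu_los = tri_dist(1, 4, 7, "days"), c1 = 2, c2 = 5)
  s <- simulate_scenario(z, sim_config(100, 10, 3, seed = 1))
  expect_equal(s$blocking$attempts, 0)
  expect_equal(s$blocking$freq, 0)
  expect_equal(s$util_ed, 0)
  expect_equal(s$util_iu, 0)
  expect_true(all(s$per_class$lambda_eff == 0))
})

test_that("the same seed reproduces the run bitwise", {
  scn <- baseline_scenario(c1 = 6L)
  a <- simulate_scenario(scn, quick_cfg(reps = 5))
  b <- simulate_scenario(scn, quick_cfg(reps = 5))
  expect_identical(a$per_class, b$per_class)
  expect_identical(a$blocking, b$blocking)
  c <- simulate_scenario(scn, sim_config(1500, 150, 5, seed = 6))
  expect_false(identical(a$per_class, c$per_class))
})

test_that("single-class exponential runs reproduce exact M/M/c values", {
  # M/M/1, rho = 0.5: delay 1 h, sojourn 2 h
  m1 <- scenario(c(0.5), transfer_fraction = 0, ed_service = exp_dist(1),
                 iu_los = tri_dist(1, 4, 7, "days"), c1 = 1, c2 = 5)
  s1 <- simulate_scenario(m1, quick_cfg())
  expect_lt(abs(s1$per_class$queueing_delay - 1), 3 * s1$per_class$delay_ci)
  expect_lt(abs(s1$per_class$system_time - 2), 3 * s1$per_class$system_ci)

  # M/M/2, rho = 0.5: delay = P_Q/(c mu - lambda) = 1/3
  m2 <- scenario(c(1), transfer_fraction = 0, ed_service = exp_dist(1),
                 iu_los = tri_dist(1, 4, 7, "days"), c1 = 2, c2 = 5)
  s2 <- simulate_scenario(m2, quick_cfg())
  expect_lt(abs(s2$per_class$queueing_delay - 1 / 3),
            3 * s2$per_class$delay_ci)
  expect_lt(abs(s2$util_ed - 0.5), 0.01)   # offered load a/c = 1/2
})

test_that("two-class preemptive M/M/1 matches the exact priority delays", {
  scn <- scenario(c(0.2, 0.3), transfer_fraction = 0,
                  ed_service = exp_dist(1),
                  iu_los = tri_dist(1, 4, 7, "days"), c1 = 1, c2 = 5)
  s <- simulate_scenario(scn, quick_cfg(reps = 40))
  # exact first-access delays: 0.25 h (class 1), 1.25 h (class 2)
  expect_lt(abs(s$per_class$queueing_delay[1] - 0.25),
            3 * s$per_class$delay_ci[1])
  expect_lt(abs(s$per_class$queueing_delay[2] - 1.25),
            3 * s$per_class$delay_ci[2])
  expect_gt(s$preemptions, 0)
})

test_that("Little's law holds per class in stable runs", {
  scn <- baseline_scenario(c1 = 6L)
  s <- simulate_scenario(scn, quick_cfg())
  expect_true(all(abs(s$per_class$L_time_avg - s$per_class$little_LW) /
                    pmax(s$per_class$L_time_avg, 0.01) < 0.05))
  expect_true(all(abs(s$per_class$lambda_eff - baseline_rates) /
                    baseline_rates < 0.1))
})

test_that("boarding blocks beds and blocking falls with more IU beds", {
  congested_iu <- function(c2)
    scenario(c(2), transfer_fraction = 0.5, lambda_direct = 0.5,
             ed_service = exp_dist(2), iu_los = exp_dist(0.1),
             c1 = 10, c2 = c2)
  s5 <- simulate_scenario(congested_iu(5L), quick_cfg(reps = 20))
  s10 <- simulate_scenario(congested_iu(10L), quick_cfg(reps = 20))
  s25 <- simulate_scenario(congested_iu(25L), quick_cfg(reps = 20))
  expect_gt(s5$blocking$freq, s10$blocking$freq)
  expect_gt(s10$blocking$freq, s25$blocking$freq)
  expect_gt(s5$blocking$freq, 0.2)   # 15 erlangs offered to 5 beds
})

test_that("the comparison table is deterministic and complete", {
  scn <- baseline_scenario(c1 = 6L)
  cmp1 <- compare_analytic_sim(scn, quick_cfg(reps = 10))
  cmp2 <- compare_analytic_sim(scn, quick_cfg(reps = 10))
  expect_identical(as.data.frame(cmp1), as.data.frame(cmp2))
  expect_equal(nrow(cmp1), 5 + 2)     # K classes + aggregate + blocking
  expect_true(all(c("quantity", "analytic", "simulated", "rel_err")
                  %in% names(cmp1)))
})
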