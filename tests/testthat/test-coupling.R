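test_that("boarding-adjusted moments follow the deterministic-shift rule", {
  expect_equal(modified_moments(0.5, 0.4, 0, 48), list(mean = 0.5, m2 = 0.4))
  m <- modified_moments(0.5333, 0.3183, 1, 48)
  expect_equal(m$mean, 48.5333, tolerance = 1e-12)
  expect_equal(m$m2, 0.3183 + 2 * 0.5333 * 48 + 48^2, tolerance = 1e-12)
  # Jensen is preserved for any blocking level
  for (pb in c(0.1, 0.5, 0.9)) {
    mm <- modified_moments(0.5333, 0.3183, pb, 32)
    expect_gte(mm$m2, mm$mean^2)
  }
  expect_error(modified_moments(1, 0.5, 0.1, 10), "second moment")
})

test_that("service-rate bounds bracket the boarding-inflated rate", {
  scn <- baseline_scenario()
  b <- mu_bounds(scn)
  expect_equal(b$mu_max, 1.875, tolerance = 1e-9)
  expect_gt(b$mean_min, 24); expect_lt(b$mean_min, 96)
  expect_equal(b$mu_min, 1 / (1 / 1.875 + b$mean_min), tolerance = 1e-12)
  expect_lte(b$mu_min, b$mu_max)

  # degenerate stay of length zero collapses the bracket
  d0 <- scenario(c(1), transfer_fraction = 0.1,
                 ed_service = tri_dist(0.1, 0.5, 1),
                 iu_los = tri_dist(0, 0, 0), c1 = 5, c2 = 10)
  b0 <- mu_bounds(d0)
  expect_equal(b0$mu_min, b0$mu_max)
})

test_that("fixed-point residual has the boundary signs that force a root", {
  scn <- baseline_scenario()
  b <- mu_bounds(scn)
  expect_gte(fixed_point_residual(b$mu_min, scn), 0)
  expect_lte(fixed_point_residual(b$mu_max, scn), 0)

  # uncoupled limit: no transfers, so the residual vanishes at mu_1
  un <- baseline_scenario()
  un$transfer_fraction <- 0; un$lambda_direct <- 0
  expect_equal(fixed_point_residual(1.875, un), 0, tolerance = 1e-12)
})

test_that("root enumeration finds the fixed point with a tiny residual", {
  scn <- baseline_scenario()
  fp <- find_mu_roots(scn)
  expect_identical(fp$status, "ok")
  expect_gte(length(fp$roots), 1L)
  expect_true(all(abs(fp$residuals) < 1e-10))
  expect_true(all(fp$roots >= fp$mu_min & fp$roots <= fp$mu_max))
  expect_lte(fp$mu_hat_min, fp$mu_hat_max)
  # weak coupling: the root is numerically the uncoupled rate
  expect_equal(fp$mu_hat_max, 1.875, tolerance = 1e-6)
  expect_true(fp$feasibility$sufficient_met)
  expect_true(fp$feasibility$necessary_met)
  # sufficient condition can never hold without the necessary one
  expect_true(!fp$feasibility$sufficient_met || fp$feasibility$necessary_met)
})

test_that("moment iteration and root enumeration agree on the baseline", {
  rep <- solve_scenario(baseline_scenario())
  expect_identical(rep$status, "ok")
  expect_true(rep$converged)
  expect_lt(min(abs(rep$fixed_point$roots - rep$mu_hat)), 1e-6)
  expect_gte(rep$p_b$p_b, 0); expect_lte(rep$p_b$p_b, 1)
  expect_true(all(rep$modified_moments$s_mean >=
                    0.5333333 - 1e-9))          # boarding never shortens
  expect_true(rep$iu_stable)
})

test_that("with no possible blocking the solve matches the uncoupled model", {
  scn <- baseline_scenario()
  scn$transfer_fraction <- 0; scn$lambda_direct <- 0
  rep <- solve_scenario(scn, find_roots = FALSE)
  expect_identical(rep$status, "ok")
  expect_equal(rep$p_b$p_b, 0)
  raw <- class_moments(baseline_rates, rep(1.6 / 3, 5),
                       rep(0.61 / 18 + (1.6 / 3)^2, 5))
  direct <- w_mgc_priority(20, raw)
  expect_equal(rep$waits$queueing_delay, direct$queueing_delay,
               tolerance = 1e-12)
})

test_that("overload is reported as unstable, not solved", {
  scn <- baseline_scenario(c1 = 5L)
  scn$arrival_rates <- scn$arrival_rates * 10
  rep <- solve_scenario(scn, find_roots = FALSE)
  expect_identical(rep$status, "unstable")
  expect_null(rep$waits)
})

test_that("per-class service overrides feed the aggregate rate", {
  svc <- c(rep(list(tri_dist(0.2, 0.8, 1.6)), 3),
           rep(list(tri_dist(0.05, 0.15, 0.4)), 2))
  scn <- scenario(baseline_rates, lambda_direct = baseline_direct,
                  transfer_fraction = baseline_x, ed_service = svc,
                  iu_los = tri_dist(1, 4, 7, "days"), c1 = 20, c2 = 125)
  rep <- solve_scenario(scn, find_roots = FALSE)
  q <- baseline_rates / sum(baseline_rates)
  means <- vapply(svc, function(d) dist_moments(d)$mean, numeric(1))
  expect_equal(rep$mu1, 1 / sum(q * means), tolerance = 1e-9)
  expect_identical(rep$status, "ok")
})

test_that("converged waits fall as either bed pool grows", {
  scn <- fast_track_premise_scenario(3.8)
  waits_c1 <- vapply(c(18L, 20L, 23L, 26L), function(c1) {
    scn$c1 <- c1
    attr(solve_scenario(scn, find_roots = FALSE)$waits,
         "aggregate_queueing_delay")
  }, numeric(1))
  expect_true(all(diff(waits_c1) < 0))

  tight <- baseline_scenario(c1 = 6L)
  waits_c2 <- vapply(c(73L, 76L, 85L, 125L), function(c2) {
    tight$c2 <- c2
    attr(solve_scenario(tight, find_roots = FALSE)$waits,
         "aggregate_queueing_delay")
  }, numeric(1))
  expect_true(all(diff(waits_c2) <= 1e-12))
})
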