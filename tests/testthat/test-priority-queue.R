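test_that("Pollaczek-Khinchine delay reduces to M/M/1 and M/D/1", {
  expect_equal(wq_mg1_fcfs(0, 1, 2), 0)
  expect_equal(wq_mg1_fcfs(0.5, 1, 2), 1)      # exponential: rho/(1-rho) * S
  expect_equal(wq_mg1_fcfs(0.5, 1, 1), 0.5)    # deterministic: half of M/M/1
  expect_error(wq_mg1_fcfs(1, 1, 2), "unstable")
})

test_that("Erlang C matches its closed form and a brute-force sum", {
  expect_equal(erlang_c(1, 0.4, 1), 0.4)       # c = 1: busy probability rho
  expect_equal(erlang_c(2, 1, 1), 1 / 3)
  expect_equal(erlang_c(5, 0, 1), 0)
  expect_error(erlang_c(2, 2, 1), "unstable")

  # independent oracle: truncated series with the geometric tail in closed
  # form, evaluated term by term
  brute <- function(c, a) {
    rho <- a / c
    tail <- a^c / (factorial(c) * (1 - rho))
    tail / (sum(a^(0:(c - 1)) / factorial(0:(c - 1))) + tail)
  }
  for (c in c(2, 5, 12)) for (rho in c(0.2, 0.6, 0.9))
    expect_equal(erlang_c(c, rho * c, 1), brute(c, rho * c),
                 tolerance = 1e-12)
})

test_that("FCFS M/G/c value reproduces exact M/M/1 and M/M/2 sojourns", {
  expect_equal(w_mgc_fcfs(2, 1, 1, 2), 4 / 3)   # = S + P_Q/(c mu - lambda)
  expect_equal(w_mgc_fcfs(1, 0.5, 1, 2), 2)     # = 1/(mu - lambda)
  expect_equal(w_mgc_fcfs(3, 0, 1, 2), 1)       # empty system, exponential
  expect_error(w_mgc_fcfs(2, 3, 1, 2), "unstable")
})

test_that("single-server preemptive-resume times match hand calculations", {
  expect_equal(w_mg1_priority(class_moments(0.5, 1, 2)), 2)
  w <- w_mg1_priority(class_moments(c(0.25, 0.25), c(1, 1), c(2, 2)))
  expect_equal(w, c(4 / 3, 8 / 3), tolerance = 1e-12)
  # work conservation: identical exponential classes average to the
  # single-class sojourn exactly
  expect_equal(sum(0.25 * w) / 0.5, 2, tolerance = 1e-10)
  lam <- c(0.1, 0.2, 0.15, 0.05)
  w4 <- w_mg1_priority(class_moments(lam, rep(1, 4), rep(2, 4)))
  expect_equal(sum(lam * w4) / sum(lam), 1 / (1 - sum(lam)),
               tolerance = 1e-10)
  expect_error(
    w_mg1_priority(class_moments(c(0.5, 0.6), c(1, 1), c(2, 2))),
    "class 2")
})

test_that("class_moments validates its invariants", {
  expect_error(class_moments(c(0.1, -0.2), c(1, 1), c(2, 2)), "rates")
  expect_error(class_moments(0.1, 2, 1), "Jensen")
  cm <- class_moments(c(0.1, 0.2), c(1, 1), c(2, 2))
  expect_equal(cm$label, c("CTAS I", "CTAS II"))
})

test_that("multi-server composition matches the verbatim worked example", {
  w <- w_mgc_priority(2, class_moments(c(0.5, 0.5), c(1, 1), c(2, 2)))
  expect_equal(w$system_time_printed, c(16 / 9, 32 / 9), tolerance = 1e-12)
  expect_equal(attr(w, "Wc1F"), 4 / 3, tolerance = 1e-12)
  expect_equal(attr(w, "W1F"), 1, tolerance = 1e-12)
})

test_that("composition collapses exactly at c = 1 and for a single class", {
  cm <- class_moments(c(0.2, 0.3), c(0.8, 1.2), c(1.2, 3.0))
  w1 <- w_mgc_priority(1, cm)
  expect_equal(w1$system_time, w_mg1_priority(cm), tolerance = 1e-12)
  # first-access delays: R_k / ((1 - sigma_{k-1})(1 - sigma_k))
  r <- cumsum(cm$lambda * cm$s_m2) / 2
  sig <- cumsum(cm$lambda * cm$s_mean)
  expect_equal(w1$queueing_delay, r / (c(1, 1 - sig[1]) * (1 - sig)),
               tolerance = 1e-12)

  one <- class_moments(1.2, 0.9, 1.5)
  w3 <- w_mgc_priority(3, one)
  scv <- 1.5 / 0.81 - 1
  wq_fcfs <- 0.9 * erlang_c(3, 1.2, 0.9) / (3 - 1.08) * (1 + scv) / 2
  expect_equal(w3$queueing_delay, wq_fcfs, tolerance = 1e-12)
})

test_that("waits are priority-ordered and monotone in load and capacity", {
  base <- class_moments(c(0.5, 1, 1.5), rep(0.8, 3), rep(0.9, 3))
  w <- w_mgc_priority(4, base)
  expect_true(all(diff(w$system_time) >= 0))
  expect_true(all(diff(w$queueing_delay) >= 0))
  expect_true(all(w$queueing_delay >= 0))

  # scaling all arrival rates up increases every wait
  for (f in c(1.1, 1.25)) {
    wf <- w_mgc_priority(4, class_moments(base$lambda * f, base$s_mean,
                                          base$s_m2))
    expect_true(all(wf$queueing_delay >= w$queueing_delay - 1e-14))
  }
  # adding servers decreases every wait
  w5 <- w_mgc_priority(5, base)
  expect_true(all(w5$queueing_delay <= w$queueing_delay + 1e-14))
  expect_true(all(w5$system_time <= w$system_time + 1e-14))
})

test_that("zero traffic and the unscaled option behave as documented", {
  cm0 <- class_moments(c(0, 0), c(1, 1), c(2, 2))
  w0 <- w_mgc_priority(3, cm0)
  expect_equal(w0$queueing_delay, c(0, 0))
  expect_equal(w0$system_time, c(1, 1))

  heavy <- class_moments(c(0.8, 0.8), c(1, 1), c(2, 2))
  expect_error(w_mgc_priority(3, heavy, scaling = "unscaled"), "unscaled")
  light <- class_moments(c(0.2, 0.2), c(1, 1), c(2, 2))
  expect_silent(w_mgc_priority(3, light, scaling = "unscaled"))
})
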