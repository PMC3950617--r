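#' Simulation configuration
#'
#' @param horizon run length, hours.
#' @param warmup initial transient discarded from statistics, hours
#'   (`warmup < horizon`).
#' @param replications number of independent replications (>= 1).
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(horizon = 2000, warmup = 200, replications = 200L,
                       seed = 1L) {
  stopifnot(horizon > 0, warmup >= 0, warmup < horizon, replications >= 1)
  structure(list(horizon = horizon, warmup = warmup,
                 replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "sim_config")
}

dist_par <- function(d) {
  if (inherits(d, "tri_dist")) c(0, d$lower, d$mode, d$upper)
  else if (inherits(d, "exp_dist")) c(1, d$rate, 0, 0)
  else stop("unsupported distribution for simulation")
}

#' Discrete-event simulation of the tandem ED/IU system
#'
#' Event-driven Monte-Carlo simulation of the scenario: Poisson arrivals per
#' acuity class, `c1` ED beds under preemptive-resume priority, transfer to
#' the `c2`-bed IU with probability `x` on ED completion, boarding (bed
#' blocking) when the IU is full, and loss of direct admissions. Boarding
#' patients are not preemptible - their treatment is complete and the bed is
#' physically occupied - a deliberate divergence from the analytic model,
#' which folds boarding into preemptible service time.
#'
#' Overloaded configurations run and are reported as such (waits simply grow
#' with the horizon); nothing is refused.
#'
#' @param scn a [scenario()].
#' @param config a [sim_config()].
#' @return An object of class `sim_result`: `per_class` data frame (mean
#'   queueing delay and system time with 95% CIs, Little's-law diagnostics),
#'   `blocking` (pooled frequency, CI half-width, analytic-free), `util_ed`,
#'   `util_iu`, `preemptions`, `replications`.
#' @export
simulate_scenario <- function(scn, config = sim_config()) {
  stopifnot(inherits(scn, "scenario"), inherits(config, "sim_config"))
  k <- length(scn$arrival_rates)
  svc <- do.call(rbind, lapply(scn$ed_service, dist_par))
  iu <- dist_par(scn$iu_los)

  set.seed(config$seed)
  reps <- lapply(seq_len(config$replications), function(r)
    .sim_core(scn$arrival_rates, svc, iu, scn$c1, scn$c2,
              scn$transfer_fraction, scn$lambda_direct,
              config$horizon, config$warmup))

  mat <- function(field) do.call(rbind, lapply(reps, `[[`, field))
  num <- function(field) vapply(reps, `[[`, numeric(1), field)

  rep_mean <- function(sums, ns) {
    m <- sums / ns
    m[ns == 0] <- NA_real_
    m
  }
  delay_m <- rep_mean(mat("sum_delay"), mat("n_delay"))
  sys_m <- rep_mean(mat("sum_sys"), mat("n_sys"))

  ci <- function(v) {               # mean and 95% t half-width across reps
    v <- v[is.finite(v)]
    n <- length(v)
    if (n == 0) return(c(NA_real_, NA_real_))
    if (n == 1) return(c(v, NA_real_))
    c(mean(v), qt(0.975, n - 1) * sd(v) / sqrt(n))
  }
  dly <- apply(delay_m, 2, ci); sy <- apply(sys_m, 2, ci)

  span <- config$horizon - config$warmup
  lam_eff <- colMeans(mat("n_arrivals")) / span
  l_avg <- colMeans(mat("area_L")) / span

  per_class <- data.frame(
    class = seq_len(k), label = scn$labels,
    queueing_delay = dly[1, ], delay_ci = dly[2, ],
    system_time = sy[1, ], system_ci = sy[2, ],
    lambda_eff = lam_eff, L_time_avg = l_avg,
    little_LW = lam_eff * sy[1, ])

  blocked <- sum(num("transfer_blocked")) + sum(num("direct_lost"))
  attempts <- sum(num("transfer_attempts")) + sum(num("direct_attempts"))
  p_block <- if (attempts > 0) blocked / attempts else 0
  # per-rep frequencies for a replication CI; rule-of-three binomial bound
  # covers the zero-observation case
  rep_freq <- (num("transfer_blocked") + num("direct_lost")) /
    pmax(1, num("transfer_attempts") + num("direct_attempts"))
  bl_ci <- ci(rep_freq)[2]
  rule3 <- if (attempts > 0) 3 / attempts else NA_real_

  structure(list(per_class = per_class,
                 blocking = list(freq = p_block, ci_halfwidth = bl_ci,
                                 attempts = attempts, blocked = blocked,
                                 rule_of_three = rule3),
                 util_ed = mean(num("area_ed")) / (span * scn$c1),
                 util_iu = mean(num("area_iu")) / (span * scn$c2),
                 preemptions = mean(num("preemptions")),
                 replications = config$replications,
                 config = config, scenario = scn),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulation: %d replications, horizon %g h (warmup %g h)\n",
              x$replications, x$config$horizon, x$config$warmup))
  print.data.frame(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("IU blocking frequency %.4g (+/- %.2g); util ED %.3f, IU %.3f; %.1f preemptions/rep\n",
              x$blocking$freq,
              if (is.na(x$blocking$ci_halfwidth)) NaN else x$blocking$ci_halfwidth,
              x$util_ed, x$util_iu, x$preemptions))
  invisible(x)
}

#' Side-by-side analytic vs simulated estimates
#'
#' Runs [solve_scenario()] and [simulate_scenario()] on the same scenario
#' and tabulates per-class queueing delays and system times plus the IU
#' blocking probability, with relative errors.
#'
#' @param scn a [scenario()].
#' @param config a [sim_config()].
#' @return An object of class `comparison_table` (a data frame with one row
#'   per class plus summary rows for the aggregate wait and the blocking
#'   probability), with attributes `analytic` and `sim` carrying the full
#'   reports.
#' @export
compare_analytic_sim <- function(scn, config = sim_config()) {
  an <- solve_scenario(scn, find_roots = FALSE)
  sm <- simulate_scenario(scn, config)
  if (is.null(an$waits))
    stop("compare_analytic_sim: analytic solve not stable (status ",
         an$status, ")")
  rel <- function(a, s) ifelse(a > 0, abs(s - a) / a, ifelse(s == 0, 0, NA))
  rows <- data.frame(
    quantity = c(paste0("delay[", scn$labels, "]"), "aggregate_delay", "p_b"),
    analytic = c(an$waits$queueing_delay,
                 attr(an$waits, "aggregate_queueing_delay"), an$p_b$p_b),
    simulated = c(sm$per_class$queueing_delay,
                  sum(sm$per_class$lambda_eff * sm$per_class$queueing_delay) /
                    sum(sm$per_class$lambda_eff),
                  sm$blocking$freq))
  rows$rel_err <- rel(rows$analytic, rows$simulated)
  structure(rows, class = c("comparison_table", "data.frame"),
            analytic = an, sim = sm)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("analytic vs simulated (hours / probability):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
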