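#' Scenario: full parameterisation of the coupled ED/IU system
#'
#' @param arrival_rates per-acuity Poisson arrival rates, patients/hour,
#'   highest priority first (CTAS I..V for the default five classes).
#' @param lambda_direct arrival rate of direct IU admissions, patients/hour.
#' @param transfer_fraction proportion `x` in `[0, 1]` of ED patients
#'   admitted to the IU on completion of ED treatment.
#' @param ed_service ED treatment-time distribution ([tri_dist()] or
#'   [exp_dist()]), either one shared distribution or a list with one entry
#'   per class.
#' @param iu_los IU length-of-stay distribution.
#' @param c1,c2 ED and IU bed counts (>= 1).
#' @param wait_metric which metric the planner compares against targets:
#'   `"queueing_delay"` (time to first treatment, default) or
#'   `"system_time"`.
#' @param bondi_scaling reference-system option of [w_mgc_priority()].
#' @param residual_life use the stationary-excess transform in [mean_min()].
#' @param labels optional class labels.
#' @param name optional scenario name.
#' @return An object of class `scenario`.
#' @examples
#' scn <- scenario(c(0.075, 0.662, 3.749, 2.86, 0.226),
#'                 lambda_direct = 0.267, transfer_fraction = 0.479 / 7.572,
#'                 ed_service = tri_dist(0.1, 0.5, 1),
#'                 iu_los = tri_dist(1, 4, 7, "days"), c1 = 20, c2 = 125)
#' @export
scenario <- function(arrival_rates, lambda_direct = 0, transfer_fraction,
                     ed_service, iu_los, c1, c2,
                     wait_metric = c("queueing_delay", "system_time"),
                     bondi_scaling = c("scaled", "unscaled"),
                     residual_life = FALSE, labels = NULL, name = NULL) {
  wait_metric <- match.arg(wait_metric)
  bondi_scaling <- match.arg(bondi_scaling)
  if (any(arrival_rates < 0)) stop("scenario: arrival rates must be >= 0")
  if (lambda_direct < 0) stop("scenario: lambda_direct must be >= 0")
  if (transfer_fraction < 0 || transfer_fraction > 1)
    stop("scenario: transfer_fraction must lie in [0, 1]")
  check_count(c1, "c1"); check_count(c2, "c2")
  k <- length(arrival_rates)
  if (inherits(ed_service, "ed_dist")) {
    ed_service <- rep(list(ed_service), k)
    shared <- TRUE
  } else {
    stopifnot(is.list(ed_service), length(ed_service) == k,
              all(vapply(ed_service, inherits, logical(1), "ed_dist")))
    shared <- FALSE
  }
  stopifnot(inherits(iu_los, "ed_dist"))
  if (is.null(labels)) {
    roman <- c("I", "II", "III", "IV", "V")
    labels <- if (k <= 5L) paste("CTAS", roman[seq_len(k)])
              else paste("class", seq_len(k))
  }
  structure(list(arrival_rates = as.numeric(arrival_rates),
                 lambda_direct = lambda_direct,
                 transfer_fraction = transfer_fraction,
                 ed_service = ed_service, shared_service = shared,
                 iu_los = iu_los, c1 = as.integer(c1), c2 = as.integer(c2),
                 wait_metric = wait_metric, bondi_scaling = bondi_scaling,
                 residual_life = residual_life, labels = labels,
                 name = name),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("ED/IU scenario", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat(sprintf("  ED: c1 = %d beds, lambda = %.4g /h (%s)\n", x$c1,
              sum(x$arrival_rates),
              paste(signif(x$arrival_rates, 4), collapse = ", ")))
  cat(sprintf("  IU: c2 = %d beds, direct %.4g /h, transfer fraction %.4g\n",
              x$c2, x$lambda_direct, x$transfer_fraction))
  invisible(x)
}

# raw (uncoupled) per-class service moments of a scenario
scenario_raw_moments <- function(scn) {
  mom <- lapply(scn$ed_service, dist_moments)
  class_moments(scn$arrival_rates,
                vapply(mom, `[[`, numeric(1), "mean"),
                vapply(mom, `[[`, numeric(1), "second_moment"),
                labels = scn$labels)
}

# aggregate uncoupled service rate mu_1 = 1 / sum(q_k S_k)
scenario_mu1 <- function(scn) {
  raw <- scenario_raw_moments(scn)
  lam <- sum(raw$lambda)
  if (lam == 0) return(1 / dist_moments(scn$ed_service[[1]])$mean)
  1 / sum(raw$lambda / lam * raw$s_mean)
}

# IU-side constants of a scenario
scenario_iu <- function(scn) {
  m <- dist_moments(scn$iu_los)
  list(mu_I = 1 / m$mean, scv = m$scv,
       mean_min = mean_min(scn$iu_los, scn$c2,
                           residual = scn$residual_life))
}

scenario_blocking <- function(scn, lambda_transfer, iu = scenario_iu(scn)) {
  blocking_probability(iu_load(scn$c2, iu$mu_I, lambda_transfer,
                               scn$lambda_direct, iu$scv))
}

#' Boarding-adjusted service moments
#'
#' Inflates the raw ED service moments by the expected boarding delay: with
#' blocking probability `p_b` and expected boarding time `boarding_mean`
#' (the mean time until the next IU departure), the modified mean is
#' `raw_mean + p_b * boarding_mean` and the second moment treats the added
#' term as a deterministic shift:
#' `raw_m2 + 2 raw_mean p_b boarding_mean + (p_b boarding_mean)^2`.
#'
#' @param raw_mean,raw_m2 raw service mean (hours) and second moment
#'   (hours^2), `raw_m2 >= raw_mean^2`.
#' @param p_b blocking probability in `[0, 1]`.
#' @param boarding_mean expected boarding delay, hours.
#' @return A list with elements `mean` and `m2`.
#' @export
modified_moments <- function(raw_mean, raw_m2, p_b, boarding_mean) {
  if (any(c(raw_mean, raw_m2, p_b, boarding_mean) < 0))
    stop("modified_moments: inputs must be non-negative")
  if (any(raw_m2 < raw_mean^2 - 1e-12))
    stop("modified_moments: raw second moment below squared mean")
  shift <- p_b * boarding_mean
  list(mean = raw_mean + shift,
       m2 = raw_m2 + 2 * raw_mean * shift + shift^2)
}

#' Bounds on the effective ED service rate
#'
#' The effective rate `mu` solves `1/mu = 1/mu_1 + P_b * mean_min`. Since
#' `0 <= P_b <= 1`, `mu` is bracketed by the never-blocked best case
#' (`mu_max = mu_1`) and the always-blocked worst case
#' (`mu_min = 1 / (1/mu_1 + mean_min(iu_los, c2))`).
#'
#' @param scn a [scenario()].
#' @return A list with `mu_min`, `mu_max` (1/hours) and the `mean_min`
#'   boarding delay used (hours).
#' @export
mu_bounds <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  mu1 <- scenario_mu1(scn)
  mm <- mean_min(scn$iu_los, scn$c2, residual = scn$residual_life)
  list(mu_min = 1 / (1 / mu1 + mm), mu_max = mu1, mean_min = mm)
}

#' Residual of the service-rate fixed-point equation
#'
#' Evaluates `1/mu - P_b(mu) * mean_min - 1/mu_1` (hours). `P_b(mu)` feeds
#' the IU with the transfer rate `x * R_d` where `R_d = min(lambda, c1 mu)`
#' is the ED throughput at service rate `mu`. A root of this residual is an
#' effective service rate consistent with the blocking it induces.
#'
#' @param mu candidate service rate, 1/hours (> 0).
#' @param scn a [scenario()].
#' @return Residual in hours (vectorised over `mu`).
#' @export
fixed_point_residual <- function(mu, scn) {
  stopifnot(inherits(scn, "scenario"), all(mu > 0))
  iu <- scenario_iu(scn)
  mu1 <- scenario_mu1(scn)
  lam <- sum(scn$arrival_rates)
  vapply(mu, function(m) {
    rd <- min(lam, scn$c1 * m)
    pb <- scenario_blocking(scn, scn$transfer_fraction * rd, iu)$p_b
    1 / m - pb * iu$mean_min - 1 / mu1
  }, numeric(1))
}

#' Enumerate roots of the fixed-point equation
#'
#' Evaluates the residual on a uniform grid over `[mu_min, mu_max]`, bisects
#' every sign-change bracket down to `|residual| < tol`, and additionally
#' accepts grid points whose residual is already below `tol` (the uncoupled
#' limit `P_b ~ 0` produces a root at the bracket end without a sign
#' change). At least one root exists because the residual is continuous,
#' `>= 0` at `mu_min` and `<= 0` at `mu_max`; an empty root list is reported
#' as a status rather than silently patched.
#'
#' @param scn a [scenario()].
#' @param grid_n grid size (>= 2), default 512.
#' @param tol residual tolerance, hours.
#' @return An object of class `fixed_point_result`: `mu_min`, `mu_max`,
#'   sorted `roots`, `residuals`, `mu_hat_min`, `mu_hat_max`, the
#'   `feasibility` verdicts (`sufficient_met`, `necessary_met`,
#'   `necessary_and_sufficient_exists`) and `status`.
#' @export
find_mu_roots <- function(scn, grid_n = 512L, tol = 1e-10) {
  stopifnot(inherits(scn, "scenario"))
  if (grid_n < 2L) stop("find_mu_roots: grid_n must be >= 2")
  bounds <- mu_bounds(scn)
  iu <- scenario_iu(scn)
  mu1 <- bounds$mu_max
  lam <- sum(scn$arrival_rates)
  resid <- function(m) {
    rd <- min(lam, scn$c1 * m)
    pb <- scenario_blocking(scn, scn$transfer_fraction * rd, iu)$p_b
    1 / m - pb * iu$mean_min - 1 / mu1
  }

  grid <- seq(bounds$mu_min, bounds$mu_max, length.out = grid_n)
  fg <- vapply(grid, resid, numeric(1))

  roots <- grid[abs(fg) < tol]
  for (i in seq_len(grid_n - 1L)) {
    if (sign(fg[i]) * sign(fg[i + 1L]) < 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      flo <- fg[i]
      for (iter in 1:200) {
        mid <- (lo + hi) / 2
        fm <- resid(mid)
        if (abs(fm) < tol || (hi - lo) < .Machine$double.eps * mid) break
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      roots <- c(roots, mid)
    }
  }
  roots <- sort(unique(roots))
  # collapse numerically duplicate roots
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-9 * max(roots))
    roots <- roots[keep]
  }
  residuals <- vapply(roots, resid, numeric(1))

  status <- if (length(roots) == 0L) "no_root_found" else "ok"
  mu_hat_min <- if (length(roots)) min(roots) else NA_real_
  mu_hat_max <- if (length(roots)) max(roots) else NA_real_

  feas <- if (length(roots)) {
    iu_rate_at <- function(m) scn$transfer_fraction * min(lam, scn$c1 * m) +
      scn$lambda_direct
    list(sufficient_met = lam <= scn$c1 * mu_hat_min &&
           iu_rate_at(mu_hat_min) <= scn$c2 * iu$mu_I,
         necessary_met = lam <= scn$c1 * mu_hat_max &&
           iu_rate_at(mu_hat_max) <= scn$c2 * iu$mu_I,
         necessary_and_sufficient_exists =
           (mu_hat_max - mu_hat_min) <= max(tol, 1e-9 * mu_hat_max))
  } else {
    list(sufficient_met = NA, necessary_met = NA,
         necessary_and_sufficient_exists = NA)
  }

  structure(list(mu_min = bounds$mu_min, mu_max = bounds$mu_max,
                 mean_min = bounds$mean_min, roots = roots,
                 residuals = residuals, mu_hat_min = mu_hat_min,
                 mu_hat_max = mu_hat_max, feasibility = feas,
                 status = status),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat(sprintf("fixed point: %d root(s) in [%.6g, %.6g] /h\n",
              length(x$roots), x$mu_min, x$mu_max))
  if (length(x$roots))
    cat("  mu_hat:", paste(signif(x$roots, 8), collapse = ", "), "\n")
  cat(sprintf("  sufficient: %s | necessary: %s | nec&suff exists: %s\n",
              x$feasibility$sufficient_met, x$feasibility$necessary_met,
              x$feasibility$necessary_and_sufficient_exists))
  invisible(x)
}

#' Solve the coupled ED/IU system
#'
#' Moment iteration: starting from `P_b = 0`, repeatedly (i) inflate the
#' per-class service moments by the boarding term ([modified_moments()]),
#' (ii) aggregate `1/mu = sum q_k S_k` with `q_k = lambda_k / lambda`,
#' (iii) recompute the ED throughput `R_d = min(lambda, c1 mu)` and the
#' blocking probability it induces, until the largest change in any modified
#' class mean drops below `tol` (default 1e-8 hours) or `max_iter` is hit.
#' If the plain iteration oscillates it is restarted with 0.5 damping on
#' `P_b`. The converged moments feed [w_mgc_priority()].
#'
#' @param scn a [scenario()].
#' @param tol convergence tolerance on the modified class means, hours.
#' @param max_iter iteration cap.
#' @param find_roots also run [find_mu_roots()] and attach the result.
#' @return An object of class `solution_report`: `status`
#'   (`"ok"`, `"unstable"` or `"no_solution"`), `converged`, `iterations`,
#'   `mu_hat`, `mu1`, `mean_min`, `p_b` (a `blocking_result`),
#'   `iu_stable`, `modified_moments`, `waits` (NULL when unstable) and
#'   optionally `fixed_point`.
#' @export
solve_scenario <- function(scn, tol = 1e-8, max_iter = 1000L,
                           find_roots = TRUE) {
  stopifnot(inherits(scn, "scenario"))
  lam <- sum(scn$arrival_rates)
  if (lam <= 0) stop("solve_scenario: total ED arrival rate must be > 0")
  raw <- scenario_raw_moments(scn)
  q <- raw$lambda / lam
  iu <- scenario_iu(scn)
  mu1 <- 1 / sum(q * raw$s_mean)

  if (lam >= scn$c1 * mu1) {
    # certain instability: even with no blocking at all the ED cannot keep up
    rd <- min(lam, scn$c1 * mu1)
    pb <- scenario_blocking(scn, scn$transfer_fraction * rd, iu)
    mod <- modified_moments(raw$s_mean, raw$s_m2, pb$p_b, iu$mean_min)
    return(structure(
      list(status = "unstable", converged = FALSE, iterations = 0L,
           mu_hat = 1 / sum(q * mod$mean), mu1 = mu1,
           mean_min = iu$mean_min, p_b = pb,
           iu_stable = scn$transfer_fraction * rd + scn$lambda_direct <=
             scn$c2 * iu$mu_I,
           modified_moments = class_moments(raw$lambda, mod$mean, mod$m2,
                                            labels = raw$label),
           waits = NULL,
           fixed_point = if (find_roots) find_mu_roots(scn) else NULL,
           scenario = scn),
      class = "solution_report"))
  }

  iterate <- function(damping) {
    pb <- 0
    s_bar_prev <- raw$s_mean
    diffs <- numeric(0)
    for (it in seq_len(max_iter)) {
      mod <- modified_moments(raw$s_mean, raw$s_m2, pb, iu$mean_min)
      d <- max(abs(mod$mean - s_bar_prev))
      diffs <- c(diffs, d)
      s_bar_prev <- mod$mean
      mu <- 1 / sum(q * mod$mean)
      rd <- min(lam, scn$c1 * mu)
      pb_new <- scenario_blocking(scn, scn$transfer_fraction * rd, iu)$p_b
      pb <- damping * pb_new + (1 - damping) * pb
      if (it > 1 && d < tol)
        return(list(converged = TRUE, iterations = it, mu = mu, pb = pb,
                    moments = mod, oscillating = FALSE))
    }
    # oscillation heuristic: the step size stopped shrinking
    n <- length(diffs)
    osc <- n >= 10 && diffs[n] > 0.5 * max(diffs[max(1, n - 10):n])
    list(converged = FALSE, iterations = max_iter, mu = mu, pb = pb,
         moments = mod, oscillating = osc)
  }

  res <- iterate(damping = 1)
  if (!res$converged && res$oscillating) res <- iterate(damping = 0.5)

  pb_final <- scenario_blocking(
    scn, scn$transfer_fraction * min(lam, scn$c1 * res$mu), iu)
  mod_cm <- class_moments(raw$lambda, res$moments$mean, res$moments$m2,
                          labels = raw$label)
  iu_stable <- scn$transfer_fraction * min(lam, scn$c1 * res$mu) +
    scn$lambda_direct <= scn$c2 * iu$mu_I

  status <- if (!res$converged) "no_solution"
            else if (lam >= scn$c1 * res$mu) "unstable"
            else "ok"
  waits <- NULL
  if (status == "ok")
    waits <- w_mgc_priority(scn$c1, mod_cm, scaling = scn$bondi_scaling)

  structure(list(status = status, converged = res$converged,
                 iterations = res$iterations, mu_hat = res$mu, mu1 = mu1,
                 mean_min = iu$mean_min, p_b = pb_final,
                 iu_stable = iu_stable, modified_moments = mod_cm,
                 waits = waits,
                 fixed_point = if (find_roots) find_mu_roots(scn) else NULL,
                 scenario = scn),
            class = "solution_report")
}

#' @export
print.solution_report <- function(x, ...) {
  cat(sprintf("ED/IU solution [status: %s, %d iteration(s)]\n",
              x$status, x$iterations))
  cat(sprintf("  mu_hat = %.6g /h (mu1 = %.6g), P_b = %.4g, E[boarding|blocked] = %.4g h\n",
              x$mu_hat, x$mu1, x$p_b$p_b, x$mean_min))
  if (!x$iu_stable) cat("  WARNING: IU necessary stability condition violated\n")
  if (!is.null(x$waits)) print(x$waits)
  invisible(x)
}
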