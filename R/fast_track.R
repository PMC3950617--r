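#' Fast-track configuration
#'
#' A fast track carves a share of the ED beds into an express line serving
#' the two lowest-acuity classes (CTAS IV-V); the remaining beds form the
#' regular line (CTAS I-III). Both lines feed the same IU and therefore see
#' the same blocking probability.
#'
#' @param fraction share of ED beds allocated to the fast track, in (0, 1).
#' @param literal_sum_constraint if `TRUE`, the two lines' uncoupled service
#'   rates are constrained to sum to the base rate (`mu_1^I + mu_1^II =
#'   mu_1`), split proportionally to bed share; the default gives both lines
#'   the base service-time distribution unchanged.
#' @return An object of class `fast_track_config`.
#' @export
fast_track_config <- function(fraction, literal_sum_constraint = FALSE) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L)
  if (fraction <= 0 || fraction >= 1)
    stop("fast_track_config: fraction must lie strictly in (0, 1)")
  structure(list(fraction = fraction,
                 literal_sum_constraint = isTRUE(literal_sum_constraint)),
            class = "fast_track_config")
}

round_half_away <- function(x) floor(x + 0.5)

#' Split a scenario into fast-track and regular lines
#'
#' CTAS IV-V go to the fast line on `round(fraction * c1)` beds
#' (round-half-away-from-zero), CTAS I-III keep the remainder. Both lines
#' inherit the IU parameters and the transfer fraction; the direct-admission
#' stream belongs to the shared IU and is carried on both line scenarios.
#'
#' @param scn a five-class [scenario()].
#' @param config a [fast_track_config()].
#' @return A list with elements `fast` and `regular` (both [scenario()]s).
#' @export
split_scenario <- function(scn, config) {
  stopifnot(inherits(scn, "scenario"), inherits(config, "fast_track_config"))
  k <- length(scn$arrival_rates)
  if (k != 5L)
    stop("split_scenario: fast-track routing is defined for five classes")
  c1_fast <- round_half_away(config$fraction * scn$c1)
  c1_reg <- scn$c1 - c1_fast
  if (c1_fast < 1L || c1_reg < 1L)
    stop("split_scenario: fraction ", config$fraction, " leaves a line with ",
         "no beds (split ", c1_fast, "/", c1_reg, " of ", scn$c1, ")")
  line_scn <- function(idx, beds, share, tag) {
    svc <- scn$ed_service[idx]
    if (config$literal_sum_constraint)
      svc <- lapply(svc, dist_scale, factor = 1 / share)
    scenario(scn$arrival_rates[idx], lambda_direct = scn$lambda_direct,
             transfer_fraction = scn$transfer_fraction, ed_service = svc,
             iu_los = scn$iu_los, c1 = beds, c2 = scn$c2,
             wait_metric = scn$wait_metric, bondi_scaling = scn$bondi_scaling,
             residual_life = scn$residual_life, labels = scn$labels[idx],
             name = paste(c(scn$name, tag), collapse = " "))
  }
  list(fast = line_scn(4:5, c1_fast, c1_fast / scn$c1, "(fast track)"),
       regular = line_scn(1:3, c1_reg, c1_reg / scn$c1, "(regular line)"))
}

#' Solve several ED lines coupled through one shared IU
#'
#' Generalisation of [solve_scenario()]'s moment iteration to an arbitrary
#' partition of the acuity classes over parallel ED lines: all lines share
#' one blocking probability, whose IU transfer rate sums every line's
#' throughput contribution `x * min(lambda_l, c_l mu_l)`. With a single line
#' holding all classes and all beds this reproduces [solve_scenario()]
#' exactly.
#'
#' @param scn the base [scenario()] (IU parameters, rates, labels).
#' @param class_sets list of integer vectors partitioning the classes.
#' @param beds integer vector of per-line bed counts.
#' @param service optional list (parallel to `class_sets`) of per-line lists
#'   of service distributions; defaults to the base scenario's.
#' @param tol,max_iter iteration controls as in [solve_scenario()].
#' @return A list with `p_b` (shared `blocking_result`), `mu_hat` per line,
#'   `reports` (per-line `solution_report`-like lists), `converged`,
#'   `iterations`, `status`.
#' @export
solve_split <- function(scn, class_sets, beds, service = NULL,
                        tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(scn, "scenario"), length(class_sets) == length(beds))
  iu <- scenario_iu(scn)
  nline <- length(class_sets)
  if (is.null(service)) service <- lapply(class_sets,
                                          function(i) scn$ed_service[i])
  raw <- lapply(seq_len(nline), function(l) {
    mom <- lapply(service[[l]], dist_moments)
    class_moments(scn$arrival_rates[class_sets[[l]]],
                  vapply(mom, `[[`, numeric(1), "mean"),
                  vapply(mom, `[[`, numeric(1), "second_moment"),
                  labels = scn$labels[class_sets[[l]]])
  })
  lam_l <- vapply(raw, function(r) sum(r$lambda), numeric(1))
  if (any(lam_l <= 0))
    stop("solve_split: every line needs a positive arrival rate")

  pb <- 0
  prev <- lapply(raw, `[[`, "s_mean")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mods <- lapply(raw, function(r)
      modified_moments(r$s_mean, r$s_m2, pb, iu$mean_min))
    d <- max(vapply(seq_len(nline), function(l)
      max(abs(mods[[l]]$mean - prev[[l]])), numeric(1)))
    prev <- lapply(mods, `[[`, "mean")
    mu_l <- vapply(seq_len(nline), function(l)
      1 / sum(raw[[l]]$lambda / lam_l[l] * mods[[l]]$mean), numeric(1))
    rd <- sum(pmin(lam_l, beds * mu_l))
    pb <- scenario_blocking(scn, scn$transfer_fraction * rd, iu)$p_b
    if (it > 1 && d < tol) { converged <- TRUE; break }
  }
  pb_final <- scenario_blocking(scn, scn$transfer_fraction *
                                  sum(pmin(lam_l, beds * mu_l)), iu)

  reports <- lapply(seq_len(nline), function(l) {
    cm <- class_moments(raw[[l]]$lambda, mods[[l]]$mean, mods[[l]]$m2,
                        labels = raw[[l]]$label)
    stable <- lam_l[l] < beds[l] * mu_l[l]
    waits <- if (converged && stable)
      w_mgc_priority(beds[l], cm, scaling = scn$bondi_scaling) else NULL
    list(beds = beds[l], lambda = lam_l[l], mu_hat = mu_l[l],
         stable = stable, modified_moments = cm, waits = waits,
         status = if (!converged) "no_solution"
                  else if (!stable) "unstable" else "ok")
  })
  status <- if (!converged) "no_solution"
            else if (any(!vapply(reports, `[[`, logical(1), "stable")))
              paste0("unstable: ",
                     paste(which(!vapply(reports, `[[`, logical(1), "stable")),
                           collapse = ", "))
            else "ok"
  list(p_b = pb_final, mu_hat = mu_l, reports = reports,
       converged = converged, iterations = it, status = status)
}

#' Solve the fast-track system
#'
#' Splits the scenario with [split_scenario()], solves both lines jointly
#' with one shared blocking probability ([solve_split()]), and aggregates
#' the two line averages with the arrival-share weights (`P_r^I` regular,
#' `P_r^II` fast, summing to one).
#'
#' @param scn a five-class [scenario()].
#' @param config a [fast_track_config()].
#' @return An object of class `fast_track_solution`: `fast_line` and
#'   `regular_line` reports, shared `p_b`, weights `p_regular`/`p_fast`,
#'   `aggregate_wait` (in the scenario's wait metric),
#'   `aggregate_system_time`, `mu_fast`, `mu_regular`, `mu_aggregate` and
#'   `status`.
#' @export
solve_fast_track <- function(scn, config) {
  split <- split_scenario(scn, config)   # validates the bed split
  c1_fast <- split$fast$c1; c1_reg <- split$regular$c1
  joint <- solve_split(scn, class_sets = list(1:3, 4:5),
                       beds = c(c1_reg, c1_fast),
                       service = list(split$regular$ed_service,
                                      split$fast$ed_service))
  reg <- joint$reports[[1]]; fast <- joint$reports[[2]]
  lam <- sum(scn$arrival_rates)
  p_reg <- reg$lambda / lam; p_fast <- fast$lambda / lam

  line_avg <- function(rep, what) {
    if (is.null(rep$waits)) return(NA_real_)
    attr(rep$waits, paste0("aggregate_", what))
  }
  metric <- scn$wait_metric
  agg_wait <- p_reg * line_avg(reg, metric) + p_fast * line_avg(fast, metric)
  agg_sys <- p_reg * line_avg(reg, "system_time") +
    p_fast * line_avg(fast, "system_time")
  mu_agg <- p_reg * joint$mu_hat[1] + p_fast * joint$mu_hat[2]

  structure(list(fast_line = fast, regular_line = reg, p_b = joint$p_b,
                 p_regular = p_reg, p_fast = p_fast,
                 aggregate_wait = agg_wait, aggregate_system_time = agg_sys,
                 mu_fast = joint$mu_hat[2], mu_regular = joint$mu_hat[1],
                 mu_aggregate = mu_agg, converged = joint$converged,
                 iterations = joint$iterations, status = joint$status,
                 config = config, scenario = scn),
            class = "fast_track_solution")
}

#' @export
print.fast_track_solution <- function(x, ...) {
  cat(sprintf("fast-track solution [status: %s]\n", x$status))
  cat(sprintf("  beds: %d fast / %d regular; weights P_r = %.4g regular, %.4g fast\n",
              x$fast_line$beds, x$regular_line$beds, x$p_regular, x$p_fast))
  cat(sprintf("  shared P_b = %.4g; aggregate %s = %.5g h\n",
              x$p_b$p_b, x$scenario$wait_metric, x$aggregate_wait))
  invisible(x)
}
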