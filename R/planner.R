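#' Per-acuity wait-time targets
#'
#' Maximum acceptable wait to first physician assessment per acuity level,
#' in minutes. Defaults follow the CTAS guideline ladder with the
#' resuscitation level set to 3 minutes (a finite stand-in for
#' "immediate").
#'
#' @param minutes numeric vector of per-class targets, strictly increasing
#'   from the highest-acuity class down.
#' @return An object of class `wait_targets`.
#' @export
wait_targets <- function(minutes = c(3, 15, 30, 60, 120)) {
  stopifnot(is.numeric(minutes), length(minutes) >= 1L, all(minutes > 0))
  if (any(diff(minutes) <= 0))
    stop("wait_targets: targets must be strictly increasing across levels")
  structure(list(minutes = minutes), class = "wait_targets")
}

#' Compare estimated waits against targets
#'
#' @param waits a `wait_estimates` object (from [w_mgc_priority()] or a
#'   solved report's `$waits`).
#' @param targets a [wait_targets()].
#' @param metric `"queueing_delay"` (default; time to first treatment) or
#'   `"system_time"`.
#' @return A data frame with one row per class (`label`, `wait_min`,
#'   `target_min`, `pass`) and attribute `overall` (all classes pass).
#' @export
meets_targets <- function(waits, targets,
                          metric = c("queueing_delay", "system_time")) {
  metric <- match.arg(metric)
  stopifnot(inherits(waits, "wait_estimates"), inherits(targets, "wait_targets"))
  k <- nrow(waits)
  if (length(targets$minutes) != k)
    stop("meets_targets: ", k, " classes but ", length(targets$minutes),
         " targets")
  wait_min <- waits[[metric]] * 60
  out <- data.frame(class = waits$class, label = waits$label,
                    wait_min = wait_min, target_min = targets$minutes,
                    pass = wait_min < targets$minutes)
  attr(out, "overall") <- all(out$pass)
  out
}

# shared scan for the two min_* searches
scan_capacity <- function(scn, targets, set_beds, start, cap, metric) {
  for (n in start:cap) {
    rep <- try(solve_scenario(set_beds(scn, n), find_roots = FALSE),
               silent = TRUE)
    if (inherits(rep, "try-error")) next
    if (rep$status != "ok" || !rep$iu_stable) next
    verdict <- meets_targets(rep$waits, targets, metric)
    if (attr(verdict, "overall"))
      return(list(capacity = n, status = "ok", report = rep,
                  verdict = verdict))
  }
  list(capacity = NA_integer_, status = "infeasible", report = NULL,
       verdict = NULL)
}

#' Smallest ED bed count meeting the targets
#'
#' Linear scan upward from the ED stability floor `ceiling(lambda / mu_1)`:
#' the first `c1` for which the coupled solve is stable, converged and every
#' class meets its target. A scan (rather than bisection) is used because
#' solver status need not be monotone immediately around instability.
#'
#' @param scn a [scenario()] with `c2` fixed.
#' @param targets a [wait_targets()].
#' @param cap largest `c1` tried before declaring infeasibility.
#' @param metric wait metric; defaults to the scenario's `wait_metric`.
#' @return A list with `capacity` (bed count, NA when infeasible), `status`,
#'   the passing `report` and its target `verdict`.
#' @export
min_ed_capacity <- function(scn, targets = wait_targets(), cap = 500L,
                            metric = NULL) {
  stopifnot(inherits(scn, "scenario"))
  metric <- metric %||% scn$wait_metric
  lam <- sum(scn$arrival_rates)
  start <- max(1L, ceiling(lam / scenario_mu1(scn)))
  scan_capacity(scn, targets,
                function(s, n) { s$c1 <- as.integer(n); s }, start, cap,
                metric)
}

#' Smallest IU bed count meeting the targets
#'
#' Same scan contract as [min_ed_capacity()], over `c2` with `c1` fixed.
#' Starts at 1: the IU stability frontier depends on the converged transfer
#' flow, so no tighter a-priori floor is imposed.
#'
#' @inheritParams min_ed_capacity
#' @export
min_iu_capacity <- function(scn, targets = wait_targets(), cap = 500L,
                            metric = NULL) {
  stopifnot(inherits(scn, "scenario"))
  metric <- metric %||% scn$wait_metric
  scan_capacity(scn, targets,
                function(s, n) { s$c2 <- as.integer(n); s }, 1L, cap, metric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply one sweep point to a scenario
sweep_modify <- function(scn, var, value) {
  switch(var,
         c2 = { scn$c2 <- as.integer(value); scn },
         iu_los_mean = {
           f <- value / dist_moments(scn$iu_los)$mean
           scn$iu_los <- dist_scale(scn$iu_los, f)
           scn
         },
         lambda_scale = {
           scn$arrival_rates <- scn$arrival_rates * value
           scn
         },
         stop("unknown sweep variable: ", var))
}

#' Capacity tradeoff sweep
#'
#' Runs [min_ed_capacity()] or [min_iu_capacity()] over a grid of one swept
#' quantity: the IU size (`c2`), the mean IU length of stay in hours
#' (`iu_los_mean`, rescaling the LOS distribution), or a multiplier on the
#' ED arrival rates (`lambda_scale`). Per-point failures are recorded and
#' the sweep continues.
#'
#' @param scn base [scenario()].
#' @param targets a [wait_targets()].
#' @param var one of `"c2"`, `"iu_los_mean"`, `"lambda_scale"`.
#' @param values grid values for `var`.
#' @param free which capacity to search: `"ed"` or `"iu"`.
#' @param cap scan cap per point.
#' @return An object of class `capacity_curve`: a data frame with columns
#'   `sweep_value`, `required_capacity`, `status`.
#' @export
tradeoff_sweep <- function(scn, targets = wait_targets(),
                           var = c("c2", "iu_los_mean", "lambda_scale"),
                           values, free = c("ed", "iu"), cap = 500L) {
  var <- match.arg(var); free <- match.arg(free)
  stopifnot(length(values) >= 1L)
  if (var == "c2" && free == "iu")
    stop("tradeoff_sweep: cannot sweep c2 while searching the IU capacity")
  rows <- lapply(values, function(v) {
    s <- sweep_modify(scn, var, v)
    res <- if (free == "ed") min_ed_capacity(s, targets, cap)
           else min_iu_capacity(s, targets, cap)
    data.frame(sweep_value = v, required_capacity = res$capacity,
               status = res$status)
  })
  out <- do.call(rbind, rows)
  attr(out, "var") <- var; attr(out, "free") <- free
  class(out) <- c("capacity_curve", "data.frame")
  out
}

#' @export
print.capacity_curve <- function(x, ...) {
  cat(sprintf("capacity curve: required %s beds vs %s\n",
              attr(x, "free"), attr(x, "var")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.capacity_curve <- function(x, ...) {
  plot(x$sweep_value, x$required_capacity, type = "b", pch = 19,
       xlab = attr(x, "var"),
       ylab = paste("required", attr(x, "free"), "beds"), ...)
  invisible(x)
}
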