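#' Per-priority arrival rates and service moments
#'
#' Container for the inputs of the multi-priority waiting-time chain: one row
#' per priority class, class 1 being the highest priority (it preempts all
#' others). The acuity labels (CTAS I..V by default) are carried alongside so
#' reports can print clinical labels regardless of the internal class order.
#'
#' @param lambda arrival rates per class, patients/hour (class 1 first).
#' @param s_mean mean service times per class, hours.
#' @param s_m2 second moments of service time per class, hours^2; must
#'   satisfy `s_m2 >= s_mean^2` (Jensen).
#' @param labels optional class labels; defaults to `CTAS I` ... in order.
#' @return A `class_moments` data frame with columns `class`, `label`,
#'   `lambda`, `s_mean`, `s_m2`.
#' @export
class_moments <- function(lambda, s_mean, s_m2, labels = NULL) {
  k <- length(lambda)
  stopifnot(k >= 1L, length(s_mean) == k, length(s_m2) == k)
  if (any(lambda < 0)) stop("class_moments: arrival rates must be >= 0")
  if (any(s_mean < 0)) stop("class_moments: service means must be >= 0")
  if (any(s_m2 < s_mean^2 - 1e-12))
    stop("class_moments: second moment below squared mean (Jensen violated)")
  if (is.null(labels)) {
    roman <- c("I", "II", "III", "IV", "V")
    labels <- if (k <= 5L) paste("CTAS", roman[seq_len(k)])
              else paste("class", seq_len(k))
  }
  structure(data.frame(class = seq_len(k), label = labels, lambda = lambda,
                       s_mean = s_mean, s_m2 = s_m2,
                       stringsAsFactors = FALSE),
            class = c("class_moments", "data.frame"))
}

#' Mean queueing delay of an M/G/1 FCFS queue
#'
#' Pollaczek-Khinchine formula `W = lambda * S2 / (2 (1 - rho))` with
#' `rho = lambda * s_mean`.
#'
#' @param lambda arrival rate (1/hours).
#' @param s_mean mean service time (hours).
#' @param s_m2 second moment of service time (hours^2).
#' @return Mean time in queue, hours.
#' @export
wq_mg1_fcfs <- function(lambda, s_mean, s_m2) {
  rho <- lambda * s_mean
  if (rho >= 1)
    stop("wq_mg1_fcfs: unstable, rho = ", signif(rho, 4), " >= 1")
  if (lambda == 0) return(0)
  lambda * s_m2 / (2 * (1 - rho))
}

#' Erlang-C delay probability
#'
#' Probability that all `c` servers of an M/M/c queue are busy, computed via
#' the Erlang-B recurrence (`C = c B / (c - a (1 - B))`), which is stable for
#' large `c`. The infinite tail of the defining sum is a geometric series and
#' is accounted for exactly.
#'
#' @param c server count (>= 1).
#' @param lambda arrival rate (1/hours).
#' @param s_mean mean service time (hours).
#' @return Delay probability in `[0, 1]`.
#' @export
erlang_c <- function(c, lambda, s_mean) {
  check_count(c, "c")
  a <- lambda * s_mean
  if (a < 0) stop("erlang_c: negative offered load")
  if (a == 0) return(0)
  if (a >= c) stop("erlang_c: unstable, offered load ", signif(a, 4),
                   " >= c = ", c)
  b <- erlang_b(c, a)
  c * b / (c - a * (1 - b))
}

#' FCFS M/G/c waiting-time approximation
#'
#' The c-server FCFS reference value
#' `[S + S * P_Q / (c - lambda S)] * (1 + C^2) / 2`, where `P_Q` is the
#' Erlang-C delay probability at offered load `lambda S` and `C^2` the SCV of
#' the service time. For exponential service this reproduces the exact M/M/c
#' mean sojourn time (e.g. `S + P_Q/(c mu - lambda)` for c = 1, 2), so the
#' returned quantity is a time-in-system-like value, not a pure queueing
#' delay; see [w_mgc_priority()] for how the two metrics are separated.
#'
#' @inheritParams erlang_c
#' @param s_m2 second moment of service time (hours^2).
#' @return Approximate mean time in system, hours.
#' @export
w_mgc_fcfs <- function(c, lambda, s_mean, s_m2) {
  check_count(c, "c")
  a <- lambda * s_mean
  if (a >= c) stop("w_mgc_fcfs: unstable, offered load ", signif(a, 4),
                   " >= c = ", c)
  if (lambda == 0 || s_mean == 0) {
    scv1 <- if (s_mean > 0) s_m2 / s_mean^2 - 1 else 0
    return(s_mean * (1 + scv1) / 2)
  }
  pq <- erlang_c(c, lambda, s_mean)
  scv <- s_m2 / s_mean^2 - 1
  (s_mean + s_mean * pq / (c - a)) * (1 + scv) / 2
}

#' Preemptive-resume priority M/G/1 per-class times
#'
#' Classical single-server preemptive-resume formula. For class `k` (class 1
#' highest priority), with `rho_k = lambda_k * s_mean_k`,
#' `sigma_k = rho_1 + ... + rho_k` and
#' `R_k = (1/2) sum_{i <= k} lambda_i * s_m2_i`:
#' \deqn{W_1^1 = \frac{(1-\rho_1) S_1 + R_1}{1-\rho_1}, \qquad
#'       W_1^k = \frac{(1-\sigma_k) S_k + R_k}{(1-\sigma_{k-1})(1-\sigma_k)}}
#' These are per-class mean times in system (for a single exponential class
#' the formula reduces to the M/M/1 sojourn `1/(mu - lambda)`).
#'
#' @param classes a [class_moments()] object.
#' @return Numeric vector of per-class mean times in system, hours.
#' @export
w_mg1_priority <- function(classes) {
  stopifnot(inherits(classes, "class_moments"))
  lam <- classes$lambda; s <- classes$s_mean; s2 <- classes$s_m2
  rho <- lam * s
  sigma <- cumsum(rho)
  if (any(sigma >= 1)) {
    first <- which(sigma >= 1)[1]
    stop("w_mg1_priority: unstable at class ", first, " (",
         classes$label[first], "): cumulative load ",
         signif(sigma[first], 4), " >= 1")
  }
  r <- cumsum(lam * s2) / 2
  k <- length(lam)
  w <- numeric(k)
  w[1] <- ((1 - sigma[1]) * s[1] + r[1]) / (1 - sigma[1])
  if (k > 1) {
    for (j in 2:k) {
      w[j] <- ((1 - sigma[j]) * s[j] + r[j]) /
        ((1 - sigma[j - 1]) * (1 - sigma[j]))
    }
  }
  w
}

#' Per-class waits in the preemptive-resume M/G/c queue
#'
#' Heuristic c-server scaling of the single-server priority solution:
#' \deqn{W_{c}^k \approx W_{c}^F \, W_1^k / W_1^F} where `W_c^F` is the FCFS
#' M/G/c value ([w_mgc_fcfs()]), `W_1^k` the single-server priority value
#' ([w_mg1_priority()]) and `W_1^F` the single-server FCFS queueing delay
#' ([wq_mg1_fcfs()]).
#'
#' Under the default `scaling = "scaled"` the single-server reference
#' quantities are evaluated with every class arrival rate divided by `c`,
#' which preserves the class mix and the per-server load and keeps the
#' reference system stable whenever the c-server system is.
#' `scaling = "unscaled"` uses the raw rates (a literal reading of the
#' composition) and is only defined while `lambda * S < 1`.
#'
#' Two metric conventions exist for the three ingredients: `W_1^F` is a pure
#' queueing delay while `W_c^F` and `W_1^k` as written are
#' time-in-system-like. Composing them verbatim mixes metrics and diverges
#' as traffic vanishes (the denominator delay goes to zero while the
#' numerators tend to the mean service time). The reported metrics therefore
#' compose like with like, with `Wq_c^F = S P_Q/(c - \lambda S) (1+C^2)/2`
#' (the delay part of the FCFS c-server value) as the c-server scale factor:
#'
#' * `queueing_delay`: time until first treatment,
#'   `Wq_c^F * A_1^k / W_1^F`, where `A_1^k = R_k / ((1-\sigma_{k-1})
#'   (1-\sigma_k))` is the exact single-server preemptive-resume delay until
#'   a class-k patient first reaches the server (lower-priority work is
#'   invisible to it).
#' * `system_time`: `s_mean + Wq_c^F * (W_1^k - S_k) / W_1^F`, the sojourn
#'   including later preemption interruptions.
#'
#' At `c = 1` these reduce exactly to the single-server priority values, and
#' for a single class the delay reduces exactly to the FCFS delay - the two
#' collapse identities the mixed-metric form violates. The verbatim
#' mixed-metric composition is retained as the diagnostic column
#' `system_time_printed`.
#'
#' @param c server (bed) count.
#' @param classes a [class_moments()] object (moments already adjusted for
#'   boarding where applicable).
#' @param scaling `"scaled"` (default) or `"unscaled"`.
#' @return A `wait_estimates` data frame with per-class `system_time` and
#'   `queueing_delay` (hours) plus attributes `W1F`, `Wc1F`, `P_Q`,
#'   `aggregate_system_time` and `aggregate_queueing_delay`
#'   (lambda-weighted means).
#' @export
w_mgc_priority <- function(c, classes, scaling = c("scaled", "unscaled")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(classes, "class_moments"))
  check_count(c, "c")
  lam_tot <- sum(classes$lambda)

  if (lam_tot == 0) {                       # empty system
    out <- data.frame(class = classes$class, label = classes$label,
                      lambda = classes$lambda,
                      system_time = classes$s_mean,
                      queueing_delay = 0,
                      system_time_printed = classes$s_mean)
    return(wait_estimates(out, W1F = 0, Wc1F = 0, P_Q = 0))
  }

  q <- classes$lambda / lam_tot
  s_agg <- sum(q * classes$s_mean)
  s2_agg <- sum(q * classes$s_m2)
  if (lam_tot * s_agg >= c)
    stop("w_mgc_priority: unstable, offered load ",
         signif(lam_tot * s_agg, 4), " >= c = ", c)

  pq <- erlang_c(c, lam_tot, s_agg)
  wcf <- w_mgc_fcfs(c, lam_tot, s_agg, s2_agg)

  div <- if (scaling == "scaled") c else 1
  if (scaling == "unscaled" && lam_tot * s_agg >= 1)
    stop("w_mgc_priority: unscaled reference M/G/1 system unstable ",
         "(lambda * S = ", signif(lam_tot * s_agg, 4), " >= 1)")
  ref <- class_moments(classes$lambda / div, classes$s_mean, classes$s_m2,
                       labels = classes$label)
  w1f <- wq_mg1_fcfs(lam_tot / div, s_agg, s2_agg)
  w1k <- w_mg1_priority(ref)

  scv <- s2_agg / s_agg^2 - 1
  wq_c <- s_agg * pq / (c - lam_tot * s_agg) * (1 + scv) / 2
  # single-server reference quantities at the scaled rates
  sigma <- cumsum(ref$lambda * ref$s_mean)
  r_k <- cumsum(ref$lambda * ref$s_m2) / 2
  access1 <- r_k / ((1 - c(0, sigma[-length(sigma)])) * (1 - sigma))
  intr1 <- pmax(0, w1k - classes$s_mean)    # delay incl. interruptions
  delay <- if (w1f > 0) wq_c * access1 / w1f else rep(0, length(w1k))
  sys_t <- classes$s_mean +
    (if (w1f > 0) wq_c * intr1 / w1f else rep(0, length(w1k)))
  printed <- if (w1f > 0) wcf * w1k / w1f else classes$s_mean
  out <- data.frame(class = classes$class, label = classes$label,
                    lambda = classes$lambda,
                    system_time = sys_t,
                    queueing_delay = delay,
                    system_time_printed = printed)
  wait_estimates(out, W1F = w1f, Wc1F = wcf, P_Q = pq)
}

wait_estimates <- function(df, W1F, Wc1F, P_Q) {
  lam_tot <- sum(df$lambda)
  agg_sys <- if (lam_tot > 0) sum(df$lambda * df$system_time) / lam_tot else 0
  agg_dly <- if (lam_tot > 0) sum(df$lambda * df$queueing_delay) / lam_tot else 0
  structure(df, class = c("wait_estimates", "data.frame"),
            W1F = W1F, Wc1F = Wc1F, P_Q = P_Q,
            aggregate_system_time = agg_sys,
            aggregate_queueing_delay = agg_dly)
}

#' @export
print.wait_estimates <- function(x, ...) {
  cat("Per-class wait estimates (hours):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat(sprintf("aggregate: system time %.5g h, queueing delay %.5g h\n",
              attr(x, "aggregate_system_time"),
              attr(x, "aggregate_queueing_delay")))
  invisible(x)
}
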