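#' Offered load on the inpatient unit
#'
#' Bundles the parameters of the downstream G/GI/c2/c2 loss system: bed
#' count, service (length-of-stay) rate, the two arrival streams (transfers
#' from the ED and direct admissions), and the squared coefficient of
#' variation of the length of stay.
#'
#' @param c2 IU bed count (>= 1).
#' @param mu_I IU service rate, 1/hours (> 0): reciprocal of the mean length
#'   of stay.
#' @param lambda_transfer ED-to-IU transfer rate `x * R_d`, patients/hour.
#' @param lambda_direct direct admission rate, patients/hour.
#' @param scv_service squared coefficient of variation of the length of stay
#'   (>= 0).
#' @return An object of class `iu_load`.
#' @export
iu_load <- function(c2, mu_I, lambda_transfer, lambda_direct = 0,
                    scv_service = 1) {
  check_count(c2, "c2")
  if (!is.numeric(mu_I) || mu_I <= 0) stop("iu_load: mu_I must be > 0")
  if (lambda_transfer < 0 || lambda_direct < 0)
    stop("iu_load: arrival rates must be >= 0")
  if (scv_service < 0) stop("iu_load: scv_service must be >= 0")
  structure(list(c2 = as.integer(c2), mu_I = mu_I,
                 lambda_transfer = lambda_transfer,
                 lambda_direct = lambda_direct,
                 scv_service = scv_service),
            class = "iu_load")
}

#' Blocking probability of the inpatient loss system
#'
#' Diffusion approximation for the probability that an admission (transfer or
#' direct) finds all `c2` IU beds occupied:
#' \deqn{P_b = \frac{\alpha\beta e^{-k\beta/v}}{(1 - e^{-k\beta/v})\,
#'       \rho_d \sqrt{c_2}}}
#' with per-bed offered load \eqn{\rho_d = (\lambda_{transfer} +
#' \lambda_{direct})/(c_2 \mu_I)}, \eqn{\beta = \sqrt{c_2}(1-\rho_d)},
#' \eqn{k = \sqrt{c_2}}, \eqn{v = (1 + C_a^2)/2} and
#' \eqn{\alpha = [1 + \beta\Phi(\beta)/\phi(\beta)]^{-1}}, where \eqn{C_a^2}
#' is the SCV of the length of stay and \eqn{\Phi,\phi} are the standard
#' normal CDF and PDF. At \eqn{\beta = 0} (critically loaded IU) the 0/0 is
#' resolved by the analytic limit \eqn{\alpha v/(c_2 \rho_d)}.
#'
#' The raw formula can leave `[0, 1]` at extreme loads; the reported `p_b` is
#' clamped to the unit interval (the steady-state analysis assumes
#' `0 <= P_b <= 1`) and the unclamped value kept for diagnostics. An offered
#' load above one bed-hour per bed-hour (`rho_d > 1`) is permitted - the
#' feasibility search must be able to evaluate such points - and flagged.
#'
#' @param load an [iu_load()].
#' @return An object of class `blocking_result`: `p_b` (clamped), `p_b_raw`,
#'   `rho_d`, `beta`, `k`, `v`, `alpha`, and the `overloaded` flag.
#' @export
blocking_probability <- function(load) {
  stopifnot(inherits(load, "iu_load"))
  c2 <- load$c2
  lam <- load$lambda_transfer + load$lambda_direct
  rho_d <- lam / (c2 * load$mu_I)
  k <- sqrt(c2)
  v <- (1 + load$scv_service) / 2
  beta <- sqrt(c2) * (1 - rho_d)

  if (rho_d == 0) {                       # no traffic: never blocked
    return(structure(list(p_b = 0, p_b_raw = 0, rho_d = 0, beta = beta,
                          k = k, v = v, alpha = NA_real_, overloaded = FALSE),
                     class = "blocking_result"))
  }

  alpha <- blocking_alpha(beta)
  if (abs(beta) < 1e-6) {                 # analytic beta -> 0 limit
    raw <- alpha * v / (c2 * rho_d)
  } else {
    e <- exp(-k * beta / v)
    raw <- if (is.infinite(e)) {
      # beta << 0: e/(1-e) -> -1, so the formula tends to alpha*|beta|/(rho_d*k)
      alpha * (-beta) / (rho_d * k)
    } else {
      alpha * beta * e / ((1 - e) * rho_d * k)
    }
  }
  structure(list(p_b = min(1, max(0, raw)), p_b_raw = raw, rho_d = rho_d,
                 beta = beta, k = k, v = v, alpha = alpha,
                 overloaded = rho_d > 1),
            class = "blocking_result")
}

# alpha(beta) = 1 / (1 + beta * Phi(beta) / phi(beta)), with asymptotic
# handling where dnorm underflows (|beta| > ~38)
blocking_alpha <- function(beta) {
  ph <- dnorm(beta)
  if (ph > 0) return(1 / (1 + beta * pnorm(beta) / ph))
  if (beta > 0) 0 else beta^2             # Mills ratio: beta*Phi/phi ~ -1 + 1/beta^2
}

#' @export
print.blocking_result <- function(x, ...) {
  cat(sprintf("IU blocking: p_b = %.6g (raw %.6g), rho_d = %.4g, beta = %.4g%s\n",
              x$p_b, x$p_b_raw, x$rho_d, x$beta,
              if (isTRUE(x$overloaded)) " [overloaded]" else ""))
  invisible(x)
}

#' Erlang-B loss probability
#'
#' Exact blocking probability of an M/M/c/c loss system, via the stable
#' recurrence `B(0) = 1`, `B(j) = a B(j-1) / (j + a B(j-1))`. Used as a
#' classical sanity oracle for the diffusion approximation.
#'
#' @param c server count (>= 1).
#' @param offered_load offered load `a` in erlangs (>= 0).
#' @return Loss probability in `[0, 1]`.
#' @export
erlang_b <- function(c, offered_load) {
  check_count(c, "c")
  if (offered_load < 0) stop("erlang_b: offered_load must be >= 0")
  if (offered_load == 0) return(0)
  b <- 1
  for (j in seq_len(c)) b <- offered_load * b / (j + offered_load * b)
  b
}
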