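#' Triangular distribution
#'
#' Three-parameter triangular distribution used for the ED treatment time and
#' the IU length of stay. Parameters may be given in hours or days; they are
#' converted to hours at construction, the single canonical time unit of the
#' package.
#'
#' @param lower,mode,upper distribution parameters, `0 <= lower <= mode <= upper`.
#'   A degenerate distribution (`lower == mode == upper`) is allowed.
#' @param unit `"hours"` (default) or `"days"`.
#' @return An object of class `tri_dist`.
#' @examples
#' ed <- tri_dist(0.1, 0.5, 1)        # ED treatment time, hours
#' los <- tri_dist(1, 4, 7, "days")   # IU length of stay
#' dist_moments(los)$mean             # 96 hours
#' @export
tri_dist <- function(lower, mode, upper, unit = c("hours", "days")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(lower), is.numeric(mode), is.numeric(upper),
            length(lower) == 1L, length(mode) == 1L, length(upper) == 1L)
  if (lower < 0) stop("tri_dist: 'lower' must be >= 0")
  if (!(lower <= mode && mode <= upper))
    stop("tri_dist: need lower <= mode <= upper (got ",
         lower, ", ", mode, ", ", upper, ")")
  f <- if (unit == "days") 24 else 1
  structure(list(lower = lower * f, mode = mode * f, upper = upper * f),
            class = c("tri_dist", "ed_dist"))
}

#' Exponential distribution
#'
#' Mainly a test hook: substituting `exp_dist` for a triangular service time
#' turns the analytic chain and the simulator into the classical M/M/c system
#' with known closed forms.
#'
#' @param rate rate parameter (1/hours), > 0.
#' @return An object of class `exp_dist`.
#' @export
exp_dist <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(rate = rate), class = c("exp_dist", "ed_dist"))
}

#' @export
print.tri_dist <- function(x, ...) {
  cat(sprintf("triangular(lower = %g, mode = %g, upper = %g) [hours]\n",
              x$lower, x$mode, x$upper))
  invisible(x)
}

#' @export
print.exp_dist <- function(x, ...) {
  cat(sprintf("exponential(rate = %g /hour)\n", x$rate))
  invisible(x)
}

#' First two moments of a service-time distribution
#'
#' @param dist a `tri_dist` or `exp_dist`.
#' @return A list with `mean` (hours), `second_moment` (hours^2),
#'   `variance` (hours^2) and `scv` (squared coefficient of variation,
#'   dimensionless; 0 for a degenerate distribution).
#' @export
dist_moments <- function(dist) UseMethod("dist_moments")

#' @export
dist_moments.tri_dist <- function(dist) {
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  mu <- (a + m + b) / 3
  v <- (a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18
  list(mean = mu, second_moment = v + mu^2, variance = v,
       scv = if (mu > 0) v / mu^2 else 0)
}

#' @export
dist_moments.exp_dist <- function(dist) {
  mu <- 1 / dist$rate
  list(mean = mu, second_moment = 2 * mu^2, variance = mu^2, scv = 1)
}

#' Cumulative distribution function
#'
#' @param dist a `tri_dist` or `exp_dist`.
#' @param z vector of evaluation points (hours).
#' @return `P(T <= z)`, vectorised over `z`.
#' @export
dist_cdf <- function(dist, z) UseMethod("dist_cdf")

#' @export
dist_cdf.tri_dist <- function(dist, z) {
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  if (b == a) return(as.numeric(z >= a))   # degenerate: unit step
  p <- numeric(length(z))
  lo <- z > a & z < m
  hi <- z >= m & z < b
  if (m > a) p[lo] <- (z[lo] - a)^2 / ((b - a) * (m - a))
  if (b > m) p[hi] <- 1 - (b - z[hi])^2 / ((b - a) * (b - m))
  if (b == m) p[z >= m & z < b] <- 1       # unreachable, kept for clarity
  p[z >= b] <- 1
  p
}

#' @export
dist_cdf.exp_dist <- function(dist, z) {
  ifelse(z <= 0, 0, 1 - exp(-dist$rate * z))
}

#' Quantile function
#'
#' @param dist a `tri_dist` or `exp_dist`.
#' @param u probabilities in `[0, 1]`.
#' @return Quantiles in hours, vectorised over `u`.
#' @export
dist_quantile <- function(dist, u) UseMethod("dist_quantile")

#' @export
dist_quantile.tri_dist <- function(dist, u) {
  stopifnot(all(u >= 0 & u <= 1))
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  if (b == a) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' @export
dist_quantile.exp_dist <- function(dist, u) {
  stopifnot(all(u >= 0 & u <= 1))
  -log(1 - u) / dist$rate
}

#' Random draws
#'
#' @param dist a `tri_dist` or `exp_dist`.
#' @param n number of draws (>= 0).
#' @param seed optional integer; when supplied the stream is seeded so the
#'   same seed always yields the same draws.
#' @return A numeric vector of `n` draws (hours).
#' @export
dist_sample <- function(dist, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  dist_quantile(dist, runif(n))
}

#' CDF of the minimum of independent components
#'
#' For component CDF values `F_i` evaluated at a common point, the CDF of the
#' minimum is `1 - prod(1 - F_i)`.
#'
#' @param cdf_values vector of probabilities in `[0, 1]`.
#' @return The minimum-order-statistic CDF value.
#' @export
min_order_cdf <- function(cdf_values) {
  if (length(cdf_values) < 1L)
    stop("min_order_cdf: need at least one component")
  if (any(cdf_values < 0 | cdf_values > 1))
    stop("min_order_cdf: CDF values must lie in [0, 1]")
  1 - prod(1 - cdf_values)
}

# closed-form integral of the triangular survival function on [0, z],
# needed for the equilibrium (residual-life) transform
tri_survival_integral <- function(dist, z) {
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  ba <- b - a; ma <- m - a; bm <- b - m
  piece <- function(zz) {
    if (zz <= a) return(zz)
    out <- a
    if (ma > 0) {
      z1 <- min(zz, m)
      out <- out + (z1 - a) - (z1 - a)^3 / (3 * ba * ma)
    }
    if (zz > m && bm > 0) {
      z2 <- min(zz, b)
      out <- out + (bm^3 - (b - z2)^3) / (3 * ba * bm)
    }
    out
  }
  vapply(z, piece, numeric(1))
}

#' Expected time until the first of several concurrent stays ends
#'
#' Mean of the minimum of `c2` iid draws from `dist`: the expected boarding
#' delay of a blocked transfer, i.e. the mean time until the next of the
#' `c2` occupied IU beds is vacated. Computed by adaptive quadrature of the
#' survival form `E[min] = lower + int (1 - F(z))^c2 dz`.
#'
#' With `residual = TRUE` the component law is first replaced by its
#' stationary-excess (residual-life) transform, modelling inspection of the
#' beds at a random time rather than at the start of each stay. The plain
#' form is the default.
#'
#' @param dist a `tri_dist` or `exp_dist` (the length-of-stay law).
#' @param c2 number of occupied beds (>= 1).
#' @param residual use the stationary-excess transform of `dist`.
#' @param abs_tol absolute quadrature tolerance in hours.
#' @return Expected minimum, hours.
#' @export
mean_min <- function(dist, c2, residual = FALSE, abs_tol = 1e-8) {
  UseMethod("mean_min")
}

#' @export
mean_min.tri_dist <- function(dist, c2, residual = FALSE, abs_tol = 1e-8) {
  check_count(c2, "c2")
  a <- dist$lower; b <- dist$upper
  if (b == a) return(a)                    # degenerate stay length
  if (!residual) {
    surv <- function(z) (1 - dist_cdf(dist, z))^c2
    a + integrate(surv, a, b, abs.tol = abs_tol,
                  subdivisions = 500L)$value
  } else {
    mu <- dist_moments(dist)$mean
    surv_e <- function(z) (1 - tri_survival_integral(dist, z) / mu)^c2
    integrate(surv_e, 0, b, abs.tol = abs_tol, subdivisions = 500L)$value
  }
}

#' @export
mean_min.exp_dist <- function(dist, c2, residual = FALSE, abs_tol = 1e-8) {
  check_count(c2, "c2")
  # memoryless: the residual transform is the distribution itself,
  # and the minimum of c2 iid exponentials is exponential with rate c2*rate
  1 / (c2 * dist$rate)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x < 1 || x != floor(x))
    stop(name, " must be a positive integer (got ", deparse(x), ")")
  invisible(x)
}

# scale a distribution by a positive factor (used when sweeping the mean LOS)
dist_scale <- function(dist, factor) UseMethod("dist_scale")
#' @export
dist_scale.tri_dist <- function(dist, factor) {
  stopifnot(factor > 0)
  structure(list(lower = dist$lower * factor, mode = dist$mode * factor,
                 upper = dist$upper * factor),
            class = class(dist))
}
#' @export
dist_scale.exp_dist <- function(dist, factor) {
  stopifnot(factor > 0)
  structure(list(rate = dist$rate / factor), class = class(dist))
}
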