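# Emission distributions: gamma step lengths parameterised by (mean, SD)
# and von Mises turning angles. No circular-statistics package is assumed;
# the von Mises density and the Best-Fisher sampler are implemented here.

#' Gamma (mean, SD) to (shape, rate) conversion
#'
#' Moment matching: `shape = mean^2/sd^2`, `rate = mean/sd^2`.
#'
#' @param mean,sd Gamma mean and standard deviation (> 0).
#' @return List with `shape` and `rate`.
#' @export
gamma_shape_rate <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' von Mises log density
#'
#' `log f(x) = kappa*cos(x - mu) - log(2*pi*I0(kappa))`, computed with the
#' exponentially scaled Bessel function so large concentrations stay finite.
#' `kappa = 0` gives the circular uniform density `1/(2*pi)`.
#'
#' @param x Angles (radians).
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Log density values.
#' @export
dvonmises_log <- function(x, mu, kappa) {
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  kappa * cos(x - mu) - log(2 * pi) - log_i0
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' circular uniform. Uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi) + mu * 0))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      out[need[ok]] <- theta
      need <- need[!ok]
    }
  }
  wrap_angle(out + mu)
}

#' Circular mean of a sample of angles
#'
#' @param x Angles (radians), `NA`s removed.
#' @return Mean direction in `(-pi, pi]`, or `NA` if empty.
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  wrap_angle(atan2(mean(sin(x)), mean(cos(x))))
}
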