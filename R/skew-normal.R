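# Skew-normal numerics: SN(xi, omega, alpha) with CDF
#   F(x) = Phi(z) - 2 T(z, alpha),  z = (x - xi) / omega,
# where T is Owen's T function. alpha = 0 recovers Normal(xi, omega).

# Gauss-Legendre rule on [0, 1], fixed at load time. The Owen integrand is
# analytic on the reduced range |a| <= 1, so 64 nodes are far below 1e-14.
.owen_gl <- local({
  rule <- NULL
  function() {
    if (is.null(rule)) rule <<- pracma::gaussLegendre(64, 0, 1)
    rule
  }
})

#' Delta parameterization of the skew-normal shape
#'
#' Maps the shape parameter \eqn{\alpha} to \eqn{\delta = \alpha / \sqrt{1 +
#' \alpha^2}}, the quantity entering the skew-normal mean and the sampling
#' representation. Odd in \eqn{\alpha}, with \eqn{|\delta| < 1}.
#'
#' @param alpha Numeric vector of shape parameters.
#' @return Numeric vector in (-1, 1).
#' @export
#' @examples
#' delta_of_alpha(c(0, 0.25, -2))
delta_of_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  alpha / sqrt(1 + alpha^2)
}

# Core quadrature for |a| <= 1, vectorized over (h, a) pairs:
# T(h, a) = a/(2 pi) * int_0^1 exp(-h^2 (1 + a^2 t^2) / 2) / (1 + a^2 t^2) dt
.owens_t_small <- function(h, a) {
  gl <- .owen_gl()
  n <- length(h)
  if (n == 0L) return(numeric(0))
  # nodes x columns: n x 64
  at2 <- outer(a^2, gl$x^2)          # a^2 t^2
  num <- exp(-0.5 * h^2 * (1 + at2))
  val <- (num / (1 + at2)) %*% gl$w
  as.numeric(a / (2 * pi) * val)
}

#' Owen's T function
#'
#' Computes \eqn{T(h, a) = \frac{1}{2\pi} \int_0^a \frac{\exp(-h^2 (1 + x^2)/2)}
#' {1 + x^2} \, dx}, the special function appearing in the skew-normal
#' distribution function. Arguments with \eqn{|a| > 1} are reduced to the unit
#' range via the identity
#' \eqn{T(h, a) = \frac{1}{2}[\Phi(h) + \Phi(ah)] - \Phi(h)\Phi(ah) - T(ah, 1/a)}
#' (for \eqn{h, a > 0}); the remaining integral is evaluated by fixed
#' Gauss-Legendre quadrature with absolute error well below 1e-12.
#'
#' @param h,a Numeric vectors (recycled to common length).
#' @return Numeric vector of T(h, a) values.
#' @export
#' @examples
#' owens_t(0, 1)         # arctan(1) / (2*pi) = 1/8
#' owens_t(0.5, 1)       # pnorm(0.5) * (1 - pnorm(0.5)) / 2
owens_t <- function(h, a) {
  stopifnot(is.numeric(h), is.numeric(a), all(is.finite(h)), all(is.finite(a)))
  n <- max(length(h), length(a))
  h <- rep_len(h, n)
  a <- rep_len(a, n)
  # T(-h, a) = T(h, a); T(h, -a) = -T(h, a)
  sgn <- sign(a)
  h0 <- abs(h)
  a0 <- abs(a)
  out <- numeric(n)
  small <- a0 <= 1
  if (any(small)) out[small] <- .owens_t_small(h0[small], a0[small])
  if (any(!small)) {
    hh <- h0[!small]
    aa <- a0[!small]
    ah <- aa * hh
    out[!small] <- 0.5 * (stats::pnorm(hh) + stats::pnorm(ah)) -
      stats::pnorm(hh) * stats::pnorm(ah) - .owens_t_small(ah, 1 / aa)
  }
  sgn * out
}

#' Skew-normal distribution function
#'
#' CDF of SN(\eqn{\xi}, \eqn{\omega}, \eqn{\alpha}):
#' \eqn{F(x) = \Phi(z) - 2 T(z, \alpha)} with \eqn{z = (x - \xi)/\omega}.
#'
#' @param x Numeric vector of quantiles.
#' @param xi Location parameter.
#' @param omega Scale parameter (> 0).
#' @param alpha Shape parameter; 0 gives the normal CDF.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
skew_normal_cdf <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  p <- stats::pnorm(z) - 2 * owens_t(z, alpha)
  pmin(pmax(p, 0), 1)
}

#' Skew-normal density
#'
#' @inheritParams skew_normal_cdf
#' @return Numeric vector of density values.
#' @export
skew_normal_pdf <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Sample from the skew-normal distribution
#'
#' Draws via the convolution representation
#' \eqn{X = \xi + \omega(\delta |Z_0| + \sqrt{1 - \delta^2} Z_1)} with
#' independent standard normals \eqn{Z_0, Z_1} and
#' \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}. Exact (no accept-reject), so the
#' draw count per call is deterministic, which keeps seeded substreams aligned.
#'
#' @param n Number of draws.
#' @inheritParams skew_normal_cdf
#' @return Numeric vector of n draws.
#' @export
skew_normal_sample <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0, n >= 0)
  d <- delta_of_alpha(alpha)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  xi + omega * (d * abs(z0) + sqrt(1 - d^2) * z1)
}

#' Mean of the skew-normal distribution
#'
#' \eqn{E[X] = \xi + \omega \delta \sqrt{2/\pi}}.
#'
#' @inheritParams skew_normal_cdf
#' @return Numeric scalar (or vector, if parameters are vectors).
#' @export
#' @examples
#' skew_normal_mean(xi = 0, omega = 3, alpha = 0.25)  # ~0.58, rounds to 0.6
skew_normal_mean <- function(xi = 0, omega = 1, alpha = 0) {
  stopifnot(all(omega > 0))
  xi + omega * delta_of_alpha(alpha) * sqrt(2 / pi)
}

# Scale parameter omega that would give standard deviation sigma at shape
# alpha; the alternative reading of the item scale rule (see
# population_config(scale_rule = "sd")).
.omega_from_sd <- function(sigma, alpha) {
  d <- delta_of_alpha(alpha)
  sigma / sqrt(1 - 2 * d^2 / pi)
}
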