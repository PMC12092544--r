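# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Owen's T and the normal CDF are evaluated by
# adaptive quadrature of their defining integrals, expectations by numerical
# integration, and distributions by Monte Carlo where stated.

# Owen's T by adaptive quadrature of the defining integral (a >= 0).
oracle_owens_t <- function(h, a) {
  sign(a) * stats::integrate(function(x) exp(-h^2 * (1 + x^2) / 2) / (1 + x^2),
                             0, abs(a), rel.tol = 1e-13)$value / (2 * pi)
}

# Standard normal CDF by quadrature of the density.
oracle_normal_cdf <- function(z) {
  stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), -Inf, z,
                   rel.tol = 1e-13)$value
}

# E[logistic(X)] for X ~ Normal(mu, sigma), by quadrature.
oracle_mean_logistic_normal <- function(mu, sigma) {
  stats::integrate(function(x) stats::plogis(x) * stats::dnorm(x, mu, sigma),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

# Skew-normal mean by quadrature of x * pdf(x), built from the density
# formula directly (not the package pdf).
oracle_sn_mean <- function(xi, omega, alpha) {
  stats::integrate(function(x) {
    z <- (x - xi) / omega
    x * 2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
  }, -Inf, Inf, rel.tol = 1e-12)$value
}

# Kolmogorov distance between a sample and a CDF.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# Hand-built person rows with prescribed transformed parameters, for tests
# that pin expertise/change tendency exactly.
fixed_person <- function(expertise, change_tendency, id = "fx") {
  data.frame(person_id = paste0(id, seq_along(expertise)),
             latent_expertise = stats::qlogis(expertise),
             expertise = expertise,
             latent_change_tendency = stats::qlogis(change_tendency),
             change_tendency = change_tendency,
             stringsAsFactors = FALSE)
}

fixed_item <- function(truth = 0, difficulty = 1, skewness = 0, bias = 0,
                       id = "it") {
  n <- max(length(truth), length(difficulty), length(skewness), length(bias))
  data.frame(item_id = paste0(id, seq_len(n)),
             truth = rep_len(truth, n), difficulty = rep_len(difficulty, n),
             skewness = rep_len(skewness, n), bias = rep_len(bias, n),
             stringsAsFactors = FALSE)
}
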