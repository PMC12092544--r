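# Individual-level generative model of sequential collaboration.
#
# A contributor i holds, for item k, an internal distribution of plausible
# values. Independent judgments are draws from the baseline distribution
#   Y_ik ~ Normal(mean = T_k, sd = D_k * E_i)
# (or its skew-normal / biased-normal variants), where T_k is the correct
# answer, D_k the item difficulty, and E_i in (0, 1) the logistic-transformed
# expertise -- smaller E_i means HIGHER expertise (tighter distribution).
#
# When a judgment y is presented, the contributor adjusts it with probability
#   P = G_i + (1 - G_i) * 4 * (F(y) - 1/2)^2,
# F being the baseline CDF and G_i in (0, 1) the personal change tendency
# (the floor of P). If they adjust, the revised judgment is drawn from the
# updated distribution, whose mean is shifted toward the presented judgment
# by the anchoring term A = E_i * (y - T_k) and whose scale is shrunk by the
# frame-of-reference factor R <= 1.

# Latent values are clamped here before the logistic so transformed
# parameters never round to exactly 0 or 1 (which would zero a scale).
.LATENT_CLAMP <- 50

#' Logistic (inverse logit) transform
#'
#' @param x Numeric vector; must be finite.
#' @return 1 / (1 + exp(-x)), strictly increasing, in (0, 1).
#' @export
logistic <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  1 / (1 + exp(-x))
}

#' Population configuration for the generative model
#'
#' Hyperparameters of the person and item populations plus the distribution
#' family of plausible values.
#'
#' Persons: latent expertise is Normal(0, `sigma_latent_expertise`) and latent
#' change tendency Normal(`mean_latent_change_tendency`,
#' `sigma_latent_change_tendency`); both are pushed through the logistic to
#' (0, 1). The default latent change-tendency mean of -1 encodes the
#' assumption that contributors maintain presented judgments more often than
#' not (baseline change tendency around 0.27).
#'
#' Items: `item_truth` is a single correct answer applied to all items or a
#' vector recycled across items; `item_difficulty` is either a single fixed
#' value or a length-2 vector `c(lower, upper)` giving a Uniform(lower, upper)
#' rule with 0 < lower < upper; `item_skewness` and `item_bias` are fixed
#' values (forced to 0 for the normal family).
#'
#' @param sigma_latent_expertise SD of latent expertise (> 0).
#' @param mean_latent_change_tendency Mean of latent change tendency.
#' @param sigma_latent_change_tendency SD of latent change tendency (> 0).
#' @param reference_factor Frame-of-reference shrinkage R in (0, 1] applied to
#'   the scale of the updated (post-decision) distribution; 1 switches the
#'   effect off.
#' @param family Plausible-value family: `"normal"`, `"skew_normal"`, or
#'   `"biased_normal"`.
#' @param item_truth Correct answer(s) T_k.
#' @param item_difficulty Fixed difficulty or `c(lower, upper)` uniform rule.
#' @param item_skewness Fixed skewness S_k (skew_normal family).
#' @param item_bias Fixed bias B_k (biased_normal family).
#' @param scale_rule How the item scale enters the skew-normal: `"omega"`
#'   (default) uses D_k * E_i directly as the scale parameter omega;
#'   `"sd"` instead treats D_k * E_i as the distribution's standard deviation
#'   and derives omega from it. Provided for sensitivity checks.
#' @return An object of class `population_config` (a validated list).
#' @export
population_config <- function(sigma_latent_expertise = 1,
                              mean_latent_change_tendency = -1,
                              sigma_latent_change_tendency = 1,
                              reference_factor = 0.4,
                              family = c("normal", "skew_normal", "biased_normal"),
                              item_truth = 0,
                              item_difficulty = c(1, 5),
                              item_skewness = 0,
                              item_bias = 0,
                              scale_rule = c("omega", "sd")) {
  family <- match.arg(family)
  scale_rule <- match.arg(scale_rule)
  stopifnot(
    is.numeric(sigma_latent_expertise), length(sigma_latent_expertise) == 1,
    sigma_latent_expertise > 0,
    is.numeric(sigma_latent_change_tendency), sigma_latent_change_tendency > 0,
    is.numeric(mean_latent_change_tendency), is.finite(mean_latent_change_tendency),
    is.numeric(reference_factor), reference_factor > 0, reference_factor <= 1,
    is.numeric(item_truth), all(is.finite(item_truth)),
    is.numeric(item_skewness), length(item_skewness) == 1, is.finite(item_skewness),
    is.numeric(item_bias), length(item_bias) == 1, is.finite(item_bias)
  )
  if (length(item_difficulty) == 2) {
    if (item_difficulty[1] <= 0)
      stop("item_difficulty lower bound must be > 0")
    if (item_difficulty[1] >= item_difficulty[2])
      stop("item_difficulty uniform rule requires lower < upper")
  } else if (length(item_difficulty) == 1) {
    if (item_difficulty <= 0) stop("item_difficulty must be > 0")
  } else {
    stop("item_difficulty must be a fixed value or c(lower, upper)")
  }
  if (family == "normal" && (item_skewness != 0 || item_bias != 0))
    stop("family = 'normal' requires item_skewness = 0 and item_bias = 0")
  structure(
    list(
      sigma_latent_expertise = sigma_latent_expertise,
      mean_latent_change_tendency = mean_latent_change_tendency,
      sigma_latent_change_tendency = sigma_latent_change_tendency,
      reference_factor = reference_factor,
      family = family,
      item_truth = item_truth,
      item_difficulty = item_difficulty,
      item_skewness = item_skewness,
      item_bias = item_bias,
      scale_rule = scale_rule
    ),
    class = "population_config"
  )
}

#' @export
print.population_config <- function(x, ...) {
  diff_rule <- if (length(x$item_difficulty) == 2)
    sprintf("Uniform(%g, %g)", x$item_difficulty[1], x$item_difficulty[2])
  else sprintf("fixed %g", x$item_difficulty)
  cat("Population configuration (", x$family, " plausible-value family)\n",
      "  latent expertise:       Normal(0, ", x$sigma_latent_expertise, ")\n",
      "  latent change tendency: Normal(", x$mean_latent_change_tendency, ", ",
      x$sigma_latent_change_tendency, ")\n",
      "  frame-of-reference R:   ", x$reference_factor, "\n",
      "  item truth: ", paste(utils::head(x$item_truth, 3), collapse = ", "),
      if (length(x$item_truth) > 3) ", ..." else "", "\n",
      "  item difficulty: ", diff_rule,
      "; skewness ", x$item_skewness, "; bias ", x$item_bias, "\n", sep = "")
  invisible(x)
}

#' Sample contributors from the population
#'
#' Latent expertise ~ Normal(0, sigma), latent change tendency ~
#' Normal(mean, sigma); transformed fields are filled by the logistic.
#' Smaller `expertise` values correspond to higher expertise.
#'
#' @param n Number of persons.
#' @param config A [population_config()].
#' @param id_prefix Prefix for person identifiers.
#' @return Data frame with columns `person_id`, `latent_expertise`,
#'   `expertise`, `latent_change_tendency`, `change_tendency`.
#' @export
sample_person <- function(n, config, id_prefix = "p") {
  stopifnot(inherits(config, "population_config"), n >= 1)
  le <- stats::rnorm(n, 0, config$sigma_latent_expertise)
  lg <- stats::rnorm(n, config$mean_latent_change_tendency,
                     config$sigma_latent_change_tendency)
  le <- pmin(pmax(le, -.LATENT_CLAMP), .LATENT_CLAMP)
  lg <- pmin(pmax(lg, -.LATENT_CLAMP), .LATENT_CLAMP)
  data.frame(
    person_id = paste0(id_prefix, seq_len(n)),
    latent_expertise = le,
    expertise = logistic(le),
    latent_change_tendency = lg,
    change_tendency = logistic(lg),
    stringsAsFactors = FALSE
  )
}

#' Sample items from the item-generation rules
#'
#' @param n Number of items.
#' @param config A [population_config()].
#' @return Data frame with columns `item_id`, `truth`, `difficulty`,
#'   `skewness`, `bias`.
#' @export
sample_item <- function(n, config) {
  stopifnot(inherits(config, "population_config"), n >= 1)
  difficulty <- if (length(config$item_difficulty) == 2) {
    stats::runif(n, config$item_difficulty[1], config$item_difficulty[2])
  } else {
    rep(config$item_difficulty, n)
  }
  data.frame(
    item_id = paste0("item", seq_len(n)),
    truth = rep_len(config$item_truth, n),
    difficulty = difficulty,
    skewness = rep(config$item_skewness, n),
    bias = rep(config$item_bias, n),
    stringsAsFactors = FALSE
  )
}

# Recycle person/item data frame columns to a common length and return the
# pieces used by the distribution functions.
.pi_fields <- function(person, item) {
  n <- max(nrow(person), nrow(item))
  idx_p <- rep_len(seq_len(nrow(person)), n)
  idx_i <- rep_len(seq_len(nrow(item)), n)
  list(
    E = person$expertise[idx_p],
    G = person$change_tendency[idx_p],
    T = item$truth[idx_i],
    D = item$difficulty[idx_i],
    S = item$skewness[idx_i],
    B = item$bias[idx_i]
  )
}

# Effective skew-normal scale given the configured scale rule.
.sn_scale <- function(D, E, S, config) {
  if (config$scale_rule == "sd") .omega_from_sd(D * E, S * E) else D * E
}

#' Baseline distribution of plausible values
#'
#' Returns the parameters of the internal distribution from which a
#' contributor's independent judgment for an item is drawn: location T_k,
#' scale D_k * E_i, and for the skew-normal family shape S_k * E_i (skewness
#' is damped by expertise); the biased-normal family shifts the location by
#' B_k * E_i.
#'
#' @param person One-row (or n-row) person data frame as from [sample_person()].
#' @param item One-row (or n-row) item data frame as from [sample_item()].
#' @param config A [population_config()] (determines the family).
#' @return Data frame with columns `family`, `location`, `scale`, `shape`.
#' @export
baseline_distribution <- function(person, item, config) {
  f <- .pi_fields(person, item)
  switch(config$family,
    normal = data.frame(family = "normal", location = f$T,
                        scale = f$D * f$E, shape = 0),
    skew_normal = data.frame(family = "skew_normal", location = f$T,
                             scale = .sn_scale(f$D, f$E, f$S, config),
                             shape = f$S * f$E),
    biased_normal = data.frame(family = "biased_normal",
                               location = f$T + f$B * f$E,
                               scale = f$D * f$E, shape = 0)
  )
}

#' Draw independent judgments
#'
#' One draw from the baseline plausible-value distribution per person/item
#' pair; used both for standalone crowds and for position 1 of a chain.
#'
#' @inheritParams baseline_distribution
#' @return Numeric vector of judgments.
#' @export
draw_independent_judgment <- function(person, item, config) {
  spec <- baseline_distribution(person, item, config)
  n <- nrow(spec)
  if (config$family == "skew_normal") {
    # vectorized over parameters via the convolution representation
    d <- delta_of_alpha(spec$shape)
    z0 <- stats::rnorm(n)
    z1 <- stats::rnorm(n)
    spec$location + spec$scale * (d * abs(z0) + sqrt(1 - d^2) * z1)
  } else {
    stats::rnorm(n, spec$location, spec$scale)
  }
}

#' Anchoring shift
#'
#' The additive pull of the updated plausible-value distribution toward the
#' presented judgment: A = E_i * (presented - T_k). Experts (E_i near 0) are
#' barely pulled; novices (E_i near 1) absorb nearly the full discrepancy.
#'
#' @inheritParams baseline_distribution
#' @param presented Presented judgment(s); finite.
#' @return Numeric vector of shifts.
#' @export
anchoring_shift <- function(person, item, presented) {
  stopifnot(all(is.finite(presented)))
  f <- .pi_fields(person, item)
  f$E * (presented - f$T)
}

# Baseline CDF evaluated at the presented judgment, per family.
.baseline_cdf <- function(person, item, presented, config) {
  f <- .pi_fields(person, item)
  switch(config$family,
    normal = stats::pnorm((presented - f$T) / (f$D * f$E)),
    skew_normal = {
      om <- .sn_scale(f$D, f$E, f$S, config)
      z <- (presented - f$T) / om
      pmin(pmax(stats::pnorm(z) - 2 * owens_t(z, f$S * f$E), 0), 1)
    },
    biased_normal = stats::pnorm((presented - f$T - f$B * f$E) / (f$D * f$E))
  )
}

#' Probability of adjusting a presented judgment
#'
#' Deterministic evaluation of
#' \eqn{P = G_i + (1 - G_i) \cdot 4 (F(y) - 1/2)^2}, where F is the CDF of the
#' baseline plausible-value distribution of the active family. The change
#' tendency G_i is the floor, attained exactly where F(y) = 1/2 (the
#' distribution median); P tends to 1 for implausible presented judgments.
#'
#' @inheritParams anchoring_shift
#' @param config A [population_config()].
#' @return Numeric vector in [G_i, 1].
#' @export
change_probability <- function(person, item, presented, config) {
  stopifnot(all(is.finite(presented)))
  f <- .pi_fields(person, item)
  F <- .baseline_cdf(person, item, presented, config)
  p <- f$G + (1 - f$G) * 4 * (F - 0.5)^2
  pmin(pmax(p, f$G), 1)
}

#' Draw adjust/maintain decisions
#'
#' Bernoulli draw per change probability: 1 = adjust, 0 = maintain.
#'
#' @param p Numeric vector of probabilities in [0, 1].
#' @return Integer vector of 0/1 decisions.
#' @export
draw_change_decision <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("change probabilities must lie in [0, 1]")
  stats::rbinom(length(p), 1L, p)
}

#' Updated distribution of plausible values
#'
#' After deciding to adjust, the revised judgment is drawn from the baseline
#' distribution shifted by the anchoring term and shrunk by the
#' frame-of-reference factor: location T_k + A_ik (plus B_k * E_i for the
#' biased-normal family), scale R * D_k * E_i, shape S_k * E_i for the
#' skew-normal family.
#'
#' @inheritParams change_probability
#' @param reference_factor Optional per-item override of the global R.
#' @return Data frame with columns `family`, `location`, `scale`, `shape`.
#' @export
updated_distribution <- function(person, item, presented, config,
                                 reference_factor = NULL) {
  stopifnot(all(is.finite(presented)))
  f <- .pi_fields(person, item)
  R <- if (is.null(reference_factor)) config$reference_factor else reference_factor
  A <- f$E * (presented - f$T)
  switch(config$family,
    normal = data.frame(family = "normal", location = f$T + A,
                        scale = R * f$D * f$E, shape = 0),
    skew_normal = data.frame(family = "skew_normal", location = f$T + A,
                             scale = R * .sn_scale(f$D, f$E, f$S, config),
                             shape = f$S * f$E),
    biased_normal = data.frame(family = "biased_normal",
                               location = f$T + f$B * f$E + A,
                               scale = R * f$D * f$E, shape = 0)
  )
}

# Draw one revised judgment per row of a distribution-spec data frame.
.draw_from_spec <- function(spec) {
  n <- nrow(spec)
  if (n == 0L) return(numeric(0))
  if (spec$family[1] == "skew_normal") {
    d <- delta_of_alpha(spec$shape)
    z0 <- stats::rnorm(n)
    z1 <- stats::rnorm(n)
    spec$location + spec$scale * (d * abs(z0) + sqrt(1 - d^2) * z1)
  } else {
    stats::rnorm(n, spec$location, spec$scale)
  }
}

#' One two-stage sequential step
#'
#' A contributor sees the presented judgment(s), computes the change
#' probability, draws the adjust/maintain decision, and -- only if adjusting --
#' emits a draw from the updated distribution. A maintained judgment is passed
#' through bit-identically.
#'
#' Vectorized over items: `person` is one contributor; `item` and `presented`
#' may have length > 1.
#'
#' @inheritParams change_probability
#' @return Data frame with one row per item: `person_id`, `item_id`,
#'   `presented_judgment`, `change_probability`, `change_decision`,
#'   `anchor_shift`, `judgment`.
#' @export
sequential_step <- function(person, item, presented, config) {
  stopifnot(nrow(person) == 1, all(is.finite(presented)))
  n <- max(nrow(item), length(presented))
  presented <- rep_len(presented, n)
  p <- change_probability(person, item, presented, config)
  decision <- draw_change_decision(p)
  judgment <- presented
  changed <- decision == 1L
  if (any(changed)) {
    spec <- updated_distribution(person, item[rep_len(seq_len(nrow(item)), n), ,
                                              drop = FALSE][changed, , drop = FALSE],
                                 presented[changed], config)
    judgment[changed] <- .draw_from_spec(spec)
  }
  data.frame(
    person_id = person$person_id,
    item_id = rep_len(item$item_id, n),
    presented_judgment = presented,
    change_probability = p,
    change_decision = decision,
    anchor_shift = anchoring_shift(person, item, presented),
    judgment = judgment,
    stringsAsFactors = FALSE
  )
}
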