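# Individual-level generative model: parameter sampling, plausible-value
# distributions, change probability, anchoring, and the sequential step.

test_that("logistic transform is correct, monotone, and rejects non-finite input", {
  expect_identical(logistic(0), 0.5)
  expect_equal(logistic(-1), 0.26894142136999512, tolerance = 1e-14)
  expect_equal(logistic(c(-700, 700)), c(0, 1), tolerance = 1e-12)
  x <- seq(-8, 8, length.out = 50)
  expect_true(all(diff(logistic(x)) > 0))
  expect_error(logistic(Inf))
  expect_error(logistic(NA_real_))
})

test_that("person sampling recovers the latent distributions and logistic transforms", {
  cfg_tiny <- population_config(sigma_latent_expertise = 1e-12)
  set.seed(101)
  p <- sample_person(50, cfg_tiny)
  expect_true(all(abs(p$expertise - 0.5) < 1e-10))
  expect_equal(p$expertise, logistic(p$latent_expertise))
  expect_equal(p$change_tendency, logistic(p$latent_change_tendency))

  cfg <- population_config()
  set.seed(102)
  p <- sample_person(1e5, cfg)
  expect_lt(abs(mean(p$latent_expertise)), 4 / sqrt(1e5))
  expect_lt(abs(sd(p$latent_expertise) - 1), 4 / sqrt(2 * 1e5))
  # mean transformed change tendency vs. quadrature of E[logistic(N(-1, 1))]
  target <- oracle_mean_logistic_normal(-1, 1)
  expect_lt(abs(mean(p$change_tendency) - target),
            4 * sd(p$change_tendency) / sqrt(1e5))
  expect_true(all(p$expertise > 0 & p$expertise < 1))
})

test_that("item sampling follows the difficulty rule and validates it", {
  cfg_fix <- population_config(item_difficulty = 3)
  set.seed(103)
  it <- sample_item(100, cfg_fix)
  expect_true(all(it$difficulty == 3))
  expect_true(all(it$truth == 0))

  cfg_unif <- population_config(item_difficulty = c(1, 5))
  it <- sample_item(1e4, cfg_unif)
  expect_true(all(it$difficulty >= 1 & it$difficulty <= 5))
  se <- sqrt((5 - 1)^2 / 12) / sqrt(1e4)
  expect_lt(abs(mean(it$difficulty) - 3), 4 * se)

  expect_error(population_config(item_difficulty = c(5, 1)), "lower < upper")
  expect_error(population_config(item_difficulty = c(0, 5)), "> 0")
  expect_error(population_config(item_difficulty = -2), "> 0")
})

test_that("family constraints and config validation hold", {
  expect_error(population_config(family = "normal", item_skewness = 1))
  expect_error(population_config(family = "normal", item_bias = 0.6))
  expect_error(population_config(sigma_latent_expertise = -1))
  expect_error(population_config(reference_factor = 1.2))
  expect_silent(population_config(reference_factor = 1))  # effect switched off
})

test_that("baseline distribution composes person and item parameters per family", {
  p <- fixed_person(0.5, 0.3)
  it <- fixed_item(truth = 0, difficulty = 2)
  cfg_n <- population_config(item_difficulty = 2)
  spec <- baseline_distribution(p, it, cfg_n)
  expect_equal(spec$location, 0)
  expect_equal(spec$scale, 1)    # D * E = 2 * 0.5
  expect_equal(spec$shape, 0)

  # skew family with S = 0 is the plain normal spec
  cfg_s0 <- population_config(family = "skew_normal", item_difficulty = 2,
                              item_skewness = 0)
  s0 <- baseline_distribution(p, fixed_item(difficulty = 2, skewness = 0), cfg_s0)
  expect_equal(s0[c("location", "scale", "shape")],
               spec[c("location", "scale", "shape")])

  # biased family shifts the location by B * E; at E = 1 and B = 0.6 -> 0.6
  cfg_b <- population_config(family = "biased_normal", item_difficulty = 3,
                             item_bias = 0.6)
  sb <- baseline_distribution(fixed_person(1 - 1e-16, 0.3),
                              fixed_item(difficulty = 3, bias = 0.6), cfg_b)
  expect_equal(sb$location, 0.6, tolerance = 1e-12)
})

test_that("independent judgments recover the stated moments", {
  cfg <- population_config(item_difficulty = 2)
  p <- fixed_person(0.5, 0.3)
  it <- fixed_item(truth = 1, difficulty = 2)
  set.seed(104)
  y <- replicate(1, draw_independent_judgment(p[rep(1, 1e5), ], it, cfg))
  expect_lt(abs(mean(y) - 1), 4 * 1 / sqrt(1e5))          # sd = D*E = 1
  expect_lt(abs(sd(y) - 1), 4 * 1 / sqrt(2 * 1e5))
})

test_that("anchoring shift scales the discrepancy by expertise", {
  it <- fixed_item(truth = 2)
  expect_equal(anchoring_shift(fixed_person(0.5, 0.3), it, 2), 0)
  expect_equal(anchoring_shift(fixed_person(0.5, 0.3), it, 12), 5)
  expect_lt(anchoring_shift(fixed_person(1e-6, 0.3), it, 12), 1e-4)
  expect_equal(anchoring_shift(fixed_person(1 - 1e-12, 0.3), it, 12), 10,
               tolerance = 1e-9)
  expect_error(anchoring_shift(fixed_person(0.5, 0.3), it, Inf))
})

test_that("change probability has the change-tendency floor and correct shape", {
  cfg <- population_config(item_difficulty = 2)
  it <- fixed_item(truth = 0, difficulty = 2)
  # at the truth the normal CDF is 1/2: P = G exactly
  expect_equal(change_probability(fixed_person(0.5, 0), it, 0, cfg), 0)
  expect_equal(change_probability(fixed_person(0.5, 0.3), it, 0, cfg), 0.3)
  # one baseline SD away with G = 0: 4 (Phi(1) - 1/2)^2, oracle via quadrature
  phi1 <- oracle_normal_cdf(1)
  expect_equal(change_probability(fixed_person(0.5, 0), it, 1, cfg),
               4 * (phi1 - 0.5)^2, tolerance = 1e-10)
  expect_equal(4 * (phi1 - 0.5)^2, 0.4661, tolerance = 1e-4)
  # far-away presented judgments are adjusted almost surely
  expect_gt(change_probability(fixed_person(0.5, 0), it, 1e6, cfg), 1 - 1e-12)
})

test_that("change probability is symmetric and monotone for the normal family", {
  cfg <- population_config(item_difficulty = 2)
  set.seed(105)
  for (rep in 1:20) {
    p <- sample_person(1, cfg)
    it <- fixed_item(truth = rnorm(1, 0, 3), difficulty = runif(1, 1, 5))
    d <- sort(runif(8, 0, 10))
    up <- change_probability(p, it, it$truth + d, cfg)
    dn <- change_probability(p, it, it$truth - d, cfg)
    expect_true(all(abs(up - dn) < 1e-12))
    expect_true(all(diff(up) >= 0))
    expect_true(all(up >= p$change_tendency & up <= 1))
  }
})

test_that("skew family: floor sits at the median, not the mean, and alpha 0 matches normal", {
  cfg <- population_config(family = "skew_normal", item_difficulty = 3,
                           item_skewness = 1)
  p <- fixed_person(0.8, 0.25)
  it <- fixed_item(truth = 0, difficulty = 3, skewness = 1)
  om <- 3 * 0.8
  al <- 1 * 0.8
  med <- uniroot(function(x) skew_normal_cdf(x, 0, om, al) - 0.5,
                 c(-10, 10), tol = 1e-12)$root
  expect_equal(change_probability(p, it, med, cfg), 0.25, tolerance = 1e-8)
  expect_gt(change_probability(p, it, med + 0.3, cfg), 0.25)
  expect_gt(change_probability(p, it, med - 0.3, cfg), 0.25)
  # with positive skew the median differs from the mean
  expect_gt(abs(skew_normal_mean(0, om, al) - med), 1e-3)
  # alpha = 0 reduction agrees with the normal family pointwise
  cfg0 <- population_config(family = "skew_normal", item_difficulty = 3,
                            item_skewness = 0)
  cfgn <- population_config(item_difficulty = 3)
  it0 <- fixed_item(difficulty = 3)
  y <- seq(-8, 8, length.out = 33)
  expect_true(all(abs(change_probability(p, it0, y, cfg0) -
                        change_probability(p, it0, y, cfgn)) < 1e-10))
})

test_that("biased family centers the evaluation at the shifted mean", {
  cfg <- population_config(family = "biased_normal", item_difficulty = 3,
                           item_bias = 0.6)
  p <- fixed_person(0.5, 0.2)
  it <- fixed_item(difficulty = 3, bias = 0.6)
  # floor attained at T + B*E = 0.3, not at T
  expect_equal(change_probability(p, it, 0.3, cfg), 0.2)
  expect_gt(change_probability(p, it, 0, cfg), 0.2)
})

test_that("change decisions are Bernoulli draws with validated probabilities", {
  expect_identical(draw_change_decision(rep(0, 100)), rep(0L, 100))
  expect_identical(draw_change_decision(rep(1, 100)), rep(1L, 100))
  set.seed(106)
  f <- mean(draw_change_decision(rep(0.25, 1e5)))
  expect_lt(abs(f - 0.25), 4 * sqrt(0.25 * 0.75 / 1e5))
  expect_error(draw_change_decision(1.01))
  expect_error(draw_change_decision(-0.1))
  expect_error(draw_change_decision(NA_real_))
})

test_that("updated distribution shifts by anchoring and shrinks by R", {
  # R = 1, presented = truth: identical to the baseline distribution
  cfg1 <- population_config(reference_factor = 1, item_difficulty = 2)
  p <- fixed_person(0.5, 0.3)
  it <- fixed_item(truth = 3, difficulty = 2)
  expect_equal(updated_distribution(p, it, 3, cfg1),
               baseline_distribution(p, it, cfg1))
  # direct substitution: T=0, E=0.5, presented=10, D=2, R=0.4
  cfg <- population_config(reference_factor = 0.4, item_difficulty = 2)
  u <- updated_distribution(fixed_person(0.5, 0.3),
                            fixed_item(difficulty = 2), 10, cfg)
  expect_equal(u$location, 5)
  expect_equal(u$scale, 0.4)
  # moment recovery from revised draws
  set.seed(107)
  step <- sequential_step(fixed_person(0.5, 1 - 1e-12),
                          fixed_item(difficulty = 2)[rep(1, 1e5), ],
                          10, cfg)
  expect_true(all(step$change_decision == 1L))
  expect_lt(abs(mean(step$judgment) - 5), 4 * 0.4 / sqrt(1e5))
  expect_lt(abs(sd(step$judgment) - 0.4), 4 * 0.4 / sqrt(2 * 1e5))
})

test_that("per-item reference-factor override is honored", {
  cfg <- population_config(reference_factor = 0.4, item_difficulty = 2)
  u <- updated_distribution(fixed_person(0.5, 0.3), fixed_item(difficulty = 2),
                            0, cfg, reference_factor = 0.9)
  expect_equal(u$scale, 0.9)
})

test_that("maintained judgments pass through bit-identically", {
  cfg <- population_config(item_difficulty = 2)
  p <- fixed_person(0.5, 1e-300)  # G ~ 0 and presented at the truth: P ~ 0
  it <- fixed_item(truth = 0.1234567891234567, difficulty = 2)
  set.seed(108)
  step <- sequential_step(p, it[rep(1, 200), ], 0.1234567891234567, cfg)
  expect_true(all(step$change_decision == 0L))
  expect_identical(step$judgment, step$presented_judgment)
  expect_true(all(step$change_probability >= 0 & step$change_probability < 1e-10))
})

test_that("decision frequency is self-consistent with computed change probabilities", {
  cfg <- population_config()
  set.seed(109)
  items <- sample_item(60, cfg)
  trials <- do.call(rbind, lapply(1:80, function(i) {
    persons <- sample_person(2, cfg, id_prefix = paste0("c", i, "p"))
    simulate_chain(persons, items, cfg, chain_id = paste0("c", i))
  }))
  p2 <- trials[trials$position == 2, ]
  se <- sqrt(sum(p2$change_probability * (1 - p2$change_probability))) / nrow(p2)
  expect_lt(abs(mean(p2$change_decision) - mean(p2$change_probability)), 4 * se)
})
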