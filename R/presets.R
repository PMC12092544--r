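# Named presets encoding the published simulation designs.

.PRESETS <- list(
  # 60 items, 100 chains of 4 contributors (400 persons, 24,000 chain
  # trials), sigma_E* = sigma_G* = 1, T_k = 0, D_k ~ Uniform(1, 5), R = 0.4;
  # matched crowds of size 4 for the wisdom-of-crowds comparison.
  baseline = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.4, family = "normal",
      item_truth = 0, item_difficulty = c(1, 5)),
    n_items = 60, n_chains = 100, chain_length = 4,
    n_crowds = 100, crowd_size = 4, seed = seed, preset_name = "baseline"),

  # Same population, chains and crowds extended to 20 contributors.
  long_chain_normal = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.4, family = "normal",
      item_truth = 0, item_difficulty = c(1, 5)),
    n_items = 60, n_chains = 100, chain_length = 20,
    n_crowds = 100, crowd_size = 20, seed = seed,
    preset_name = "long_chain_normal"),

  # Long chains with right-skewed plausible values, S_k = 1 for all items.
  long_chain_skew = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.4, family = "skew_normal",
      item_truth = 0, item_difficulty = c(1, 5), item_skewness = 1),
    n_items = 60, n_chains = 100, chain_length = 20,
    n_crowds = 100, crowd_size = 20, seed = seed,
    preset_name = "long_chain_skew"),

  # Bias-vs-skew comparison: sigma_E* = sigma_G* = 1, D_k = 3, R = 0.5,
  # 1000 chains; three plausible-value families that share the mean 0.6 at
  # E_i = 1 (unbiased normal, bias B_k = 0.6, skewness S_k = 0.25).
  bias_skew_normal = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.5, family = "normal",
      item_truth = 0, item_difficulty = 3),
    n_items = 60, n_chains = 1000, chain_length = 20,
    n_crowds = 1000, crowd_size = 20, seed = seed,
    preset_name = "bias_skew_normal"),

  bias_skew_biased = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.5, family = "biased_normal",
      item_truth = 0, item_difficulty = 3, item_bias = 0.6),
    n_items = 60, n_chains = 1000, chain_length = 20,
    n_crowds = 1000, crowd_size = 20, seed = seed,
    preset_name = "bias_skew_biased"),

  bias_skew_skewed = function(seed) experiment_config(
    population = population_config(
      sigma_latent_expertise = 1, sigma_latent_change_tendency = 1,
      reference_factor = 0.5, family = "skew_normal",
      item_truth = 0, item_difficulty = 3, item_skewness = 0.25),
    n_items = 60, n_chains = 1000, chain_length = 20,
    n_crowds = 1000, crowd_size = 20, seed = seed,
    preset_name = "bias_skew_skewed")
)

#' Available preset names
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.PRESETS)

#' Build a preset experiment configuration
#'
#' Presets encode the published simulation designs verbatim: `"baseline"`
#' (100 chains of 4 over 60 items, difficulty Uniform(1,5), R = 0.4),
#' `"long_chain_normal"` and `"long_chain_skew"` (chains and crowds of 20;
#' the skew variant sets item skewness 1), and the `"bias_skew_*"` trio
#' (fixed difficulty 3, R = 0.5, 1000 chains; unbiased, mean-biased by 0.6,
#' or skewed by 0.25).
#'
#' @param name Preset name; see [preset_names()].
#' @param seed Master seed.
#' @return An [experiment_config()].
#' @export
preset_config <- function(name, seed = 1) {
  if (!name %in% names(.PRESETS))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.PRESETS), collapse = ", "))
  .PRESETS[[name]](seed)
}
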