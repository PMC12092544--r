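# Configuration and tabular I/O.
#
# Delimited-text dialect: UTF-8, comma-separated, header row, "." decimal,
# missing fields empty. Numeric columns are written with 17 significant
# digits ("%.17g") so a write/read round trip reproduces doubles bit-exactly.

#' Write a table as CSV with round-trip-exact numerics
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
write_table_csv <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) {
      s <- sprintf("%.17g", y[[j]])
      s[is.na(y[[j]])] <- NA_character_
      y[[j]] <- s
    }
  }
  utils::write.csv(y, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read a table written by [write_table_csv()]
#'
#' @param path Input file.
#' @return Data frame with numeric columns restored.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
}

# Flatten an experiment_config into a plain list for the manifest / YAML.
.config_to_list <- function(config) {
  pop <- config$population
  list(
    preset = config$preset_name,
    seed = config$seed,
    n_items = config$n_items, n_chains = config$n_chains,
    chain_length = config$chain_length,
    n_crowds = config$n_crowds, crowd_size = config$crowd_size,
    population = list(
      sigma_latent_expertise = pop$sigma_latent_expertise,
      mean_latent_change_tendency = pop$mean_latent_change_tendency,
      sigma_latent_change_tendency = pop$sigma_latent_change_tendency,
      reference_factor = pop$reference_factor,
      family = pop$family,
      item_truth = pop$item_truth,
      item_difficulty = pop$item_difficulty,
      item_skewness = pop$item_skewness,
      item_bias = pop$item_bias,
      scale_rule = pop$scale_rule
    )
  )
}

.EXPERIMENT_KEYS <- c("preset", "seed", "n_items", "n_chains", "chain_length",
                      "n_crowds", "crowd_size", "population")
.POPULATION_KEYS <- c("sigma_latent_expertise", "mean_latent_change_tendency",
                      "sigma_latent_change_tendency", "reference_factor",
                      "family", "item_truth", "item_difficulty",
                      "item_skewness", "item_bias", "scale_rule")

# Build an experiment_config from a plain list (preset base + overrides).
.config_from_list <- function(spec) {
  unknown <- setdiff(names(spec), .EXPERIMENT_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  seed <- if (is.null(spec$seed)) 1L else spec$seed
  if (!is.null(spec$preset)) {
    base <- preset_config(spec$preset, seed = seed)
  } else {
    base <- experiment_config(seed = seed)
  }
  pop_args <- .config_to_list(base)$population
  if (!is.null(spec$population)) {
    unknown <- setdiff(names(spec$population), .POPULATION_KEYS)
    if (length(unknown))
      stop("unknown population keys: ", paste(unknown, collapse = ", "))
    pop_args[names(spec$population)] <- spec$population
  }
  pop_args$item_difficulty <- unlist(pop_args$item_difficulty)
  pop_args$item_truth <- unlist(pop_args$item_truth)
  population <- do.call(population_config, pop_args)
  counts <- list(n_items = base$n_items, n_chains = base$n_chains,
                 chain_length = base$chain_length, n_crowds = base$n_crowds,
                 crowd_size = base$crowd_size)
  for (k in names(counts)) if (!is.null(spec[[k]])) counts[[k]] <- spec[[k]]
  experiment_config(population = population,
                    n_items = counts$n_items, n_chains = counts$n_chains,
                    chain_length = counts$chain_length,
                    n_crowds = counts$n_crowds, crowd_size = counts$crowd_size,
                    seed = seed, preset_name = spec$preset)
}

#' Load an experiment configuration from a YAML file
#'
#' The file may name a `preset` and override any of its fields; keys outside
#' the configuration schema are rejected with the offending names.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (!is.list(spec)) stop("config file must contain a mapping")
  .config_from_list(spec)
}

#' Run a preset and write its tables
#'
#' Simulates the named preset and writes, under `output_dir`:
#' `chain_trials.csv`, `crowd_judgments.csv`, `items.csv`, `persons.csv`,
#' `position_summary.csv`, `crowd_summary.csv`, and `manifest.yml` (config
#' echo, seed, package version). Outputs are byte-identical across runs with
#' the same name and seed.
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
run_preset <- function(name, seed = 1, output_dir = ".") {
  config <- preset_config(name, seed = seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  res <- simulate_experiment(config)
  files <- c(
    chain_trials = file.path(output_dir, "chain_trials.csv"),
    crowd_judgments = file.path(output_dir, "crowd_judgments.csv"),
    items = file.path(output_dir, "items.csv"),
    persons = file.path(output_dir, "persons.csv"),
    position_summary = file.path(output_dir, "position_summary.csv"),
    crowd_summary = file.path(output_dir, "crowd_summary.csv"),
    manifest = file.path(output_dir, "manifest.yml")
  )
  write_table_csv(res$trials, files["chain_trials"])
  if (!is.null(res$crowd)) write_table_csv(res$crowd, files["crowd_judgments"])
  write_table_csv(res$items, files["items"])
  write_table_csv(res$persons, files["persons"])
  write_table_csv(position_summaries(res$trials, res$items),
                  files["position_summary"])
  if (!is.null(res$crowd))
    write_table_csv(crowd_summaries(res$crowd, res$items),
                    files["crowd_summary"])
  manifest <- c(.config_to_list(config),
                list(package_version =
                       as.character(utils::packageVersion("seqcollab"))))
  yaml::write_yaml(manifest, files["manifest"])
  invisible(files)
}

#' Summarize a trial table file
#'
#' Reads a chain trial table and its item table and writes position
#' summaries; the change-magnitude rows cover adjusted trials only, and an
#' input lacking the trial-table schema is rejected with the missing column
#' names.
#'
#' @param trials_path CSV of chain trials.
#' @param items_path CSV of items.
#' @param output_path Where to write the summary CSV.
#' @return Invisibly, the summary data frame.
#' @export
summarize_trials_file <- function(trials_path, items_path, output_path) {
  trials <- read_table_csv(trials_path)
  need <- c("chain_id", "position", "person_id", "item_id",
            "presented_judgment", "change_probability", "change_decision",
            "judgment")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("not a chain trial table; missing columns: ",
         paste(miss, collapse = ", "))
  items <- read_table_csv(items_path)
  summ <- position_summaries(trials, items)
  write_table_csv(summ, output_path)
  invisible(summ)
}

#' Parameter sweep over population hyperparameters
#'
#' Reruns a scaled copy of an experiment over a grid of population-parameter
#' values and collects the per-position summaries, in the spirit of
#' robustness appendices that vary the expertise SD, change-tendency SD, and
#' frame-of-reference factor one at a time.
#'
#' @param base An [experiment_config()] providing everything not swept.
#' @param grid Data frame; columns must be population_config argument names,
#'   one row per cell.
#' @param seed Master seed (each cell runs under `seed`).
#' @return Data frame of position summaries with the grid columns attached.
#' @export
sweep_parameters <- function(base, grid, seed = 1) {
  stopifnot(inherits(base, "experiment_config"), is.data.frame(grid),
            nrow(grid) >= 1)
  bad <- setdiff(names(grid), .POPULATION_KEYS)
  if (length(bad)) stop("not population parameters: ", paste(bad, collapse = ", "))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    pop_args <- .config_to_list(base)$population
    for (k in names(grid)) pop_args[[k]] <- grid[[k]][r]
    pop_args$item_difficulty <- unlist(pop_args$item_difficulty)
    pop_args$item_truth <- unlist(pop_args$item_truth)
    cfg <- experiment_config(
      population = do.call(population_config, pop_args),
      n_items = base$n_items, n_chains = base$n_chains,
      chain_length = base$chain_length, n_crowds = base$n_crowds,
      crowd_size = base$crowd_size, seed = seed)
    res <- simulate_experiment(cfg)
    summ <- position_summaries(res$trials, res$items)
    for (k in names(grid)) summ[[k]] <- grid[[k]][r]
    out[[r]] <- summ
  }
  do.call(rbind, out)
}
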