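# Group-level simulation: sequential chains of dependent judgments and
# independent crowds aggregated by unweighted averaging.
#
# Seeding plan: the experiment seed initializes one master stream from which
# the item set and one integer sub-seed per chain and per crowd are drawn.
# Each chain/crowd then runs under its own sub-seed, so individual chains are
# reproducible independently of execution order.

#' Experiment configuration
#'
#' Bundles a [population_config()] with the design counts of a simulation
#' experiment: number of items (shared by all chains and crowds), number and
#' length of sequential chains, and number and size of independent crowds.
#'
#' @param population A [population_config()].
#' @param n_items Number of judgment items (>= 1).
#' @param n_chains Number of sequential chains (>= 1).
#' @param chain_length Contributors per chain (>= 1).
#' @param n_crowds Number of independent crowds (>= 0).
#' @param crowd_size Contributors per crowd (>= 1).
#' @param seed Integer master seed.
#' @param preset_name Optional name recorded when the config comes from a preset.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(population = population_config(),
                              n_items = 60,
                              n_chains = 100,
                              chain_length = 4,
                              n_crowds = 100,
                              crowd_size = 4,
                              seed = 1,
                              preset_name = NULL) {
  stopifnot(
    inherits(population, "population_config"),
    n_items >= 1, n_chains >= 1, chain_length >= 1,
    n_crowds >= 0, crowd_size >= 1,
    is.numeric(seed), length(seed) == 1, is.finite(seed)
  )
  structure(
    list(population = population, n_items = as.integer(n_items),
         n_chains = as.integer(n_chains), chain_length = as.integer(chain_length),
         n_crowds = as.integer(n_crowds), crowd_size = as.integer(crowd_size),
         seed = as.integer(seed), preset_name = preset_name),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration",
      if (!is.null(x$preset_name)) paste0(" [preset: ", x$preset_name, "]"),
      "\n  ", x$n_chains, " chains of length ", x$chain_length, ", ",
      x$n_crowds, " crowds of size ", x$crowd_size, ", ",
      x$n_items, " items, seed ", x$seed, "\n", sep = "")
  print(x$population)
  invisible(x)
}

# Integer sub-seeds drawn from the current stream.
.subseeds <- function(n) {
  if (n == 0L) return(integer(0))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one sequential chain
#'
#' Position 1 gives independent judgments (one per item) from the baseline
#' distribution; every later position receives the previous position's emitted
#' judgment per item and performs the two-stage adjust-or-maintain step.
#'
#' @param persons Ordered person data frame (one row per chain position) as
#'   from [sample_person()].
#' @param items Item data frame as from [sample_item()].
#' @param config A [population_config()].
#' @param chain_id Identifier stored in the output.
#' @return Data frame of trial records, `chain_length * n_items` rows, with
#'   columns `chain_id`, `position`, `person_id`, `item_id`,
#'   `presented_judgment`, `change_probability`, `change_decision`,
#'   `anchor_shift`, `judgment`. Position-1 rows have NA for the fields that
#'   presuppose a presented judgment.
#' @export
simulate_chain <- function(persons, items, config, chain_id = "chain1") {
  stopifnot(nrow(persons) >= 1, nrow(items) >= 1,
            inherits(config, "population_config"))
  L <- nrow(persons)
  n_it <- nrow(items)
  out <- vector("list", L)
  first <- draw_independent_judgment(persons[1, , drop = FALSE], items, config)
  out[[1]] <- data.frame(
    chain_id = chain_id, position = 1L,
    person_id = persons$person_id[1], item_id = items$item_id,
    presented_judgment = NA_real_, change_probability = NA_real_,
    change_decision = NA_integer_, anchor_shift = NA_real_,
    judgment = first, stringsAsFactors = FALSE
  )
  current <- first
  for (pos in seq_len(L)[-1]) {
    step <- sequential_step(persons[pos, , drop = FALSE], items, current, config)
    out[[pos]] <- data.frame(chain_id = chain_id, position = pos, step,
                             stringsAsFactors = FALSE)
    current <- step$judgment
  }
  do.call(rbind, out)
}

#' Simulate a full experiment: chains plus independent crowds
#'
#' Samples one shared item set, then fresh contributors for every chain and
#' crowd (no person appears twice), and runs all chains and crowds under
#' deterministic per-chain sub-seeds.
#'
#' @param config An [experiment_config()].
#' @return List of class `experiment_result` with elements
#'   \describe{
#'     \item{trials}{flat chain trial table (see [simulate_chain()])}
#'     \item{crowd}{flat crowd table: `crowd_id`, `member`, `person_id`,
#'       `item_id`, `judgment`}
#'     \item{items}{the shared item set}
#'     \item{persons}{roster of all sampled persons with a `role` column}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  pop <- config$population
  set.seed(config$seed)
  items <- sample_item(config$n_items, pop)
  chain_seeds <- .subseeds(config$n_chains)
  crowd_seeds <- .subseeds(config$n_crowds)

  chain_out <- vector("list", config$n_chains)
  chain_persons <- vector("list", config$n_chains)
  for (c_i in seq_len(config$n_chains)) {
    set.seed(chain_seeds[c_i])
    id <- sprintf("chain%03d", c_i)
    persons <- sample_person(config$chain_length, pop,
                             id_prefix = paste0(id, "_p"))
    chain_persons[[c_i]] <- persons
    chain_out[[c_i]] <- simulate_chain(persons, items, pop, chain_id = id)
  }

  crowd_out <- vector("list", config$n_crowds)
  crowd_persons <- vector("list", config$n_crowds)
  for (w_i in seq_len(config$n_crowds)) {
    set.seed(crowd_seeds[w_i])
    id <- sprintf("crowd%03d", w_i)
    persons <- sample_person(config$crowd_size, pop,
                             id_prefix = paste0(id, "_p"))
    crowd_persons[[w_i]] <- persons
    jd <- lapply(seq_len(config$crowd_size), function(m) {
      data.frame(crowd_id = id, member = m,
                 person_id = persons$person_id[m], item_id = items$item_id,
                 judgment = draw_independent_judgment(
                   persons[m, , drop = FALSE], items, pop),
                 stringsAsFactors = FALSE)
    })
    crowd_out[[w_i]] <- do.call(rbind, jd)
  }

  roster <- rbind(
    if (config$n_chains > 0)
      cbind(do.call(rbind, chain_persons), role = "chain"),
    if (config$n_crowds > 0)
      cbind(do.call(rbind, crowd_persons), role = "crowd")
  )
  structure(
    list(trials = do.call(rbind, chain_out),
         crowd = if (config$n_crowds > 0) do.call(rbind, crowd_out) else NULL,
         items = items, persons = roster, config = config),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Simulated experiment: ", nrow(x$trials), " chain trial records, ",
      if (is.null(x$crowd)) 0 else nrow(x$crowd), " crowd judgments, ",
      nrow(x$items), " items, ", nrow(x$persons), " persons\n", sep = "")
  invisible(x)
}

#' Running unweighted average of a crowd for one item
#'
#' Element n is the mean of the first n members' judgments for the item, in
#' sampling order -- the wisdom-of-crowds estimator as a function of crowd
#' size.
#'
#' @param crowd Crowd table (rows for one or more crowds).
#' @param crowd_id Which crowd.
#' @param item_id Which item.
#' @return Numeric vector of cumulative means, length = crowd size.
#' @export
crowd_running_average <- function(crowd, crowd_id, item_id) {
  rows <- crowd[crowd$crowd_id == crowd_id & crowd$item_id == item_id, ,
                drop = FALSE]
  if (nrow(rows) == 0) stop("no judgments for this crowd/item")
  rows <- rows[order(rows$member), , drop = FALSE]
  cumsum(rows$judgment) / seq_len(nrow(rows))
}

#' Simulate a chain with a prescribed expertise composition
#'
#' Builds a chain whose positions 2..L are filled by contributors drawn
#' without replacement from the requested expertise classes of a classified
#' pool (see [classify_expertise()]). Position 1 is either a freshly sampled
#' contributor giving an independent judgment (default) or a fixed vector of
#' starting values per item, mirroring designs that seed chains with
#' preselected judgments.
#'
#' @param composition Character vector of class labels (e.g. `c("high",
#'   "average")`), one per chain position after the first.
#' @param pool Person data frame with an `expertise_class` column; rows used
#'   here are consumed (use the returned `used` ids to remove them).
#' @param items Item data frame.
#' @param config A [population_config()].
#' @param chain_id Identifier for the output.
#' @param start Either `NULL` (sample a fresh position-1 person) or a numeric
#'   vector of starting judgments, one per item (recycled).
#' @return List with `trials` (trial records for positions 2..L, plus
#'   position 1 when a person starts the chain) and `used` (person ids
#'   consumed from the pool).
#' @export
simulate_composed_chain <- function(composition, pool, items, config,
                                    chain_id = "chain1", start = NULL) {
  stopifnot(length(composition) >= 1, "expertise_class" %in% names(pool))
  picked <- character(0)
  members <- vector("list", length(composition))
  avail <- pool
  for (j in seq_along(composition)) {
    cand <- which(avail$expertise_class == composition[j])
    if (length(cand) == 0)
      stop("pool exhausted for expertise class '", composition[j], "'")
    pick <- cand[sample.int(length(cand), 1)]
    members[[j]] <- avail[pick, , drop = FALSE]
    picked <- c(picked, avail$person_id[pick])
    avail <- avail[-pick, , drop = FALSE]
  }
  out <- list()
  if (is.null(start)) {
    starter <- sample_person(1, config, id_prefix = paste0(chain_id, "_start"))
    current <- draw_independent_judgment(starter, items, config)
    out[[1]] <- data.frame(
      chain_id = chain_id, position = 1L, person_id = starter$person_id,
      item_id = items$item_id, presented_judgment = NA_real_,
      change_probability = NA_real_, change_decision = NA_integer_,
      anchor_shift = NA_real_, judgment = current, stringsAsFactors = FALSE)
  } else {
    current <- rep_len(start, nrow(items))
  }
  for (j in seq_along(composition)) {
    step <- sequential_step(members[[j]], items, current, config)
    out[[length(out) + 1]] <- data.frame(chain_id = chain_id,
                                         position = j + 1L, step,
                                         stringsAsFactors = FALSE)
    current <- step$judgment
  }
  list(trials = do.call(rbind, out), used = picked)
}
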