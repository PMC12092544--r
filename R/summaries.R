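# Dependent-variable layer: the summary statistics computed from trial and
# crowd tables -- change probability, change magnitude, accuracy, improvement,
# relative accuracy -- plus expertise proxies, classification, the single-step
# probe, and chain-composition analysis.
#
# Aggregation order is fixed: average over items within each contributor
# first, then over contributors. Dispersion is reported as the SD across
# contributors together with a 99% normal-theory confidence interval of the
# mean.

.CI_Z <- stats::qnorm(0.995)

#' Judgment accuracy (absolute error)
#'
#' |judgment - truth|; lower is more accurate. With truth 0 this is simply the
#' absolute judgment.
#'
#' @param judgment,truth Finite numeric vectors.
#' @return Non-negative numeric vector.
#' @export
accuracy <- function(judgment, truth = 0) {
  stopifnot(all(is.finite(judgment)), all(is.finite(truth)))
  abs(judgment - truth)
}

#' Relative judgment accuracy in percent
#'
#' 100 * |judgment - truth| / truth, defined for positive truths; used to make
#' items with different answer magnitudes comparable.
#'
#' @inheritParams accuracy
#' @return Non-negative numeric vector (percent).
#' @export
relative_accuracy <- function(judgment, truth) {
  stopifnot(all(is.finite(judgment)), all(is.finite(truth)))
  if (any(truth <= 0)) stop("relative accuracy requires truth > 0")
  100 * abs(judgment - truth) / truth
}

#' Change magnitude of an adjusted judgment
#'
#' |revised - presented|, defined only for trials where the contributor
#' decided to adjust; maintained trials are excluded by contract.
#'
#' @param presented,revised Finite numeric vectors.
#' @param decision Optional 0/1 vector; any 0 raises an error.
#' @return Non-negative numeric vector.
#' @export
change_magnitude <- function(presented, revised, decision = NULL) {
  stopifnot(all(is.finite(presented)), all(is.finite(revised)))
  if (!is.null(decision) && any(decision == 0))
    stop("change magnitude is defined only for adjusted (decision = 1) trials")
  abs(revised - presented)
}

#' Improvement of an adjusted judgment
#'
#' accuracy(presented) - accuracy(revised): positive when the adjustment moved
#' the judgment closer to the truth, negative when it worsened it.
#'
#' @inheritParams change_magnitude
#' @param truth Correct answer(s).
#' @return Numeric vector.
#' @export
improvement <- function(presented, revised, truth = 0, decision = NULL) {
  if (!is.null(decision) && any(decision == 0))
    stop("improvement is defined only for adjusted (decision = 1) trials")
  accuracy(presented, truth) - accuracy(revised, truth)
}

#' Expertise proxy from independent judgments
#'
#' Mean judgment accuracy (mean absolute error) over a contributor's first
#' `k_first` independent judgments; smaller values indicate higher expertise.
#' This is the observable stand-in for the latent expertise parameter.
#'
#' @param judgments Numeric vector of one person's independent judgments, in
#'   item order.
#' @param truths Matching correct answers (recycled).
#' @param k_first How many leading judgments enter the proxy.
#' @return Non-negative scalar.
#' @export
expertise_proxy <- function(judgments, truths = 0, k_first = 20) {
  if (length(judgments) < k_first)
    stop("need at least ", k_first, " judgments for the expertise proxy")
  idx <- seq_len(k_first)
  mean(accuracy(judgments[idx], rep_len(truths, length(judgments))[idx]))
}

#' Classify contributors by expertise proxy
#'
#' Standardizes the proxies (an error score: smaller = better) and labels
#' contributors `"high"` when their error is more than 1 SD below the mean,
#' `"average"` when within 1 SD of the mean, and `"low"` otherwise. The
#' labels are invariant to affine rescaling of the proxies; with zero
#' variance everyone is `"average"`.
#'
#' @param proxies Numeric vector of proxy error scores (length >= 2).
#' @return Character vector of labels `"high"`, `"average"`, `"low"`.
#' @export
classify_expertise <- function(proxies) {
  stopifnot(is.numeric(proxies), length(proxies) >= 2, all(is.finite(proxies)))
  s <- stats::sd(proxies)
  if (s == 0) return(rep("average", length(proxies)))
  z <- (proxies - mean(proxies)) / s
  ifelse(z < -1, "high", ifelse(z <= 1, "average", "low"))
}

# mean/sd/99% CI helper over a per-person vector.
.msd <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else NA_real_
  half <- if (n > 1) .CI_Z * s / sqrt(n) else NA_real_
  data.frame(mean = m, sd = s, ci_lower = m - half, ci_upper = m + half, n = n)
}

# Average x over items within each person, then summarize across persons.
.person_then_pop <- function(x, person) {
  per <- tapply(x, person, mean)
  .msd(as.numeric(per))
}

#' Per-position summaries of a chain trial table
#'
#' Computes, for every chain position, the mean, SD, and 99% CI of
#' \itemize{
#'   \item change probability (positions >= 2),
#'   \item change magnitude (adjusted trials only),
#'   \item judgment accuracy (absolute error, all positions),
#' }
#' aggregating over items within each contributor first and then across
#' contributors.
#'
#' @param trials Chain trial table as produced by [simulate_chain()] /
#'   [simulate_experiment()].
#' @param items Item table supplying the truths.
#' @return Data frame with columns `position`, `statistic`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`, `n`; attribute `aggregation` records the order.
#' @export
position_summaries <- function(trials, items) {
  need <- c("chain_id", "position", "person_id", "item_id", "judgment")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  truth <- items$truth[match(trials$item_id, items$item_id)]
  if (any(is.na(truth))) stop("trial table references unknown items")
  person_key <- paste(trials$chain_id, trials$person_id)
  rows <- list()
  for (pos in sort(unique(trials$position))) {
    at <- trials$position == pos
    acc <- .person_then_pop(accuracy(trials$judgment[at], truth[at]),
                            person_key[at])
    rows[[length(rows) + 1]] <- data.frame(position = pos,
                                           statistic = "accuracy", acc)
    if (pos > 1) {
      cp <- .person_then_pop(trials$change_probability[at], person_key[at])
      rows[[length(rows) + 1]] <- data.frame(position = pos,
                                             statistic = "change_probability", cp)
      ch <- at & trials$change_decision == 1L
      if (any(ch, na.rm = TRUE)) {
        ch[is.na(ch)] <- FALSE
        mag <- .person_then_pop(
          change_magnitude(trials$presented_judgment[ch], trials$judgment[ch]),
          person_key[ch])
        rows[[length(rows) + 1]] <- data.frame(position = pos,
                                               statistic = "change_magnitude", mag)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aggregation") <- "items within contributor, then contributors"
  out
}

#' Per-size summaries of crowd running averages
#'
#' For each crowd size n, the accuracy |running average - truth| of the
#' unweighted average of the first n members, averaged over items within each
#' crowd and then across crowds. Also reports the signed deviation
#' (running average - truth), which exposes bias that the absolute error
#' alone cannot.
#'
#' @param crowd Crowd table from [simulate_experiment()].
#' @param items Item table supplying the truths.
#' @return Data frame with columns `size`, `statistic` (`crowd_accuracy` or
#'   `crowd_signed_error`), `mean`, `sd`, `ci_lower`, `ci_upper`, `n`.
#' @export
crowd_summaries <- function(crowd, items) {
  need <- c("crowd_id", "member", "item_id", "judgment")
  miss <- setdiff(need, names(crowd))
  if (length(miss)) stop("crowd table lacks columns: ", paste(miss, collapse = ", "))
  truth <- items$truth[match(crowd$item_id, items$item_id)]
  if (any(is.na(truth))) stop("crowd table references unknown items")
  # cumulative mean per crowd x item in member order
  o <- order(crowd$crowd_id, crowd$item_id, crowd$member)
  cid <- crowd$crowd_id[o]
  iid <- crowd$item_id[o]
  jd <- crowd$judgment[o]
  tr <- truth[o]
  grp <- paste(cid, iid)
  runmean <- unlist(lapply(split(jd, factor(grp, levels = unique(grp))),
                           function(v) cumsum(v) / seq_along(v)),
                    use.names = FALSE)
  size <- unlist(lapply(rle(grp)$lengths, seq_len), use.names = FALSE)
  rows <- list()
  for (nn in sort(unique(size))) {
    at <- size == nn
    acc <- .person_then_pop(abs(runmean[at] - tr[at]), cid[at])
    rows[[length(rows) + 1]] <- data.frame(size = nn,
                                           statistic = "crowd_accuracy", acc)
    sgn <- .person_then_pop(runmean[at] - tr[at], cid[at])
    rows[[length(rows) + 1]] <- data.frame(size = nn,
                                           statistic = "crowd_signed_error", sgn)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aggregation") <- "items within crowd, then crowds"
  out
}

#' Single-step probe with fixed presented-judgment offsets
#'
#' For each contributor and each offset d, presents the judgment T_k + d for
#' one item, records the (deterministic) change probability, and estimates the
#' expected improvement conditional on adjusting by repeated draws from the
#' updated distribution. Contributors are classified by the expertise proxy
#' computed from `k_first` independent judgments on the supplied proxy items.
#'
#' @param persons Person data frame.
#' @param item One-row item data frame for the probed item.
#' @param offsets Numeric vector of presented-judgment offsets from the truth.
#' @param config A [population_config()].
#' @param proxy_items Item data frame used for the expertise proxy (first
#'   `k_first` rows are used).
#' @param reps Monte-Carlo repetitions per person x offset for the
#'   improvement estimate.
#' @param k_first Judgments entering the expertise proxy.
#' @return List with `detail` (per person x offset) and `by_class` (per
#'   expertise class x offset mean change probability and improvement).
#' @export
probe_single_step <- function(persons, item, offsets, config,
                              proxy_items = NULL, reps = 100, k_first = 20) {
  stopifnot(nrow(item) == 1, all(is.finite(offsets)))
  n <- nrow(persons)
  if (is.null(proxy_items)) proxy_items <- sample_item(k_first, config)
  proxy <- vapply(seq_len(n), function(i) {
    jd <- draw_independent_judgment(persons[i, , drop = FALSE],
                                    proxy_items[seq_len(k_first), , drop = FALSE],
                                    config)
    expertise_proxy(jd, proxy_items$truth[seq_len(k_first)], k_first)
  }, numeric(1))
  cls <- classify_expertise(proxy)
  detail <- list()
  for (i in seq_len(n)) {
    p1 <- persons[i, , drop = FALSE]
    for (d in offsets) {
      presented <- item$truth + d
      p <- change_probability(p1, item, presented, config)
      spec <- updated_distribution(p1, item, presented, config)
      revised <- .draw_from_spec(spec[rep(1, reps), , drop = FALSE])
      imp <- mean(improvement(presented, revised, item$truth))
      detail[[length(detail) + 1]] <- data.frame(
        person_id = p1$person_id, expertise = p1$expertise,
        expertise_proxy = proxy[i], expertise_class = cls[i],
        offset = d, change_probability = p, mean_improvement = imp,
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  agg <- stats::aggregate(
    cbind(change_probability, mean_improvement) ~ expertise_class + offset,
    data = detail, FUN = mean)
  list(detail = detail, by_class = agg)
}

#' Chain-composition experiment
#'
#' Samples a pool of contributors, classifies them by the expertise proxy, and
#' simulates chains whose later positions follow prescribed expertise-class
#' compositions (e.g. expert-expert vs. novice-expert). Persons are consumed
#' without replacement, so no contributor appears in two chains.
#'
#' @param config A [population_config()].
#' @param items Item data frame (the proxy uses the first `k_first` items).
#' @param compositions Named list of class-label vectors, one entry per
#'   composition, each of length chain_length - 1.
#' @param n_chains_each Chains per composition.
#' @param pool_size Number of contributors sampled and classified.
#' @param start Passed to [simulate_composed_chain()].
#' @param k_first Judgments entering the expertise proxy.
#' @return List with `trials` (all composed-chain records plus a
#'   `composition` column), `pool` (classified roster), and `final_accuracy`
#'   (per composition: mean, sd, 99% CI of the final-position absolute error,
#'   items averaged within chain first).
#' @export
composition_experiment <- function(config, items, compositions,
                                   n_chains_each = 100, pool_size = 2000,
                                   start = NULL, k_first = 20) {
  stopifnot(inherits(config, "population_config"), length(compositions) >= 1,
            !is.null(names(compositions)))
  pool <- sample_person(pool_size, config, id_prefix = "pool_p")
  proxy <- vapply(seq_len(pool_size), function(i) {
    jd <- draw_independent_judgment(pool[i, , drop = FALSE],
                                    items[seq_len(k_first), , drop = FALSE],
                                    config)
    expertise_proxy(jd, items$truth[seq_len(k_first)], k_first)
  }, numeric(1))
  pool$expertise_proxy <- proxy
  pool$expertise_class <- classify_expertise(proxy)
  avail <- pool
  all_trials <- list()
  for (nm in names(compositions)) {
    for (r in seq_len(n_chains_each)) {
      res <- simulate_composed_chain(compositions[[nm]], avail, items, config,
                                     chain_id = sprintf("%s_%03d", nm, r),
                                     start = start)
      avail <- avail[!avail$person_id %in% res$used, , drop = FALSE]
      res$trials$composition <- nm
      all_trials[[length(all_trials) + 1]] <- res$trials
    }
  }
  trials <- do.call(rbind, all_trials)
  truth <- items$truth[match(trials$item_id, items$item_id)]
  final_pos <- max(trials$position)
  rows <- list()
  for (nm in names(compositions)) {
    at <- trials$composition == nm & trials$position == final_pos
    acc <- .person_then_pop(accuracy(trials$judgment[at], truth[at]),
                            trials$chain_id[at])
    rows[[length(rows) + 1]] <- data.frame(composition = nm, acc)
  }
  final_accuracy <- do.call(rbind, rows)
  rownames(final_accuracy) <- NULL
  list(trials = trials, pool = pool, final_accuracy = final_accuracy)
}
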