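#' Rank a candidate pool by worst-case risk
#'
#' Evaluates every pool member's evaluation value `J`
#' ([evaluate_candidate()]) and returns the ascending ranking.  In
#' `"single_pass"` mode (default) every candidate is scored against the
#' fixed training set and the pool is sorted by `J` (ties broken by
#' candidate id).  In `"sequential"` mode the remaining candidates are
#' re-evaluated after each acceptance: the current minimizer is moved into
#' the training set (its non-experimental positives committed to `+1`,
#' carrying their confidence weights) and its `J` at removal time is
#' recorded, so the ranking reflects the one-by-one growth of the training
#' set.
#'
#' @param pool a [labeled_set()] of candidates, each with at least one
#'   non-experimental positive.
#' @param train a [labeled_set()] of certain samples.
#' @param refs a [reference_sets()]; defaults to `reference_sets(train)`.
#' @param params a [confidence_params()].
#' @param config a [risk_config()].
#' @param mode `"single_pass"` or `"sequential"`.
#' @return object of class `pneaselect_ranking`: list with `ordered`
#'   (candidate ids ascending by `J`), `j_values`, `weights` (per-candidate
#'   weight rows, aligned with `ordered`), `mode`.
#' @export
rank_pool <- function(pool, train, refs = reference_sets(train),
                      params = confidence_params(), config = risk_config(),
                      mode = c("single_pass", "sequential")) {
  mode <- match.arg(mode)
  if (length(pool) == 0L) stop("empty candidate pool")
  has_ne <- apply(pool$status, 1L, function(s) any(s %in% nonexp_types()))
  if (any(!has_ne))
    stop("pool candidate(s) without a non-experimental positive: ",
         paste(head(pool$ids[!has_ne], 5L), collapse = ", "))
  W <- weight_matrix(pool, refs, params)
  eval_one <- function(i, cur_train) {
    ev <- tryCatch(
      evaluate_candidate(list(x = pool$features[i, ],
                              status = pool$status[i, ],
                              weights = W[i, ]),
                         cur_train, config = config),
      error = function(e) stop("candidate '", pool$ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
    ev$J
  }
  n <- length(pool)
  if (mode == "single_pass") {
    j <- vapply(seq_len(n), eval_one, numeric(1L), cur_train = train)
    ord <- order(j, pool$ids)
  } else {
    remaining <- seq_len(n)
    ord <- integer(0)
    j <- numeric(n)
    cur <- train
    while (length(remaining) > 0L) {
      js <- vapply(remaining, eval_one, numeric(1L), cur_train = cur)
      pick <- remaining[order(js, pool$ids[remaining])[1L]]
      j[pick] <- js[match(pick, remaining)]
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
      cur <- bind_labeled_sets(cur, commit_candidates(pool[pick], W[pick, ,
                                                                   drop = FALSE]))
    }
  }
  structure(list(ordered = pool$ids[ord],
                 j_values = unname(j[ord]),
                 weights = W[ord, , drop = FALSE],
                 mode = mode),
            class = "pneaselect_ranking")
}

# Commit pool candidates as training samples: non-experimental positives
# become experimental-grade +1 labels but keep their confidence weights.
commit_candidates <- function(subset, weights) {
  status <- subset$status
  status[status %in% nonexp_types()] <- "experimental"
  labeled_set(subset$features, status, locations = subset$locations,
              ids = subset$ids, weights = weights,
              require_positive = FALSE)
}

#' Relative change rates of ascending evaluation values
#'
#' For the ascending evaluation values `J_1 <= ... <= J_n`, the change rate
#' of position `i` is `r_i = (J_{i+1} - J_i) / J_i`, the relative growth of
#' the evaluation value toward the next-ranked candidate; it is undefined
#' (`NA`) for the last position.  A zero denominator is guarded by adding
#' `1e-12`, with a warning.
#'
#' @param j_values numeric vector sorted ascending, length >= 2.
#' @return numeric vector of length `length(j_values)`, last element `NA`.
#' @export
change_rates <- function(j_values) {
  n <- length(j_values)
  stopifnot(n >= 2L)
  if (is.unsorted(j_values, strictly = FALSE))
    stop("j_values must be sorted ascending")
  denom <- j_values[-n]
  if (any(denom == 0)) {
    warning("zero evaluation value in a denominator; adding 1e-12 guard")
    denom <- denom + 1e-12
  }
  c((j_values[-1L] - j_values[-n]) / denom, NA_real_)
}

#' Preferred proportion of the ranked pool
#'
#' Partitions the ascending ranking into `intervals` contiguous intervals,
#' each covering a proportion `step` of the pool (position `i` falls in
#' interval `ceiling(i * intervals / n)`; `n_t` counts the positions in
#' interval `t`).  The mean change rate `R_t` of each interval is compared
#' with the overall mean change rate `Rbar`: the preferred proportion
#' `theta* = step * t*`, where `t*` is the longest prefix of intervals
#' whose mean rates all stay at or below `Rbar`.  While the evaluation
#' values grow slowly the ranked candidates remain comparably useful; the
#' first interval whose change rate exceeds the overall level marks the
#' point past which additional candidates stop helping, and the selection
#' stops just before it.  If no interval exceeds `Rbar` the whole pool is
#' preferred (`theta* = 1`).
#'
#' @param ranking a `pneaselect_ranking` (or a list with `j_values`).
#' @param step proportion step `s` (default 0.10).
#' @param intervals number of intervals `T` (default 10); `step * intervals`
#'   must equal 1.
#' @return list of class `pneaselect_theta` with `theta_star` (in
#'   `{step, 2*step, ..., 1}`), `interval_rates` (`R_t`),
#'   `interval_counts` (`n_t`), `mean_rate` (`Rbar`), `rates` (per-position
#'   change rates), `step`, `intervals`.
#' @export
preferred_proportion <- function(ranking, step = 0.10, intervals = 10L) {
  stopifnot(abs(step * intervals - 1) < 1e-9)
  j <- ranking$j_values
  n <- length(j)
  if (n < 2L) stop("need at least two ranked candidates")
  if (n < intervals)
    warning("pool (", n, ") smaller than the number of intervals (",
            intervals, "); some intervals are empty and are treated as ",
            "stable")
  r <- change_rates(j)
  pos_interval <- ceiling(seq_len(n) * intervals / n)
  n_t <- tabulate(pos_interval, nbins = intervals)
  rbar <- mean(r, na.rm = TRUE)
  R_t <- vapply(seq_len(intervals), function(t) {
    rt <- r[pos_interval == t]
    rt <- rt[!is.na(rt)]
    if (length(rt) == 0L) NA_real_ else mean(rt)
  }, numeric(1L))
  # empty / rate-free intervals carry no evidence of instability
  stable <- is.na(R_t) | R_t <= rbar + 1e-12
  t_star <- if (stable[1L]) {
    run <- which(!stable)
    if (length(run) == 0L) intervals else run[1L] - 1L
  } else 1L  # theta* is at least one step
  structure(list(theta_star = step * t_star,
                 interval_rates = R_t, interval_counts = n_t,
                 mean_rate = rbar, rates = r,
                 step = step, intervals = intervals),
            class = "pneaselect_theta")
}

#' Select the preferred supplement from a candidate pool
#'
#' Runs [rank_pool()], determines the preferred proportion
#' ([preferred_proportion()]), and returns the top `theta*` fraction of the
#' ascending ranking as a training-ready [labeled_set()]: selected
#' non-experimental positives are committed to `+1` and carry their
#' posterior confidence as loss weights.  The selected count is
#' `floor(theta* * n + 0.5)` (at least 1).
#'
#' @inheritParams rank_pool
#' @param step,intervals passed to [preferred_proportion()].
#' @return list with `selected` (a [labeled_set()]), `ranking` (the full
#'   `pneaselect_ranking`), `theta` (the `pneaselect_theta`), `selected_ids`.
#' @export
select_supplement <- function(pool, train, refs = reference_sets(train),
                              params = confidence_params(),
                              config = risk_config(),
                              mode = "single_pass",
                              step = 0.10, intervals = 10L) {
  ranking <- rank_pool(pool, train, refs, params, config, mode = mode)
  theta <- preferred_proportion(ranking, step = step, intervals = intervals)
  n_sel <- max(1L, floor(theta$theta_star * length(ranking$ordered) + 0.5))
  sel_ids <- ranking$ordered[seq_len(n_sel)]
  idx <- match(sel_ids, pool$ids)
  selected <- commit_candidates(pool[idx],
                                ranking$weights[seq_len(n_sel), ,
                                                drop = FALSE])
  list(selected = selected, ranking = ranking, theta = theta,
       selected_ids = sel_ids)
}

#' Export a ranking as a table
#'
#' @param ranking a `pneaselect_ranking`.
#' @param theta optional `pneaselect_theta` to annotate intervals and the
#'   selection cut.
#' @return data frame with columns `id`, `rank`, `J`, `rate`, and (when
#'   `theta` is given) `interval`, `selected`.
#' @export
ranking_table <- function(ranking, theta = NULL) {
  n <- length(ranking$ordered)
  out <- data.frame(id = ranking$ordered, rank = seq_len(n),
                    J = ranking$j_values,
                    rate = change_rates(ranking$j_values),
                    stringsAsFactors = FALSE)
  if (!is.null(theta)) {
    out$interval <- ceiling(seq_len(n) * theta$intervals / n)
    out$selected <- seq_len(n) <=
      max(1L, floor(theta$theta_star * n + 0.5))
  }
  out
}
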