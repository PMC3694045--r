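#' Experiment configuration
#'
#' @param folds number of cross-validation folds (default 10).
#' @param randomizations number of fold-assignment randomizations (default
#'   10); reported standard deviations are over randomizations.
#' @param arms subset of `c("none", "top_theta", "all")`: train with no
#'   supplement, with the preferred proportion of the pool, or with the
#'   whole pool.
#' @param classifier `"kridge"` or `"mlknn"`.
#' @param classifier_args list of extra arguments for the trainer (e.g.
#'   `list(k = 5)` for `mlknn`).
#' @param params a [confidence_params()].
#' @param config a [risk_config()].
#' @param step,intervals selection proportion grid (defaults 0.10 / 10).
#' @param seed integer seed for the fold randomizations.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(folds = 10L, randomizations = 10L,
                              arms = c("none", "top_theta", "all"),
                              classifier = "kridge",
                              classifier_args = list(),
                              params = confidence_params(),
                              config = risk_config(),
                              step = 0.10, intervals = 10L,
                              seed = 1L) {
  stopifnot(folds >= 2L, randomizations >= 1L)
  arms <- match.arg(arms, c("none", "top_theta", "all"), several.ok = TRUE)
  classifier <- match.arg(classifier, c("kridge", "mlknn"))
  structure(list(folds = as.integer(folds),
                 randomizations = as.integer(randomizations),
                 arms = arms, classifier = classifier,
                 classifier_args = classifier_args,
                 params = params, config = config,
                 step = step, intervals = as.integer(intervals),
                 seed = as.integer(seed)),
            class = "pneaselect_experiment_config")
}

arm_supplement <- function(arm, train, pool, ec) {
  switch(arm,
         none = list(supplement = NULL, theta = NA_real_),
         top_theta = {
           sel <- select_supplement(pool, train,
                                    params = ec$params, config = ec$config,
                                    step = ec$step,
                                    intervals = ec$intervals)
           list(supplement = sel$selected, theta = sel$theta$theta_star)
         },
         all = {
           refs <- reference_sets(train)
           W <- weight_matrix(pool, refs, ec$params)
           list(supplement = commit_candidates(pool, W), theta = 1)
         })
}

fit_and_score <- function(train, supplement, test_features, true_sets, ec) {
  model <- do.call(retrain_with_supplement,
                   c(list(train = train, selected = supplement,
                          classifier = ec$classifier),
                     if (ec$classifier == "kridge")
                       list(config = ec$config),
                     ec$classifier_args))
  pred <- predict(model, test_features)
  metric_report(pred, true_sets)
}

metric_names <- c("accu", "mcc", "f1", "avgprec", "rloss", "coverage")

#' Repeated k-fold cross-validation with supplement arms
#'
#' Reproduces the select-retrain-evaluate protocol under repeated k-fold
#' cross-validation: in every fold the held-in portion of `train` is
#' augmented per arm (the selection is recomputed against that portion, so
#' no information from the held-out fold enters the ranking), the
#' classifier is retrained, and the held-out fold is scored with the six
#' multi-label metrics.  Per randomization the metrics are averaged over
#' folds; the report gives mean and standard deviation over the
#' randomizations.  Pool samples never contribute test proteins.
#'
#' @param train a [labeled_set()] of certain samples.
#' @param pool candidate [labeled_set()] (ids disjoint from `train`).
#' @param ec an [experiment_config()].
#' @return list of class `pneaselect_cv_report` with `summary` (data frame:
#'   arm, metric, mean, sd), `per_randomization` (arm x metric x
#'   randomization array), `theta_stars` (per randomization x fold, for the
#'   `top_theta` arm), `config`.
#' @export
run_cv_experiment <- function(train, pool, ec = experiment_config()) {
  if (length(intersect(train$ids, pool$ids)))
    stop("train and pool share protein ids")
  R <- ec$randomizations
  Fk <- ec$folds
  n <- length(train)
  if (Fk > n) stop("more folds than training samples")
  per <- array(NA_real_,
               dim = c(length(ec$arms), length(metric_names), R),
               dimnames = list(ec$arms, metric_names, NULL))
  thetas <- matrix(NA_real_, R, Fk)
  set.seed(ec$seed)
  for (r in seq_len(R)) {
    fold_id <- sample(rep_len(seq_len(Fk), n))
    fold_vals <- array(NA_real_,
                       dim = c(length(ec$arms), length(metric_names), Fk),
                       dimnames = list(ec$arms, metric_names, NULL))
    for (f in seq_len(Fk)) {
      tr <- train[fold_id != f]
      te <- train[fold_id == f]
      true_sets <- sign_to_sets(status_sign(te))
      for (arm in ec$arms) {
        sup <- arm_supplement(arm, tr, pool, ec)
        if (arm == "top_theta") thetas[r, f] <- sup$theta
        rep_ <- fit_and_score(tr, sup$supplement, te$features, true_sets,
                              ec)
        fold_vals[arm, , f] <- unlist(rep_[metric_names])
      }
    }
    per[, , r] <- apply(fold_vals, c(1L, 2L), mean)
  }
  mean_ <- apply(per, c(1L, 2L), mean)
  sd_ <- apply(per, c(1L, 2L), sd)
  summary <- data.frame(
    arm = rep(ec$arms, times = length(metric_names)),
    metric = rep(metric_names, each = length(ec$arms)),
    mean = as.vector(mean_), sd = as.vector(sd_),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, per_randomization = per,
                 theta_stars = thetas, config = ec),
            class = "pneaselect_cv_report")
}

#' @export
print.pneaselect_cv_report <- function(x, ...) {
  ec <- x$config
  cat(sprintf("Cross-validation report: %d randomizations x %d folds\n",
              ec$randomizations, ec$folds))
  for (arm in unique(x$summary$arm)) {
    s <- x$summary[x$summary$arm == arm, ]
    cat(sprintf("  %-9s %s\n", arm, paste(
      sprintf("%s %.4f+/-%.4f", s$metric, s$mean, s$sd), collapse = " ")))
  }
  invisible(x)
}

#' Single train/test evaluation with supplement arms
#'
#' The training set is augmented per arm (selection computed against the
#' whole training set) and the fitted classifier is scored once on the
#' independent test set.
#'
#' @param train,pool,ec as in [run_cv_experiment()].
#' @param test a [labeled_set()] with true labels, ids disjoint from both.
#' @return list of class `pneaselect_test_report` with `reports` (one
#'   `pneaselect_metric_report` per arm), `theta_stars` (per arm),
#'   `selected_ids` (for the `top_theta` arm), `config`.
#' @export
run_independent_test <- function(train, pool, test,
                                 ec = experiment_config()) {
  ids <- c(train$ids, pool$ids, test$ids)
  if (anyDuplicated(ids))
    stop("train, pool and test must have disjoint protein ids")
  true_sets <- sign_to_sets(status_sign(test))
  reports <- list()
  thetas <- setNames(rep(NA_real_, length(ec$arms)), ec$arms)
  selected_ids <- NULL
  set.seed(ec$seed)
  for (arm in ec$arms) {
    sup <- arm_supplement(arm, train, pool, ec)
    thetas[[arm]] <- sup$theta
    if (arm == "top_theta" && !is.null(sup$supplement))
      selected_ids <- sup$supplement$ids
    reports[[arm]] <- fit_and_score(train, sup$supplement, test$features,
                                    true_sets, ec)
  }
  structure(list(reports = reports, theta_stars = thetas,
                 selected_ids = selected_ids, config = ec),
            class = "pneaselect_test_report")
}

#' @export
print.pneaselect_test_report <- function(x, ...) {
  for (arm in names(x$reports)) {
    cat(sprintf("  %-9s ", arm))
    print(x$reports[[arm]])
  }
  invisible(x)
}
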