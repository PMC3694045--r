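#' Multi-label k-nearest-neighbour baseline
#'
#' Generic neighbour-vote classifier: the score of label `j` at a query is
#' the Laplace-smoothed fraction of the `k` nearest training samples
#' (Euclidean distance, distance ties broken by training index) that are
#' positive for `j`: `(votes + 1) / (k + 2)`, always in `(0, 1)`.  A label
#' is predicted when its score exceeds 0.5.  The classifier is
#' weight-unaware; supplement samples participate with their hard labels.
#'
#' @param train a [labeled_set()].
#' @param k number of neighbours (`1 <= k <= n`).
#' @return model of class `pneaselect_mlknn`.
#' @export
train_mlknn <- function(train, k = 5L) {
  n <- length(train)
  stopifnot(k >= 1L)
  if (k > n) stop("k = ", k, " exceeds the training size ", n)
  structure(list(features = train$features, signs = status_sign(train),
                 locations = train$locations, k = as.integer(k)),
            class = "pneaselect_mlknn")
}

#' @export
predict.pneaselect_mlknn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  Q <- ncol(object$signs)
  scores <- matrix(0, n, Q, dimnames = list(rownames(newdata),
                                            object$locations))
  pos <- object$signs > 0
  for (i in seq_len(n)) {
    d <- colSums((t(object$features) - newdata[i, ])^2)
    nb <- order(d)[seq_len(object$k)]  # order() breaks ties by index
    votes <- colSums(pos[nb, , drop = FALSE])
    scores[i, ] <- (votes + 1) / (object$k + 2)
  }
  predict_labels(scores, threshold = 0.5)
}

#' Weight-aware kernel ridge one-vs-rest baseline
#'
#' One regularized kernel least-squares scorer per label, reusing the risk
#' model's solver ([fit_weighted_rls()]); per-(sample, label) loss weights
#' are honoured when `use_weights` is `TRUE`, so supplement samples with
#' uncertain labels contribute proportionally to their confidence.  A label
#' is predicted when its real-valued score exceeds 0.
#'
#' @param train a [labeled_set()] (weights taken from the set when
#'   present).
#' @param config a [risk_config()].
#' @param use_weights honour per-label weights (default `TRUE`).
#' @return model of class `pneaselect_kridge`.
#' @export
train_kernel_ovr <- function(train, config = risk_config(),
                             use_weights = TRUE) {
  w <- if (use_weights) set_weights(train) else NULL
  fit <- fit_weighted_rls(train$features, status_sign(train), w, config)
  structure(list(fit = fit, locations = train$locations),
            class = "pneaselect_kridge")
}

#' @export
predict.pneaselect_kridge <- function(object, newdata, ...) {
  scores <- predict(object$fit, newdata)
  colnames(scores) <- object$locations
  predict_labels(scores, threshold = 0)
}

#' Turn a score matrix into a prediction result
#'
#' Labels whose score exceeds `threshold` form the predicted set; when no
#' label clears it the top-ranked label is emitted so every prediction is
#' non-empty.  Ranks break score ties by label index.
#'
#' @param scores `n x Q` score matrix.
#' @param threshold decision threshold.
#' @return list of class `pneaselect_prediction` with `label_sets`,
#'   `scores`, `ranks`.
#' @export
predict_labels <- function(scores, threshold = 0) {
  scores <- as.matrix(scores)
  ranks <- t(apply(scores, 1L, score_ranks))
  sets <- lapply(seq_len(nrow(scores)), function(i) {
    s <- which(unname(scores[i, ]) > threshold)
    if (length(s) == 0L) s <- which(unname(ranks[i, ]) == 1L)
    s
  })
  structure(list(label_sets = sets, scores = scores, ranks = ranks),
            class = "pneaselect_prediction")
}

#' Retrain a classifier on the training set plus a supplement
#'
#' @param train a [labeled_set()].
#' @param selected supplement [labeled_set()] (e.g.
#'   `select_supplement(...)$selected`), or `NULL` for no supplement.
#' @param classifier `"kridge"` or `"mlknn"`.
#' @param ... passed to the trainer ([train_kernel_ovr()] /
#'   [train_mlknn()]).
#' @return the fitted model.
#' @export
retrain_with_supplement <- function(train, selected = NULL,
                                    classifier = c("kridge", "mlknn"), ...) {
  classifier <- match.arg(classifier)
  full <- if (is.null(selected) || length(selected) == 0L) train
          else bind_labeled_sets(train, selected)
  switch(classifier,
         kridge = train_kernel_ovr(full, ...),
         mlknn = train_mlknn(full, ...))
}
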