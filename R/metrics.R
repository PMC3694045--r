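#' Pooled confusion counts over all (sample, label) decisions
#'
#' Every (sample, label) pair contributes one decision; counts are pooled
#' over all `n * Q` pairs, which matches the locative-protein counting
#' convention (a protein in `N` locations contributes `N` positive
#' decisions).
#'
#' @param predicted_sets list of integer vectors (predicted label indices
#'   per sample, subsets of `1..Q`).
#' @param true_sets list of integer vectors (true label indices).
#' @param Q number of labels.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(predicted_sets, true_sets, Q) {
  stopifnot(length(predicted_sets) == length(true_sets))
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(true_sets)) {
    p <- predicted_sets[[i]]
    t <- true_sets[[i]]
    if (length(c(p, t)) && any(c(p, t) < 1L | c(p, t) > Q))
      stop("label index outside 1..Q at sample ", i)
    tp <- tp + length(intersect(p, t))
    fp <- fp + length(setdiff(p, t))
    fn <- fn + length(setdiff(t, p))
    tn <- tn + Q - length(union(p, t))
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Global accuracy, MCC and F1 from pooled counts
#'
#' `Accu = (TP + TN) / (TP + FP + TN + FN)`;
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, 0 with a
#' warning when the denominator vanishes;
#' `F1 = 2TP / (2TP + FP + FN)`, 0 when no positives exist on either side.
#'
#' @param counts named vector from [confusion_counts()].
#' @return named numeric vector `c(accu, mcc, f1)`.
#' @export
global_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- tp + fp + tn + fn
  stopifnot(total > 0)
  accu <- (tp + tn) / total
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) {
    warning("degenerate confusion counts; MCC set to 0")
    0
  } else (tp * tn - fp * fn) / mden
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accu = accu, mcc = mcc, f1 = f1)
}

# ranks from scores: rank 1 = highest score, score ties broken by label
# index (lower index ranks better)
score_ranks <- function(scores) {
  rank(-scores, ties.method = "first")
}

#' Multi-label ranking metrics
#'
#' From per-(sample, label) confidence scores and the true label sets:
#' average precision (`avgprec`) averages, over the relevant labels of each
#' sample, the precision of the rank prefix ending at that label; ranking
#' loss (`rloss`) is the per-sample fraction of (relevant, irrelevant)
#' label pairs ranked in the wrong order; coverage is the mean over samples
#' of the worst rank of a relevant label minus 1.  Ranks break score ties
#' by label index.
#'
#' @param scores `n x Q` numeric score matrix.
#' @param true_sets list of non-empty integer vectors of true label
#'   indices.
#' @param Q number of labels (defaults to `ncol(scores)`).
#' @return named numeric vector `c(avgprec, rloss, coverage)`.
#' @export
ranking_metrics <- function(scores, true_sets, Q = ncol(scores)) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(true_sets) == n, ncol(scores) == Q)
  ap <- rl <- cov <- numeric(n)
  for (i in seq_len(n)) {
    t <- true_sets[[i]]
    if (length(t) == 0L)
      stop("sample ", i, " has an empty true label set; ranking loss is ",
           "undefined")
    r <- score_ranks(scores[i, ])
    rel_ranks <- r[t]
    ap[i] <- mean(vapply(rel_ranks, function(rr)
      sum(rel_ranks <= rr) / rr, numeric(1L)))
    irr <- setdiff(seq_len(Q), t)
    rl[i] <- if (length(irr) == 0L) 0 else
      sum(outer(rel_ranks, r[irr], ">")) / (length(t) * length(irr))
    cov[i] <- max(rel_ranks) - 1
  }
  c(avgprec = mean(ap), rloss = mean(rl), coverage = mean(cov))
}

#' Full metric report for a prediction result
#'
#' @param pred a `pneaselect_prediction` (see [predict_labels()]), or a
#'   list with `label_sets` and `scores`.
#' @param true_sets list of true label index sets.
#' @param Q number of labels.
#' @return list of class `pneaselect_metric_report` with `counts` and the
#'   six metrics `accu`, `mcc`, `f1`, `avgprec`, `rloss`, `coverage`.
#' @export
metric_report <- function(pred, true_sets, Q = ncol(pred$scores)) {
  counts <- confusion_counts(pred$label_sets, true_sets, Q)
  g <- global_metrics(counts)
  r <- ranking_metrics(pred$scores, true_sets, Q)
  structure(c(list(counts = counts), as.list(g), as.list(r)),
            class = "pneaselect_metric_report")
}

#' @export
print.pneaselect_metric_report <- function(x, ...) {
  cat(sprintf(
    "Accu %.4f | MCC %.4f | F1 %.4f | Avgprec %.4f | Rloss %.4f | Coverage %.4f\n",
    x$accu, x$mcc, x$f1, x$avgprec, x$rloss, x$coverage))
  invisible(x)
}

# true label index sets from a signed matrix
sign_to_sets <- function(signs) {
  lapply(seq_len(nrow(signs)), function(i) which(unname(signs[i, ]) > 0))
}
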