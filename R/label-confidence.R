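#' Confidence parameters for non-experimental labels
#'
#' @param priors named probabilities that a label of each non-experimental
#'   evidence type is the actual label, before looking at the feature
#'   vector.  Defaults reflect the relative strength of the three evidence
#'   qualifiers: 0.85 for "Probable", 0.80 for "Potential", 0.75 for
#'   "By similarity".
#' @param bandwidth Gaussian kernel bandwidth `sigma` shared by the Parzen
#'   estimates and the risk model: a positive number, or `"median"` to use
#'   the median pairwise Euclidean distance of the certain reference set.
#' @return a `confidence_params` list.
#' @export
confidence_params <- function(priors = c(probable = 0.85, potential = 0.80,
                                         by_similarity = 0.75),
                              bandwidth = "median") {
  if (!all(nonexp_types() %in% names(priors)))
    stop("priors must name probable, potential and by_similarity")
  priors <- priors[nonexp_types()]
  if (any(priors <= 0 | priors >= 1))
    stop("priors must lie strictly in (0, 1)")
  if (is.numeric(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive")
  structure(list(priors = priors, bandwidth = bandwidth),
            class = "pneaselect_confidence_params")
}

#' Median-heuristic kernel bandwidth
#'
#' @param features numeric matrix.
#' @return the median pairwise Euclidean distance (positive); falls back to
#'   1 when fewer than two distinct points are available.
#' @export
median_bandwidth <- function(features) {
  if (nrow(features) < 2L) return(1)
  m <- median(dist(features))
  if (!is.finite(m) || m <= 0) 1 else m
}

resolve_bandwidth <- function(params, reference_features) {
  if (identical(params$bandwidth, "median"))
    median_bandwidth(reference_features)
  else params$bandwidth
}

#' Parzen-window density estimate with a Gaussian kernel
#'
#' Average of `exp(-||x - p||^2 / (2 sigma^2))` over the reference points
#' `p` (the kernel's normalizing constant is omitted; it cancels in every
#' likelihood ratio this estimate feeds).  Returns 0 for an empty
#' reference set.
#'
#' @param x numeric query vector.
#' @param points numeric matrix of reference points (rows), possibly with
#'   zero rows.
#' @param bandwidth positive kernel width `sigma`.
#' @return nonnegative scalar.
#' @export
parzen_density <- function(x, points, bandwidth) {
  stopifnot(bandwidth > 0)
  points <- as.matrix(points)
  if (nrow(points) == 0L) return(0)
  d2 <- colSums((t(points) - as.numeric(x))^2)
  mean(exp(-d2 / (2 * bandwidth^2)))
}

#' Reference sets for posterior estimation
#'
#' @param certain_set [labeled_set()] of samples whose labels are all
#'   certain (the original experimentally annotated training set); used for
#'   the class-conditional density estimates.
#' @param nonexp_set optional [labeled_set()] of the non-experimentally
#'   annotated pool, retained for provenance; it takes no part in the
#'   density estimates.
#' @return a `reference_sets` list.
#' @export
reference_sets <- function(certain_set, nonexp_set = NULL) {
  stopifnot(inherits(certain_set, "pnea_labeled_set"))
  if (length(certain_set) == 0L)
    stop("certain reference set is empty")
  if (any(!status_certain(certain_set)))
    stop("certain_set contains non-experimental statuses")
  structure(list(certain_set = certain_set, nonexp_set = nonexp_set),
            class = "pneaselect_reference_sets")
}

#' Posterior probability that a non-experimental label is the actual label
#'
#' Bayes combination of the evidence-type prior with Parzen-window
#' class-conditional density estimates taken over the certain reference
#' set: with prior `p` and densities `d_own` (certain samples sharing the
#' annotated positive at `label`) and `d_opp` (certain samples negative
#' there),
#' `posterior = p * d_own / (p * d_own + (1 - p) * d_opp)`.
#' When both densities vanish, or when one class has no certain samples at
#' all for the label, the bare prior is returned (with a warning in the
#' empty-class case, controlled by `fallback`).
#'
#' @param x feature vector of the sample carrying the non-experimental
#'   label.
#' @param label location name or column index.
#' @param evidence_type one of `"probable"`, `"potential"`,
#'   `"by_similarity"`.
#' @param refs a [reference_sets()].
#' @param params a [confidence_params()].
#' @param fallback what to do when the certain set has no positives or no
#'   negatives for `label`: `"prior"` (default) returns the bare prior with
#'   a warning, `"error"` stops.
#' @return probability in `[0, 1]`.
#' @export
posterior_nonexp <- function(x, label, evidence_type, refs, params,
                             fallback = c("prior", "error")) {
  fallback <- match.arg(fallback)
  stopifnot(evidence_type %in% nonexp_types())
  prior <- unname(params$priors[[evidence_type]])
  certain <- refs$certain_set
  j <- if (is.character(label)) match(label, certain$locations) else label
  if (is.na(j) || j < 1L || j > length(certain$locations))
    stop("unknown label: ", label)
  sign_j <- status_sign(certain)[, j]
  own <- certain$features[sign_j == 1L, , drop = FALSE]
  opp <- certain$features[sign_j == -1L, , drop = FALSE]
  if (nrow(own) == 0L || nrow(opp) == 0L) {
    msg <- paste0("no certain ", if (nrow(own) == 0L) "positives" else
                  "negatives", " for label '", certain$locations[j],
                  "'; falling back to the bare prior")
    if (fallback == "error") stop(msg)
    warning(msg)
    return(prior)
  }
  sigma <- resolve_bandwidth(params, certain$features)
  d_own <- parzen_density(x, own, sigma)
  d_opp <- parzen_density(x, opp, sigma)
  num <- prior * d_own
  den <- num + (1 - prior) * d_opp
  if (den == 0) return(prior)  # no density mass from either class
  num / den
}

#' Per-label loss weight of one sample
#'
#' Certain statuses (experimental positives and negatives) are fully
#' trusted and get weight 1; a non-experimental positive gets the
#' posterior probability that its annotation is the actual label.
#'
#' @param x feature vector of the sample.
#' @param status_row character vector of the sample's statuses over the
#'   location vocabulary.
#' @param refs a [reference_sets()].
#' @param params a [confidence_params()].
#' @return numeric weight vector in `[0, 1]`, aligned with `status_row`.
#' @export
label_weight <- function(x, status_row, refs, params) {
  vapply(seq_along(status_row), function(j) {
    s <- status_row[j]
    if (s %in% nonexp_types())
      posterior_nonexp(x, j, s, refs, params)
    else 1
  }, numeric(1L))
}

#' Loss-weight matrix of a labeled set
#'
#' Applies [label_weight()] row-wise.
#'
#' @param set a [labeled_set()].
#' @inheritParams label_weight
#' @return numeric `n x Q` matrix of weights.
#' @export
weight_matrix <- function(set, refs, params) {
  out <- matrix(1, length(set), length(set$locations),
                dimnames = dimnames(set$status))
  for (i in seq_len(length(set))) {
    js <- which(set$status[i, ] %in% nonexp_types())
    for (j in js)
      out[i, j] <- posterior_nonexp(set$features[i, ], j, set$status[i, j],
                                    refs, params)
  }
  out
}
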