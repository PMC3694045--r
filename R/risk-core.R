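#' Risk model configuration
#'
#' @param bandwidth Gaussian kernel width `sigma`, shared with the
#'   label-confidence posterior (`"median"` resolves against the training
#'   features at fit time).
#' @param regularization positive `gamma` multiplying the squared RKHS norm
#'   of each per-label scorer.
#' @param enumeration_cap maximum number `m` of non-experimental
#'   coordinates enumerated per candidate (`2^m` assignments; default 12).
#' @return a `risk_config` list.
#' @export
risk_config <- function(bandwidth = "median", regularization = 0.1,
                        enumeration_cap = 12L) {
  if (is.numeric(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive")
  stopifnot(regularization > 0, enumeration_cap >= 1L)
  structure(list(bandwidth = bandwidth, regularization = regularization,
                 enumeration_cap = as.integer(enumeration_cap)),
            class = "pneaselect_risk_config")
}

#' Gaussian Gram matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / (2 sigma^2))`; the diagonal of a
#' self-Gram matrix is all ones.
#'
#' @param features_a,features_b numeric matrices with matching column
#'   count; `features_b` defaults to `features_a`.
#' @param bandwidth positive kernel width `sigma`.
#' @return `nrow(features_a) x nrow(features_b)` matrix.
#' @export
gram_matrix <- function(features_a, features_b = features_a, bandwidth) {
  stopifnot(bandwidth > 0)
  a <- as.matrix(features_a)
  b <- as.matrix(features_b)
  if (ncol(a) != ncol(b)) stop("feature dimensions differ")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # guard rounding on (near-)identical rows
  exp(-d2 / (2 * bandwidth^2))
}

# Solve the weighted kernel RLS system for one label:
# minimize (1/N) (K a - t)' W (K a - t) + gamma a' K a,  W = diag(w).
# Symmetric form: with S = diag(sqrt(w)),
#   a = S (S K S + N gamma I)^{-1} S t,
# solved by Cholesky with a small jitter retry for near-singular systems.
solve_wkrls <- function(K, t, w, gamma) {
  n <- nrow(K)
  s <- sqrt(w)
  A <- (s * K) * rep(s, each = n)   # diag(s) K diag(s)
  diag(A) <- diag(A) + n * gamma
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    diag(A) <- diag(A) + 1e-10
    R <- tryCatch(chol(A), error = function(e)
      stop("singular kernel system; increase the regularization gamma"))
  }
  s * backsolve(R, forwardsolve(t(R), s * t))
}

#' Fit a weighted, regularized kernel least-squares model
#'
#' Minimizes, over functions `f_1..f_Q` in the RKHS of the Gaussian kernel,
#' the per-sample-averaged weighted quadratic loss plus an RKHS-norm
#' penalty:
#' `(1/n) * sum_ij w_ij (f_j(x_i) - y_ij)^2 + gamma * sum_j ||f_j||^2`.
#' By the representer theorem each minimizer is a kernel expansion over the
#' training points, `f_j(x) = sum_i alpha_ij k(x, x_i)`; the expansion
#' coefficients solve, per label, `(W_j K + n gamma I) alpha_j = W_j y_j`
#' with `W_j = diag(w_.j)` (the stacked `Q`-label system is block diagonal,
#' the Kronecker product of the identity over labels with `K`).
#'
#' @param features `n x d` training features.
#' @param targets `n x Q` matrix over `{-1, +1}`.
#' @param weights `n x Q` matrix in `[0, 1]`; `NULL` means all ones.
#' @param config a [risk_config()].
#' @return object of class `pneaselect_wkrls` with elements `alpha`
#'   (`n x Q`), `features`, `gram`, `targets`, `weights`, `bandwidth`,
#'   `gamma`, `objective` (the attained objective value) and `misfit` (the
#'   weighted data-misfit part alone).
#' @export
fit_weighted_rls <- function(features, targets, weights = NULL, config) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  n <- nrow(features)
  stopifnot(n >= 1L, nrow(targets) == n)
  if (!all(targets %in% c(-1, 1)))
    stop("targets must be -1/+1")
  if (is.null(weights)) weights <- matrix(1, n, ncol(targets))
  weights <- as.matrix(weights)
  stopifnot(all(dim(weights) == dim(targets)),
            all(weights >= 0), all(weights <= 1))
  sigma <- if (identical(config$bandwidth, "median"))
    median_bandwidth(features) else config$bandwidth
  K <- gram_matrix(features, bandwidth = sigma)
  fit_weighted_rls_gram(K, targets, weights, config$regularization,
                        features = features, bandwidth = sigma)
}

# Gram-level fitting core, reused by candidate evaluation where K is
# assembled incrementally.
fit_weighted_rls_gram <- function(K, targets, weights, gamma,
                                  features = NULL, bandwidth = NULL) {
  n <- nrow(K)
  Q <- ncol(targets)
  alpha <- matrix(0, n, Q, dimnames = list(NULL, colnames(targets)))
  for (j in seq_len(Q))
    alpha[, j] <- solve_wkrls(K, targets[, j], weights[, j], gamma)
  Fhat <- K %*% alpha
  misfit <- sum(weights * (Fhat - targets)^2) / n
  penalty <- gamma * sum(alpha * (K %*% alpha))
  structure(list(alpha = alpha, features = features, gram = K,
                 targets = targets, weights = weights,
                 bandwidth = bandwidth, gamma = gamma,
                 fitted = Fhat, misfit = misfit,
                 objective = misfit + penalty),
            class = "pneaselect_wkrls")
}

#' @export
predict.pneaselect_wkrls <- function(object, newdata, ...) {
  if (is.null(object$features))
    stop("model was fitted at the Gram level; no features stored")
  Kx <- gram_matrix(as.matrix(newdata), object$features, object$bandwidth)
  Kx %*% object$alpha
}

#' Classification risk brought by one hypothesized candidate
#'
#' Appends the candidate (features `x`, hypothesized `+/-1` assignment
#' `assignment`, per-label weights `cand_weights`) to the training set and
#' returns the minimized objective of the weighted kernel RLS problem on
#' the augmented set -- the classification risk the candidate would bring
#' under that assignment.
#'
#' @param train a [labeled_set()] (its `weights` are honored; missing
#'   weights count as 1).
#' @param x candidate feature vector.
#' @param assignment numeric `+/-1` vector over the `Q` locations.
#' @param cand_weights numeric weights in `[0,1]` over the `Q` locations
#'   (1 on certain coordinates, posterior confidence on non-experimental
#'   ones).
#' @param config a [risk_config()].
#' @return nonnegative scalar risk.
#' @export
candidate_risk <- function(train, x, assignment, cand_weights, config) {
  sigma <- if (identical(config$bandwidth, "median"))
    median_bandwidth(train$features) else config$bandwidth
  feats <- rbind(train$features, matrix(x, nrow = 1L))
  K <- gram_matrix(feats, bandwidth = sigma)
  targets <- rbind(status_sign(train), assignment)
  weights <- rbind(set_weights(train), cand_weights)
  fit <- fit_weighted_rls_gram(K, targets, weights, config$regularization)
  fit$objective
}

feasible_assignments <- function(sign_row, uncertain_idx) {
  m <- length(uncertain_idx)
  base <- as.numeric(sign_row)
  if (m == 0L) return(list(base))
  # enumerate in lexicographic order with -1 before +1
  grid <- expand.grid(rep(list(c(-1, 1)), m))[, rev(seq_len(m)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    a <- base
    a[uncertain_idx] <- as.numeric(grid[r, ])
    a
  })
}

#' Worst-case evaluation of one candidate
#'
#' A candidate's actual label set is only partially known: certain
#' coordinates are pinned to their annotated signs while each
#' non-experimental positive may truly be `+1` or `-1`.  This enumerates
#' all `2^m` feasible assignments (`m` = number of non-experimental
#' coordinates), computes [candidate_risk()] for each, and returns the
#' evaluation value `J` = the maximum risk together with the attaining
#' assignment (ties resolved toward the lexicographically smallest
#' assignment, `-1` before `+1`).
#'
#' @param candidate list with elements `x` (feature vector), `status`
#'   (character status vector over the locations) and optionally `weights`
#'   (per-label weights; computed from `refs`/`params` when absent).
#' @param train a [labeled_set()].
#' @param refs a [reference_sets()] (used only when `candidate$weights` is
#'   absent).
#' @param params a [confidence_params()] (idem).
#' @param config a [risk_config()].
#' @return list of class `pneaselect_candidate_eval` with `J`,
#'   `worst_assignment`, `per_assignment_risks` (risk per enumerated
#'   assignment, names encode the assignment), `weights`.
#' @export
evaluate_candidate <- function(candidate, train, refs = NULL, params = NULL,
                               config = risk_config()) {
  status <- candidate$status
  uncertain <- which(status %in% nonexp_types())
  m <- length(uncertain)
  if (m > config$enumeration_cap)
    stop("candidate has ", m, " non-experimental labels; the enumeration ",
         "cap is ", config$enumeration_cap,
         " (no approximate maximization is provided)")
  sign_row <- ifelse(status != "negative", 1, -1)
  w <- candidate$weights
  if (is.null(w)) {
    if (is.null(refs) || is.null(params))
      stop("either candidate$weights or refs+params must be supplied")
    w <- label_weight(candidate$x, status, refs, params)
  }
  assigns <- feasible_assignments(sign_row, uncertain)
  risks <- vapply(assigns, function(a)
    candidate_risk(train, candidate$x, a, w, config), numeric(1L))
  names(risks) <- vapply(assigns, function(a)
    paste(ifelse(a > 0, "+", "-"), collapse = ""), character(1L))
  best <- which(risks == max(risks))[1L]  # first = lexicographically smallest
  structure(list(J = unname(risks[best]),
                 worst_assignment = assigns[[best]],
                 per_assignment_risks = risks,
                 weights = w),
            class = "pneaselect_candidate_eval")
}
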