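# Independent oracles used across the suite.  Each re-derives the quantity
# from its definition (explicit loops, numerical optimization, pair
# enumeration) without calling the package's computational path.

# Gaussian kernel, written out per entry
oracle_kernel <- function(x, y, sigma) exp(-sum((x - y)^2) / (2 * sigma^2))

# Written-out weighted kernel RLS objective over representer coefficients
# alpha (n x Q): (1/n) sum_ij w_ij (f_j(x_i) - y_ij)^2 + gamma sum_j a_j' K a_j
oracle_wkrls_objective <- function(alpha, K, targets, weights, gamma) {
  n <- nrow(K)
  Fhat <- K %*% alpha
  sum(weights * (Fhat - targets)^2) / n +
    gamma * sum(diag(t(alpha) %*% K %*% alpha))
}

# Direct numerical minimization of the objective (independent of the
# closed form); returns the attained objective value.
oracle_minimize_wkrls <- function(features, targets, weights, gamma, sigma) {
  n <- nrow(features)
  Q <- ncol(targets)
  K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    oracle_kernel(features[i, ], features[j, ], sigma)))
  fn <- function(par) oracle_wkrls_objective(matrix(par, n, Q), K,
                                             targets, weights, gamma)
  gr <- function(par) {
    alpha <- matrix(par, n, Q)
    G <- (2 / n) * K %*% (weights * (K %*% alpha - targets)) +
      2 * gamma * K %*% alpha
    as.vector(G)
  }
  opt <- optim(rep(0, n * Q), fn, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  opt$value
}

# Brute-force confusion counts by looping over every (sample, label) cell
oracle_counts <- function(predicted_sets, true_sets, Q) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(true_sets)) {
    for (q in seq_len(Q)) {
      p <- q %in% predicted_sets[[i]]
      t <- q %in% true_sets[[i]]
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Rank of each label: 1 = highest score, ties to the lower label index
oracle_ranks <- function(scores) {
  ord <- order(-scores, seq_along(scores))
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  r
}

# Ranking metrics by explicit pair/prefix enumeration
oracle_ranking <- function(scores, true_sets) {
  n <- nrow(scores)
  Q <- ncol(scores)
  ap <- rl <- cov <- numeric(n)
  for (i in seq_len(n)) {
    t <- true_sets[[i]]
    r <- oracle_ranks(scores[i, ])
    prec <- numeric(length(t))
    for (a in seq_along(t)) {
      rr <- r[t[a]]
      prec[a] <- sum(r[t] <= rr) / rr
    }
    ap[i] <- mean(prec)
    irr <- setdiff(seq_len(Q), t)
    wrong <- 0L
    for (a in t) for (b in irr) if (r[a] > r[b]) wrong <- wrong + 1L
    rl[i] <- if (length(irr)) wrong / (length(t) * length(irr)) else 0
    cov[i] <- max(r[t]) - 1
  }
  c(avgprec = mean(ap), rloss = mean(rl), coverage = mean(cov))
}

# Straightforward re-implementation of the amphiphilic pseudo amino acid
# composition: explicit loops, no shared code with pseaac_vector().
oracle_pseaac <- function(sequence, props_raw, lambda, weight) {
  aa <- c("A","R","N","D","C","E","Q","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  std <- lapply(props_raw, function(v) {
    v <- v[aa]
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  })
  f <- sapply(aa, function(a) sum(chars == a) / L)
  taus <- c()
  for (p in seq_along(std)) {
    for (j in seq_len(lambda)) {
      s <- 0
      for (i in seq_len(L - j))
        s <- s + std[[p]][chars[i]] * std[[p]][chars[i + j]]
      taus <- c(taus, s / (L - j))
    }
  }
  unname(c(f, weight * taus) / (1 + weight * sum(taus)))
}

# Random multi-label instance for metric tests
random_prediction_instance <- function(n, Q) {
  scores <- matrix(runif(n * Q), n, Q)
  true_sets <- lapply(seq_len(n), function(i)
    sort(sample.int(Q, sample.int(max(1L, Q - 1L), 1L))))
  pred_sets <- lapply(seq_len(n), function(i) {
    s <- which(runif(Q) > 0.5)
    if (length(s) == 0L) s <- sample.int(Q, 1L)
    s
  })
  list(scores = scores, true_sets = true_sets, pred_sets = pred_sets)
}

# Small random labeled set with certain statuses
random_certain_set <- function(n, Q, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feats <- matrix(rnorm(n * d), n, d)
  status <- matrix("negative", n, Q)
  for (i in seq_len(n))
    status[i, sample.int(Q, sample.int(min(2L, Q), 1L))] <- "experimental"
  labeled_set(feats, status, locations = paste0("loc", seq_len(Q)),
              ids = sprintf("S%03d", seq_len(n)))
}

random_sequence <- function(L) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               L, replace = TRUE), collapse = "")
}

# tolerance-based membership on the selection proportion grid
on_theta_grid <- function(theta, step = 0.1) {
  all(vapply(theta, function(t)
    is.na(t) || any(abs(t - step * seq_len(round(1 / step))) < 1e-9),
    logical(1)))
}
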