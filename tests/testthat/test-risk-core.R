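test_that("Gram matrices follow the Gaussian kernel entry-wise", {
  set.seed(31)
  A <- matrix(rnorm(12), 4, 3)
  K <- gram_matrix(A, bandwidth = 1.3)
  expect_equal(diag(K), rep(1, 4))
  expect_equal(K, t(K))
  for (i in 1:4) for (j in 1:4)
    expect_equal(K[i, j], oracle_kernel(A[i, ], A[j, ], 1.3),
                 tolerance = 1e-12)
  B <- matrix(rnorm(6), 2, 3)
  K2 <- gram_matrix(A, B, bandwidth = 0.7)
  for (i in 1:4) for (j in 1:2)
    expect_equal(K2[i, j], oracle_kernel(A[i, ], B[j, ], 0.7),
                 tolerance = 1e-12)
  # distant points decorrelate
  expect_lt(gram_matrix(matrix(0, 1, 1), matrix(50, 1, 1), 1)[1, 1], 1e-300)
  eig <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(eig > -1e-10))
})

test_that("heavy regularization shrinks the fit toward zero", {
  set.seed(8)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(sample(c(-1, 1), 10, TRUE), 5, 2)
  fit <- fit_weighted_rls(X, Y, NULL, risk_config(bandwidth = 1,
                                                  regularization = 1e8))
  expect_lt(max(abs(fit$fitted)), 1e-6)
  # objective approaches the zero-function misfit: per-sample average of
  # the summed per-label unit losses, (5 * 2) / 5
  expect_equal(fit$objective, 2, tolerance = 1e-5)
})

test_that("a single point is interpolated as regularization vanishes", {
  X <- matrix(c(0.3, -0.2), 1, 2)
  Y <- matrix(c(1, -1), 1, 2)
  fit <- fit_weighted_rls(X, Y, NULL, risk_config(bandwidth = 1,
                                                  regularization = 1e-10))
  expect_equal(as.numeric(fit$fitted), c(1, -1), tolerance = 1e-6)
})

test_that("the closed form matches direct numerical minimization", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    Q <- sample(2:4, 1)
    gamma <- sample(c(0.01, 0.1, 1), 1)
    X <- matrix(rnorm(n * 3), n, 3)
    Y <- matrix(sample(c(-1, 1), n * Q, TRUE), n, Q)
    W <- matrix(runif(n * Q), n, Q)
    fit <- fit_weighted_rls(X, Y, W, risk_config(bandwidth = 1.2,
                                                 regularization = gamma))
    oracle <- oracle_minimize_wkrls(X, Y, W, gamma, 1.2)
    expect_equal(fit$objective, oracle, tolerance = 1e-6)
  }
})

test_that("zero-weight labels stop influencing the misfit", {
  set.seed(13)
  X <- matrix(rnorm(8), 4, 2)
  Y <- matrix(sample(c(-1, 1), 8, TRUE), 4, 2)
  W <- matrix(1, 4, 2)
  W[2, 1] <- 0
  cfg <- risk_config(bandwidth = 1, regularization = 0.1)
  f1 <- fit_weighted_rls(X, Y, W, cfg)
  Y2 <- Y
  Y2[2, 1] <- -Y2[2, 1]  # flip the ignored target
  f2 <- fit_weighted_rls(X, Y2, W, cfg)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-12)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
})

make_toy_train <- function(n = 6, Q = 3, d = 2, seed = 1) {
  random_certain_set(n, Q, d, seed = seed)
}

test_that("candidate risk matches the objective-level oracle", {
  train <- make_toy_train(6, 3, 2, seed = 21)
  set.seed(22)
  x <- rnorm(2)
  assignment <- c(1, -1, 1)
  w <- c(0.8, 1, 0.6)
  cfg <- risk_config(bandwidth = 1.5, regularization = 0.1)
  got <- candidate_risk(train, x, assignment, w, cfg)
  oracle <- oracle_minimize_wkrls(rbind(train$features, x),
                                  rbind(status_sign(train), assignment),
                                  rbind(matrix(1, 6, 3), w),
                                  0.1, 1.5)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("risk under the penalty limit is the zero-function misfit", {
  train <- make_toy_train(5, 3, 2, seed = 33)
  w <- c(0.5, 1, 0.25)
  got <- candidate_risk(train, rnorm(2), c(1, -1, -1), w,
                        risk_config(bandwidth = 1, regularization = 1e9))
  # (f = 0): each label contributes its weight once, averaged over n+1
  expect_equal(got, (sum(matrix(1, 5, 3)) + sum(w)) / 6, tolerance = 1e-4)
})

test_that("duplicating a training point is the least risky hypothesis", {
  train <- make_toy_train(6, 3, 2, seed = 44)
  cfg <- risk_config(bandwidth = 1, regularization = 0.1)
  x <- train$features[1, ]
  truth <- status_sign(train)[1, ]
  risks <- vapply(list(truth, -truth, c(-1, 1, 1) * truth),
                  function(a) candidate_risk(train, x, a, rep(1, 3), cfg),
                  numeric(1))
  expect_true(all(risks[1] <= risks[-1]))
})

test_that("the worst case enumerates every feasible assignment", {
  train <- make_toy_train(6, 4, 2, seed = 55)
  cfg <- risk_config(bandwidth = 1, regularization = 0.1)
  set.seed(56)
  x <- rnorm(2)

  # m = 0: a fully certain candidate has a singleton feasible set
  cand0 <- list(x = x, status = c("experimental", "negative", "negative",
                                  "negative"), weights = rep(1, 4))
  ev0 <- evaluate_candidate(cand0, train, config = cfg)
  expect_length(ev0$per_assignment_risks, 1L)
  expect_equal(ev0$J, candidate_risk(train, x, c(1, -1, -1, -1),
                                     rep(1, 4), cfg))

  # m = 2: J equals the brute-force max over the 4 assignments
  w <- c(0.8, 1, 0.7, 1)
  cand2 <- list(x = x, status = c("probable", "negative", "potential",
                                  "negative"), weights = w)
  ev2 <- evaluate_candidate(cand2, train, config = cfg)
  expect_length(ev2$per_assignment_risks, 4L)
  byhand <- vapply(list(c(-1, -1, -1, -1), c(-1, -1, 1, -1),
                        c(1, -1, -1, -1), c(1, -1, 1, -1)),
                   function(a) candidate_risk(train, x, a, w, cfg),
                   numeric(1))
  expect_equal(ev2$J, max(byhand), tolerance = 1e-12)
  expect_true(all(ev2$J >= ev2$per_assignment_risks - 1e-15))
  # the reported worst assignment attains J
  expect_equal(candidate_risk(train, x, ev2$worst_assignment, w, cfg),
               ev2$J, tolerance = 1e-12)
})

test_that("J is invariant to enumeration order and caps at m = cap", {
  train <- make_toy_train(5, 4, 2, seed = 66)
  cfg <- risk_config(bandwidth = 1, regularization = 0.1)
  x <- train$features[2, ] + 0.1
  cand <- list(x = x,
               status = c("probable", "potential", "by_similarity",
                          "negative"),
               weights = c(0.9, 0.8, 0.7, 1))
  ev <- evaluate_candidate(cand, train, config = cfg)
  expect_equal(ev$J, max(ev$per_assignment_risks))
  # permuting the recorded risks cannot change the maximum
  expect_equal(ev$J, max(sample(ev$per_assignment_risks)))

  cfg_small <- risk_config(bandwidth = 1, regularization = 0.1,
                           enumeration_cap = 2L)
  expect_error(evaluate_candidate(cand, train, config = cfg_small),
               "enumeration cap")
})

test_that("near-singular systems stay solvable with modest gamma", {
  X <- rbind(c(0, 0), c(0, 0), c(1, 1))  # duplicated rows
  Y <- matrix(c(1, 1, -1, -1, 1, 1), 3, 2)
  fit <- fit_weighted_rls(X, Y, NULL, risk_config(bandwidth = 1,
                                                  regularization = 1e-8))
  expect_true(all(is.finite(fit$alpha)))
})
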