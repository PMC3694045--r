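# small pool/train pair exercised across the ranking tests
make_selection_fixture <- function(n_pool = 6, seed = 9, Q = 3, d = 2) {
  set.seed(seed)
  train <- random_certain_set(12, Q, d)
  status <- matrix("negative", n_pool, Q)
  status[cbind(seq_len(n_pool), sample.int(Q, n_pool, TRUE))] <-
    sample(c("probable", "potential", "by_similarity"), n_pool, TRUE)
  pool <- labeled_set(matrix(rnorm(n_pool * d), n_pool, d), status,
                      locations = train$locations,
                      ids = sprintf("c%02d", seq_len(n_pool)))
  list(train = train, pool = pool,
       params = confidence_params(bandwidth = 1),
       config = risk_config(bandwidth = 1, regularization = 0.1))
}

test_that("change rates are the relative successive differences", {
  expect_equal(change_rates(c(2, 2, 2, 2)), c(0, 0, 0, NA))
  r <- change_rates(c(0.5, 0.7, 1.1))
  expect_true(all(r[1:2] > 0))
  expect_equal(change_rates(c(1.0, 1.1, 1.32)),
               c(0.1, 0.2, NA), tolerance = 1e-12)
  expect_warning(r0 <- change_rates(c(0, 1)), "1e-12")
  expect_true(is.finite(r0[1]))
  expect_error(change_rates(c(2, 1)), "ascending")
})

test_that("single-pass ranking equals sorting individual evaluations", {
  fx <- make_selection_fixture()
  refs <- reference_sets(fx$train)
  rk <- rank_pool(fx$pool, fx$train, refs, fx$params, fx$config)
  expect_equal(rk$j_values, sort(rk$j_values))
  byhand <- vapply(seq_len(6), function(i) {
    w <- label_weight(fx$pool$features[i, ], fx$pool$status[i, ], refs,
                      fx$params)
    evaluate_candidate(list(x = fx$pool$features[i, ],
                            status = fx$pool$status[i, ], weights = w),
                       fx$train, config = fx$config)$J
  }, numeric(1))
  expect_equal(rk$ordered, fx$pool$ids[order(byhand, fx$pool$ids)])
  expect_equal(rk$j_values, sort(byhand), tolerance = 1e-12)
})

test_that("duplicate candidates tie and resolve by id", {
  fx <- make_selection_fixture(n_pool = 4, seed = 15)
  pool <- fx$pool
  pool$features[2, ] <- pool$features[1, ]
  pool$status[2, ] <- pool$status[1, ]
  pool <- labeled_set(pool$features, pool$status,
                      locations = pool$locations, ids = pool$ids)
  rk <- rank_pool(pool, fx$train, params = fx$params, config = fx$config)
  i1 <- match("c01", rk$ordered)
  i2 <- match("c02", rk$ordered)
  expect_equal(rk$j_values[i1], rk$j_values[i2], tolerance = 1e-12)
  expect_lt(i1, i2)  # id tie-break
})

test_that("a singleton pool ranks trivially", {
  fx <- make_selection_fixture(n_pool = 1, seed = 27)
  rk <- rank_pool(fx$pool, fx$train, params = fx$params, config = fx$config)
  expect_equal(rk$ordered, "c01")
  expect_length(rk$j_values, 1L)
})

test_that("sequential mode grows the training set one candidate at a time", {
  fx <- make_selection_fixture(n_pool = 4, seed = 51)
  refs <- reference_sets(fx$train)
  rk <- rank_pool(fx$pool, fx$train, refs, fx$params, fx$config,
                  mode = "sequential")
  expect_setequal(rk$ordered, fx$pool$ids)
  # the first pick agrees with the single-pass argmin
  sp <- rank_pool(fx$pool, fx$train, refs, fx$params, fx$config)
  expect_equal(rk$ordered[1], sp$ordered[1])
})

test_that("the preferred proportion stops before the rate blow-up", {
  # flat in intervals 1-3 of the ranking, sharply rising afterwards
  j <- c(seq(1, 1.0001, length.out = 30),
         1.0001 * cumprod(rep(1.25, 70)))
  ranking <- structure(list(j_values = j), class = "pneaselect_ranking")
  theta <- preferred_proportion(ranking)
  expect_equal(theta$theta_star, 0.30)
  expect_equal(theta$interval_counts, rep(10L, 10))
  # brute-force check of the rule over all 10 cut points
  r <- change_rates(j)
  iv <- ceiling(seq_along(j) * 10 / length(j))
  R_t <- vapply(1:10, function(t) mean(r[iv == t], na.rm = TRUE),
                numeric(1))
  rbar <- mean(r, na.rm = TRUE)
  ok_prefix <- vapply(1:10, function(t) all(R_t[1:t] <= rbar + 1e-12),
                      logical(1))
  expect_equal(theta$theta_star, 0.1 * max(which(ok_prefix)))
})

test_that("theta* stays on the proportion grid", {
  set.seed(61)
  for (i in 1:10) {
    j <- sort(abs(rnorm(40, 1, 0.5)))
    th <- preferred_proportion(structure(list(j_values = j),
                                         class = "pneaselect_ranking"))
    expect_true(on_theta_grid(th$theta_star))
  }
  # constant evaluation values: every interval is stable, take everything
  th <- preferred_proportion(structure(list(j_values = rep(2, 30)),
                                       class = "pneaselect_ranking"))
  expect_equal(th$theta_star, 1)
})

test_that("pools smaller than the interval count warn and still work", {
  expect_warning(
    th <- preferred_proportion(structure(list(j_values = c(1, 1.1, 1.2, 5)),
                                         class = "pneaselect_ranking")),
    "smaller than")
  expect_true(on_theta_grid(th$theta_star))
})

test_that("selection returns a nested prefix with committed labels", {
  fx <- make_selection_fixture(n_pool = 10, seed = 71)
  sel <- select_supplement(fx$pool, fx$train, params = fx$params,
                           config = fx$config)
  n_sel <- length(sel$selected_ids)
  expect_equal(sel$selected_ids,
               sel$ranking$ordered[seq_len(n_sel)])
  expect_equal(n_sel,
               max(1L, floor(sel$theta$theta_star * 10 + 0.5)))
  # committed statuses are certain and weights are retained
  expect_true(all(status_certain(sel$selected)))
  expect_true(all(sel$selected$weights >= 0 & sel$selected$weights <= 1))
  # nested-selection property across the theta grid
  for (th in seq(0.1, 0.9, by = 0.1)) {
    a <- sel$ranking$ordered[seq_len(max(1, floor(th * 10 + 0.5)))]
    b <- sel$ranking$ordered[seq_len(max(1, floor((th + 0.1) * 10 + 0.5)))]
    expect_true(all(a %in% b))
  }
  tab <- ranking_table(sel$ranking, sel$theta)
  expect_equal(sum(tab$selected), n_sel)
  expect_equal(tab$id[seq_len(n_sel)], sel$selected_ids)
})

test_that("selection rejects an empty pool and is deterministic", {
  fx <- make_selection_fixture(n_pool = 5, seed = 81)
  empty <- fx$pool[0]
  expect_error(rank_pool(empty, fx$train, params = fx$params,
                         config = fx$config), "empty candidate pool")
  s1 <- suppressWarnings(select_supplement(fx$pool, fx$train,
                                           params = fx$params,
                                           config = fx$config))
  s2 <- suppressWarnings(select_supplement(fx$pool, fx$train,
                                           params = fx$params,
                                           config = fx$config))
  expect_identical(s1$selected_ids, s2$selected_ids)
  expect_equal(s1$ranking$j_values, s2$ranking$j_values)
})

test_that("correct-label candidates outrank label-flipped decoys", {
  set.seed(91)
  study <- generate_study(synthetic_config(n_train = 30, n_pool = 40,
                                           n_test = 10, seed = 91))
  sel <- select_supplement(study$pool, study$train)
  prefix_frac <- enrichment_score(sel$selected_ids, study)
  pool_frac <- mean(study$pool_correct)
  expect_gte(prefix_frac, pool_frac)
})
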