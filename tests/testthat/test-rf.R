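make_separable <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("high", "low"), each = n / 2))
  tibble::tibble(
    x1 = rnorm(n, ifelse(y == "low", 2, -2), 0.5),
    x2 = rnorm(n),
    y = y
  )
}

test_that("grid search returns the accuracy-maximising spec and is deterministic", {
  d <- make_separable()
  g1 <- rf_grid_search(d[c("x1", "x2")], d$y, n_trees_grid = c(5, 15),
                       max_depth_grid = c(2, 6), seed = 3)
  expect_gte(g1$score, 0.95)
  expect_equal(nrow(g1$surface), 4)
  g2 <- rf_grid_search(d[c("x1", "x2")], d$y, n_trees_grid = c(5, 15),
                       max_depth_grid = c(2, 6), seed = 3)
  expect_identical(g1$surface, g2$surface)
  # grid of size one returns that spec
  g3 <- rf_grid_search(d[c("x1", "x2")], d$y, n_trees_grid = 7,
                       max_depth_grid = 4, seed = 3)
  expect_equal(c(g3$n_trees, g3$max_depth), c(7, 4))
  expect_error(rf_grid_search(d[c("x1", "x2")], rep("high", nrow(d))),
               "classes")
})

test_that("grid search is invariant to row order", {
  d <- make_separable(40)
  perm <- sample(nrow(d))
  g1 <- rf_grid_search(d[c("x1", "x2")], d$y, 10, 5, seed = 4)
  g2 <- rf_grid_search(d[perm, c("x1", "x2")], d$y[perm], 10, 5, seed = 4)
  expect_equal(g1$score, g2$score, tolerance = 0.06)
})

test_that("OOB noise-injection importance finds planted signal and ignores noise", {
  imps_signal_first <- 0
  null_imps <- c()
  for (s in 1:5) {
    set.seed(s)
    n <- 80
    y <- factor(rep(c("high", "low"), each = n / 2))
    X <- tibble::tibble(
      signal = rnorm(n, ifelse(y == "low", 2, -2), 0.4),
      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
    )
    imp <- oob_importance(X, y, n_trees = 25, max_depth = 6, seed = s)
    expect_equal(nrow(imp), 4)
    if (imp$feature[1] == "signal") imps_signal_first <- imps_signal_first + 1
    null_imps <- c(null_imps, imp$importance[imp$feature != "signal"])
  }
  expect_gte(imps_signal_first, 4)
  expect_lt(mean(abs(null_imps)), 0.05)
})

test_that("with all-noise features, importances straddle zero", {
  set.seed(9)
  y <- factor(rep(c("high", "low"), each = 30))
  X <- tibble::as_tibble(matrix(rnorm(60 * 5), 60,
                                dimnames = list(NULL, paste0("f", 1:5))))
  imp <- dplyr::bind_rows(lapply(1:4, function(s) {
    oob_importance(X, y, n_trees = 20, max_depth = 5, seed = s)
  }))
  expect_lt(min(imp$importance), 0)
  expect_gt(max(imp$importance), -1e-9)
})

test_that("the normalised RMSE follows its printed definition", {
  r <- paper_rmse(c(0, 1, 1, 0), c(0, 1, 0, 0))
  expect_equal(r$rmse, sqrt(1 / 1.25), tolerance = 1e-12)
  expect_equal(r$re, 0.25)
  expect_equal(paper_rmse(c(0, 1, 0.5), c(0, 1, 0.5))$rmse, 0)
  # invariant to a common shift of both vectors
  set.seed(2)
  yo <- rnorm(10); yp <- rnorm(10)
  expect_equal(paper_rmse(yo, yp)$rmse, paper_rmse(yo + 3, yp + 3)$rmse,
               tolerance = 1e-12)
  expect_error(paper_rmse(c(1, 1), c(1, 1)), "denominator|range")
  expect_equal(conventional_rmse(c(0, 2), c(0, 0)), sqrt(2))
})

test_that("backward elimination traces p-1 entries and retains the RMSE minimiser", {
  ft <- fixture_features()
  feat_cols <- setdiff(names(ft), c("subject_id", "group", "epoch_index",
                                    "window_start_s"))
  expect_length(feat_cols, 12)
  tr <- backward_eliminate(ft[feat_cols], ft$group, n_trees = 11,
                           max_depth = 10, seed = 2)
  expect_equal(nrow(tr), 11)
  expect_equal(tr$n_features, 11:1)
  expect_true(all(tr$rmse >= 0) && all(tr$re >= 0))
  expect_equal(retained_features(tr), tr$retained[[which.min(tr$rmse)]])
  expect_true(all(retained_features(tr) %in% feat_cols))
  # one feature dropped per round, sets nested
  for (i in 2:nrow(tr)) {
    expect_true(all(tr$retained[[i]] %in% tr$retained[[i - 1]]))
    expect_equal(length(tr$retained[[i - 1]]) - length(tr$retained[[i]]), 1)
  }
})

test_that("a pure-noise companion feature is eliminated before the signal", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    y <- factor(rep(c("high", "low"), each = n / 2))
    X <- tibble::tibble(signal = rnorm(n, ifelse(y == "low", 1.5, -1.5), 0.5),
                        noise = rnorm(n))
    tr <- backward_eliminate(X, y, n_trees = 20, max_depth = 5, seed = s)
    if (tr$dropped[1] == "noise") wins <- wins + 1
  }
  expect_gte(wins, 9)
})
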