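test_that("PCA basics: ordering, orthonormality, uncorrelated scores", {
  set.seed(1)
  n <- 200
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X$d <- X$a + rnorm(n, 0, 0.3)
  b <- fit_pca(X)
  expect_true(all(diff(b$eigenvalues) <= 1e-9))
  G <- b$loadings %*% t(b$loadings)
  expect_equal(G, diag(4), tolerance = 1e-9, ignore_attr = TRUE)
  S <- cov(b$scores)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-9)
  expect_equal(sum(b$contribution), 100, tolerance = 1e-9)
  expect_true(all(diff(b$cumulative) >= -1e-12))
})

test_that("variance along one direction gives a 100% first component", {
  t <- seq(0, 1, length.out = 50)
  X <- tibble::tibble(x = t, y = 2 * t)
  b <- fit_pca(X)
  expect_equal(b$contribution[1], 100, tolerance = 1e-9)
})

test_that("the 2x2 Gaussian case approaches its closed-form eigenstructure", {
  # covariance [[2,1],[1,2]] has eigenvalues (3,1); after standardisation
  # the correlation matrix [[1,.5],[.5,1]] has eigenvalues (1.5, 0.5),
  # i.e. contributions (75%, 25%)
  set.seed(2)
  n <- 20000
  z <- matrix(rnorm(2 * n), ncol = 2)
  L <- chol(matrix(c(2, 1, 1, 2), 2))
  X <- z %*% L
  b <- fit_pca(tibble::as_tibble(as.data.frame(X)))
  expect_equal(b$contribution, c(75, 25), tolerance = 1.5)
})

test_that("constant columns are rejected by name", {
  X <- tibble::tibble(ok = rnorm(10), flat = rep(2, 10))
  expect_error(fit_pca(X), "flat")
})

test_that("full-rank projection reconstructs the standardised data", {
  set.seed(3)
  X <- tibble::as_tibble(matrix(rnorm(50 * 4), 50,
                                dimnames = list(NULL, paste0("v", 1:4))))
  b <- fit_pca(X)
  sc <- pca_scores(b, X)
  Z <- scale(as.matrix(X))
  back <- sc %*% b$loadings
  expect_equal(back, Z, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cumulative contributions reproduce the published running sums", {
  contr <- c(25.108, 17.233, 14.176, 11.548, 10.016, 9.624)
  cum <- cumulative_contribution(contr)
  expect_equal(cum[2], 42.341, tolerance = 1e-9)
  expect_equal(cum[6], 87.705, tolerance = 1e-9)
  expect_equal(cumulative_contribution(100), 100)
  expect_error(cumulative_contribution(c(10, -1)), ">= 0")
})

test_that("component selection follows the cumulative threshold rule", {
  fake <- list(cumulative = c(50, 80, 90, 100))
  expect_equal(select_k(fake, threshold = 0.877), 3)
  expect_equal(select_k(fake, threshold = 1), 4)
  expect_equal(select_k(fake, threshold = 0.4), 1)
  expect_equal(select_k(fake, k = 2), 2)       # fixed k wins
  expect_error(select_k(list(cumulative = c(50, 60)), threshold = 0.9),
               "unattainable")
})

test_that("composite weights reproduce the published coefficients", {
  contr <- c(25.108, 17.233, 14.176, 11.548, 10.016, 9.624)
  w <- composite_weights(contr, k = 6)
  expect_equal(round(w[3], 4), 0.1616)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0) && all(diff(w) <= 0))
  expect_equal(composite_weights(contr, k = 1), 1)
  expect_equal(composite_weights(c(30, 10), 2), c(0.75, 0.25))
})

test_that("input maps stack epochs with zero padding and unit scaling", {
  set.seed(4)
  scores <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 60),
    group = rep(c("high", "low"), each = 60),
    epoch_index = rep(1:60, 2)
  )
  for (k in 1:6) scores[[paste0("PC", k)]] <- rnorm(120)
  inp <- build_cnn_inputs(scores, shape = c(13, 20), stack = 20)
  expect_length(inp$maps, 6)               # 60 epochs, stack 20, no overlap
  expect_equal(dim(inp$maps[[1]]), c(13, 20))
  for (m in inp$maps) {
    expect_equal(m[7:13, ], matrix(0, 7, 20))  # rows 7-13 zero padding
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_equal(as.character(inp$labels),
               rep(c("high", "low"), each = 3))
  # identical epochs give identical map columns
  const <- scores
  for (k in 1:6) const[[paste0("PC", k)]] <- rep(seq(0, 1, length.out = 6)[k], 120)
  inp2 <- build_cnn_inputs(const, stack = 20)
  expect_equal(inp2$maps[[1]][, 1], inp2$maps[[1]][, 20])
  expect_error(build_cnn_inputs(scores, shape = c(4, 20), stack = 20),
               "shape")
})
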