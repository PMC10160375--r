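test_that("conv_block computes valid convolutions with ReLU", {
  ones3 <- matrix(1, 3, 3)
  k2 <- matrix(1, 2, 2)
  expect_equal(conv_block(ones3, k2), matrix(4, 2, 2))
  expect_equal(conv_block(ones3, matrix(0, 2, 2)), matrix(0, 2, 2))
  # single-1 kernel reproduces the input sub-window
  x <- matrix(1:9 / 10, 3, 3)
  ident <- matrix(c(1, 0, 0, 0), 2, 2)   # picks the top-left of each patch
  expect_equal(conv_block(x, ident), x[1:2, 1:2])
  # negative responses are clipped at zero
  expect_equal(conv_block(ones3, -k2), matrix(0, 2, 2))
  expect_equal(conv_block(ones3, -k2, activation = "linear"),
               matrix(-4, 2, 2))
  expect_error(conv_block(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("max pooling takes window maxima under both paddings", {
  m <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(max_pool(m, pool = 2, stride = 2),
               matrix(c(6, 14, 8, 16), 2, 2))
  cst <- matrix(3, 5, 5)
  expect_equal(max_pool(cst, pool = 3, stride = 1, padding = "same"), cst)
  set.seed(1)
  r <- matrix(rnorm(30), 5, 6)
  expect_true(all(max_pool(r, 3, 1, "same") <= max(r)))
  expect_true(all(max_pool(r, 2) <= max(r)))
})

test_that("pca_fuse adds the projected map and honours the zero basis", {
  conv <- matrix(c(1, 2, 3, 4), 2, 2)
  pooled <- matrix(c(4, 3, 2, 1), 2, 2)
  expect_equal(pca_fuse(conv, pooled, NULL), pooled)
  zero_b <- list(mu = numeric(4), V = matrix(0, 4, 1))
  expect_equal(pca_fuse(conv, pooled, zero_b), pooled)
  # hand-built 1-component basis: V = e1, mu = 0 -> adds (1,0,0,0)
  b1 <- list(mu = numeric(4), V = matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(pca_fuse(conv, pooled, b1),
               pooled + matrix(c(1, 0, 0, 0), 2, 2))
  # general basis: oracle by direct matrix arithmetic
  set.seed(2)
  V <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  mu <- rnorm(4)
  b2 <- list(mu = mu, V = V)
  want <- pooled + matrix(V %*% (t(V) %*% (as.vector(conv) - mu)), 2, 2)
  expect_equal(pca_fuse(conv, pooled, b2), want, tolerance = 1e-12)
  expect_identical(pca_fuse(conv, pooled, b2), pca_fuse(conv, pooled, b2))
  expect_error(pca_fuse(matrix(1, 3, 3), pooled, b2), "dimension")
})

test_that("softmax head and cross-entropy follow their closed forms", {
  expect_equal(softmax(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(sum(softmax(rnorm(5))), 1, tolerance = 1e-12)
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0), c(0.75, 0.25)), -log(0.75),
               tolerance = 1e-12)
  expect_gte(cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("SGD and the learning-rate rule apply the stated updates", {
  p <- list(W = matrix(1), b = 0.5)
  g0 <- list(W = matrix(0), b = 0)
  expect_equal(sgd_step(p, g0, lr = 0.1, weight_decay = 0), p)
  p2 <- sgd_step(list(W = matrix(1)), list(W = matrix(0.5)), lr = 0.1)
  expect_equal(p2$W[1, 1], 0.95)
  # decay applies to weights, not biases
  p3 <- sgd_step(list(W = matrix(1), b = 1),
                 list(W = matrix(0), b = 0), lr = 0.1, weight_decay = 0.5)
  expect_equal(p3$W[1, 1], 0.95)
  expect_equal(p3$b, 1)
  expect_equal(adjust_learning_rate(0.1, 1, 1.3), 0.05)   # 30% jump halves
  expect_equal(adjust_learning_rate(0.1, 1, 1.2), 0.1)    # 20% does not
  expect_equal(adjust_learning_rate(0.1, NA, 2), 0.1)     # first epoch
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  cfg <- cnn_config(input_shape = c(9, 12), n_filters = c(2, 2), kernel = 3,
                    fusion_components = 3, warmup_samples = 6)
  geom <- eegsa:::cnn_geometry(cfg)
  params <- eegsa:::init_cnn_params(cfg, 2, seed = 3)
  # keep pre-activations away from the ReLU kink so the finite-difference
  # probe does not straddle a subgradient boundary
  params$b1[] <- 0.05
  params$b2[] <- 0.07
  maps <- lapply(1:6, function(i) matrix(runif(9 * 12), 9, 12))
  fus <- eegsa:::fit_fusion_bases(maps, params, geom, cfg)
  x <- maps[[1]]; y1 <- c(0, 1)
  fw <- eegsa:::cnn_forward(x, params, fus, geom, cfg, cache = TRUE)
  gr <- eegsa:::cnn_backward(fw, y1, params, fus, geom)
  loss_fn <- function(p) {
    cross_entropy(y1, eegsa:::cnn_forward(x, p, fus, geom, cfg)$probs)
  }
  eps <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(abs(num), abs(gr[[nm]][i]), 1e-6), 1e-4)
    }
  }
})

test_that("zero fusion bases reduce the network to the plain CNN exactly", {
  set.seed(8)
  cfg <- cnn_config(n_filters = c(3, 3), fusion_components = 4)
  geom <- eegsa:::cnn_geometry(cfg)
  params <- eegsa:::init_cnn_params(cfg, 2, seed = 1)
  maps <- lapply(1:5, function(i) matrix(runif(260), 13, 20))
  fus <- eegsa:::fit_fusion_bases(maps, params, geom, cfg)
  zero <- lapply(fus, function(b) list(mu = b$mu * 0, V = b$V * 0))
  for (x in maps) {
    plain <- eegsa:::cnn_forward(x, params, list(b1 = NULL, b2 = NULL),
                                 geom, cfg)
    zeroed <- eegsa:::cnn_forward(x, params, zero, geom, cfg)
    expect_identical(plain$probs, zeroed$probs)
  }
})

test_that("training separates separable maps and is seed-deterministic", {
  toy <- toy_maps(n_per_class = 30)
  cfg <- cnn_config(max_iterations = 120, eval_every = 40)
  m1 <- train_cnn(toy$maps, toy$labels, cfg, seed = 2)
  expect_gte(dplyr::last(m1$epoch_trajectory$train_acc), 0.95)
  m2 <- train_cnn(toy$maps, toy$labels, cfg, seed = 2)
  expect_identical(m1$loss_trajectory, m2$loss_trajectory)
  expect_identical(m1$params, m2$params)
  # prediction contracts
  pred <- predict_cnn(m1, toy$maps[m1$test_idx])
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$label == "low", pred$score > 0.5)
  expect_error(train_cnn(toy$maps, rep("high", 60), cfg, seed = 1),
               "classes")
  both <- c(1:5, 31:35)
  expect_error(train_cnn(toy$maps[both], toy$labels[both],
                         cnn_config(batch_size = 50), seed = 1),
               "batch size")
})
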