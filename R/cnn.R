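#' Configuration of the PCA-fused convolutional classifier
#'
#' Defaults follow the published training setup: 13 x 20 input maps,
#' 5 x 5 convolution kernels, 3 x 3 max pooling, mini-batches of 20,
#' initial learning rate 0.1 with weight decay 0.0001, and a
#' learning-rate rule that halves the rate whenever the epoch-mean loss
#' grows by more than 25%. Pooling uses stride 1 with same-padding so a
#' 3 x 3 window fits the small maps; two convolution blocks are used.
#'
#' @param input_shape Input map shape (rows, cols).
#' @param n_filters Filters per convolution block (length 2).
#' @param kernel Convolution kernel side (square).
#' @param pool Pooling window side (square, stride 1, same padding).
#' @param fusion_components Principal components retained by each fusion
#'   basis (0 disables fusion, giving the plain CNN).
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial SGD learning rate (epsilon).
#' @param weight_decay L2 weight-decay coefficient.
#' @param max_iterations Mini-batch updates to run.
#' @param loss_increase_threshold Relative epoch-loss growth that triggers
#'   a learning-rate cut (default 0.25).
#' @param lr_cut Fractional learning-rate reduction when triggered
#'   (default 0.5).
#' @param warmup_samples Training maps used to fit the frozen fusion bases.
#' @param init_sd SD of the Gaussian weight initialisation.
#' @param eval_every Iterations between train/test accuracy evaluations
#'   recorded in the trajectory (the final iteration is always evaluated).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_shape = c(13, 20), n_filters = c(4, 4),
                       kernel = 5, pool = 3, fusion_components = 8,
                       batch_size = 20, learning_rate = 0.1,
                       weight_decay = 1e-4, max_iterations = 600,
                       loss_increase_threshold = 0.25, lr_cut = 0.5,
                       warmup_samples = 64, init_sd = 0.1,
                       eval_every = 50) {
  stopifnot(length(input_shape) == 2, all(input_shape > 0),
            kernel <= min(input_shape), batch_size > 0,
            learning_rate > 0, max_iterations > 0, lr_cut > 0, lr_cut <= 1)
  structure(list(
    input_shape = input_shape, n_filters = n_filters, kernel = kernel,
    pool = pool, fusion_components = fusion_components,
    batch_size = batch_size, learning_rate = learning_rate,
    weight_decay = weight_decay, max_iterations = max_iterations,
    loss_increase_threshold = loss_increase_threshold, lr_cut = lr_cut,
    warmup_samples = warmup_samples, init_sd = init_sd,
    eval_every = eval_every), class = "cnn_config")
}

## ---- exported building blocks -------------------------------------------

#' Convolution block: valid convolution plus ReLU
#'
#' `g = max(sum_{x,y} a * w + b, 0)` per output position (stride 1, valid
#' padding).
#'
#' @param input Matrix (H x W) or array (H, W, C_in).
#' @param weights Matrix (k x k) or array (k, k, C_in, C_out).
#' @param bias Numeric bias per output channel.
#' @param activation `"relu"` (default) or `"linear"`.
#' @return Array (H-k+1, W-k+1, C_out); a matrix when C_out is 1.
#' @export
conv_block <- function(input, weights, bias = 0, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (is.matrix(input)) dim(input) <- c(dim(input), 1L)
  if (is.matrix(weights)) dim(weights) <- c(dim(weights), 1L, 1L)
  k <- dim(weights)[1]
  stopifnot(dim(weights)[2] == k, dim(weights)[3] == dim(input)[3])
  H <- dim(input)[1]; W <- dim(input)[2]
  if (k > H || k > W) stop("kernel larger than input", call. = FALSE)
  geom <- make_patch_index(H, W, k, dim(input)[3])
  Wmat <- matrix(weights, ncol = dim(weights)[4])
  Z <- matrix(as.vector(input)[geom$idx], nrow = nrow(geom$idx)) %*% Wmat
  Z <- sweep(Z, 2, rep_len(bias, ncol(Z)), `+`)
  if (activation == "relu") Z <- pmax(Z, 0)
  out <- array(Z, dim = c(geom$Hout, geom$Wout, ncol(Z)))
  if (dim(out)[3] == 1) out <- out[, , 1] else out
}

#' Max pooling
#'
#' Each output value is the maximum over its pooling window.
#'
#' @param map Matrix (H x W).
#' @param pool Window side (square).
#' @param stride Step between windows (default `pool`).
#' @param padding `"valid"` (default) or `"same"` (stride-1 same-size
#'   output, borders padded with -Inf).
#' @return Pooled matrix.
#' @export
max_pool <- function(map, pool = 3, stride = pool,
                     padding = c("valid", "same")) {
  padding <- match.arg(padding)
  H <- nrow(map); W <- ncol(map)
  if (padding == "same") {
    if (stride != 1) stop("same padding implemented for stride 1", call. = FALSE)
    pid <- make_pool_index(H, W, pool)
    v <- matrix(-Inf, H * W, ncol(pid$idx))
    ok <- !is.na(pid$idx)
    v[ok] <- as.vector(map)[pid$idx[ok]]
    return(matrix(apply(v, 1, max), H, W))
  }
  if (pool > H || pool > W) stop("pool window larger than map", call. = FALSE)
  oi <- seq(1, H - pool + 1, by = stride)
  oj <- seq(1, W - pool + 1, by = stride)
  out <- matrix(0, length(oi), length(oj))
  for (a in seq_along(oi)) for (b in seq_along(oj)) {
    out[a, b] <- max(map[oi[a]:(oi[a] + pool - 1), oj[b]:(oj[b] + pool - 1)])
  }
  out
}

#' Fit a fusion basis from convolution activations
#'
#' The fusion basis is the centred principal subspace of warm-up
#' convolution outputs: mean vector and the top `m` loading directions.
#' It is fitted once on a warm-up batch and frozen for the whole training.
#'
#' @param conv_flats Matrix of flattened convolution maps (samples x d).
#' @param m Number of components retained.
#' @return List with `mu` (length d) and `V` (d x m, orthonormal columns).
#' @export
fit_fusion_basis <- function(conv_flats, m = 8) {
  mu <- colMeans(conv_flats)
  Z <- sweep(conv_flats, 2, mu)
  m <- min(m, nrow(conv_flats) - 1, ncol(conv_flats))
  if (m < 1) stop("need at least 2 warm-up samples", call. = FALSE)
  V <- svd(Z, nu = 0, nv = m)$v
  list(mu = mu, V = V)
}

#' Fuse a convolution map into a pooled map
#'
#' Projects the flattened convolution map onto the (frozen) fusion basis
#' and adds the reconstruction point-by-point to the pooled map:
#' `fused = pooled + reshape(V V' (flatten(conv) - mu))`. A `NULL` basis
#' (or zero basis) leaves the pooled map unchanged, reducing the fused
#' network to the plain CNN exactly.
#'
#' @param conv_map Convolution output (matrix or array).
#' @param pooled_map Pooled output with as many elements as `conv_map`.
#' @param basis A fusion basis from [fit_fusion_basis()], or `NULL`.
#' @return Fused map with the shape of `pooled_map`.
#' @export
pca_fuse <- function(conv_map, pooled_map, basis) {
  if (is.null(basis)) return(pooled_map)
  x <- as.vector(conv_map)
  if (length(x) != length(basis$mu) || nrow(basis$V) != length(x)) {
    stop("fusion basis dimension does not match the convolution map",
         call. = FALSE)
  }
  u <- as.vector(basis$V %*% crossprod(basis$V, x - basis$mu))
  if (length(u) != length(pooled_map)) {
    stop("projected map does not match the pooled shape", call. = FALSE)
  }
  pooled_map + array(u, dim = dim(pooled_map) %||% length(pooled_map))
}

#' Softmax probabilities and cross-entropy loss
#'
#' `softmax(y)_i = exp(y_i) / sum_j exp(y_j)` (computed with the max
#' subtracted for stability); `cross_entropy(p, q) = -sum p log q` with the
#' natural logarithm.
#'
#' @param logits Numeric vector of class scores.
#' @param p,q Probability vectors (target and predicted).
#' @return `softmax()`: probability vector; `cross_entropy()`: scalar loss.
#' @export
softmax <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' @rdname softmax
#' @export
cross_entropy <- function(p, q) {
  stopifnot(length(p) == length(q))
  -sum(p * log(q))
}

#' One SGD update
#'
#' `w <- w - lr * (grad + weight_decay * w)` applied to every parameter
#' array.
#'
#' @param params Named list of parameter arrays.
#' @param grads Matching list of gradients.
#' @param lr Learning rate.
#' @param weight_decay L2 decay coefficient (biases are not decayed).
#' @return Updated parameter list.
#' @export
sgd_step <- function(params, grads, lr, weight_decay = 0) {
  for (nm in names(params)) {
    decay <- if (grepl("^b", nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (grads[[nm]] + decay * params[[nm]])
  }
  params
}

#' Learning-rate adjustment rule
#'
#' When the epoch-mean loss grows by more than `threshold` relative to the
#' previous epoch, the learning rate is reduced by the fraction `cut`
#' (default: halved).
#'
#' @param lr Current learning rate.
#' @param prev_loss,curr_loss Mean loss of the previous and current epoch.
#' @param threshold Relative increase triggering the cut (default 0.25).
#' @param cut Fractional reduction (default 0.5).
#' @return The (possibly reduced) learning rate.
#' @export
adjust_learning_rate <- function(lr, prev_loss, curr_loss,
                                 threshold = 0.25, cut = 0.5) {
  if (is.finite(prev_loss) && prev_loss > 0 &&
      (curr_loss - prev_loss) / prev_loss > threshold) {
    lr * (1 - cut)
  } else lr
}

## ---- internal geometry and fast forward/backward ------------------------

make_patch_index <- function(H, W, k, Cin) {
  Hout <- H - k + 1; Wout <- W - k + 1
  x <- rep(seq_len(Hout), Wout)
  y <- rep(seq_len(Wout), each = Hout)
  base <- x + (y - 1) * H
  off <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1, (seq_len(k) - 1) * H, `+`)),
    (seq_len(Cin) - 1) * H * W, `+`))
  list(idx = outer(base, off, `+`), Hout = Hout, Wout = Wout)
}

make_pool_index <- function(H, W, pool = 3) {
  r <- (pool - 1) %/% 2
  offs <- expand.grid(di = -r:(pool - 1 - r), dj = -r:(pool - 1 - r))
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  idx <- sapply(seq_len(nrow(offs)), function(o) {
    ii <- i + offs$di[o]; jj <- j + offs$dj[o]
    ifelse(ii >= 1 & ii <= H & jj >= 1 & jj <= W, ii + (jj - 1) * H, NA_integer_)
  })
  list(idx = idx)
}

# channel-expanded same-padding pool index: flat indices into as.vector of
# an (n x ch) activation matrix, one row per output element
expand_pool_index <- function(pidx, ch) {
  n <- nrow(pidx)
  idx_all <- do.call(rbind, lapply(seq_len(ch) - 1, function(c) pidx + c * n))
  ok <- !is.na(idx_all)
  idx_all[!ok] <- 1L   # placeholder; masked by ok
  list(idx = idx_all, ok = ok, n = n, ch = ch)
}

# precomputed sorted-scatter: aggregates a value vector by the fixed index
# vector `targets` without per-call unique/match
make_scatter <- function(idxvec, d) {
  o <- order(idxvec)
  sorted <- idxvec[o]
  ends <- c(which(diff(sorted) != 0), length(sorted))
  list(o = o, ends = ends, targets = sorted[ends], d = d)
}

scatter_add <- function(sc, v) {
  cs <- cumsum(v[sc$o])
  sums <- cs[sc$ends] - c(0, cs[sc$ends[-length(sc$ends)]])
  out <- numeric(sc$d)
  out[sc$targets] <- sums
  out
}

cnn_geometry <- function(cfg) {
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]; k <- cfg$kernel
  g1 <- make_patch_index(H, W, k, 1L)
  g1$pidx <- make_pool_index(g1$Hout, g1$Wout, cfg$pool)$idx
  g1$pe <- expand_pool_index(g1$pidx, cfg$n_filters[1])
  g2 <- make_patch_index(g1$Hout, g1$Wout, k, cfg$n_filters[1])
  g2$pidx <- make_pool_index(g2$Hout, g2$Wout, cfg$pool)$idx
  g2$pe <- expand_pool_index(g2$pidx, cfg$n_filters[2])
  d1 <- g1$Hout * g1$Wout * cfg$n_filters[1]
  g2$scat <- make_scatter(as.vector(g2$idx), d1)
  list(l1 = g1, l2 = g2, d1 = d1,
       d2 = g2$Hout * g2$Wout * cfg$n_filters[2])
}

init_cnn_params <- function(cfg, n_classes = 2, seed = 1) {
  k <- cfg$kernel
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(k * k * cfg$n_filters[1], 0, cfg$init_sd),
                k * k, cfg$n_filters[1]),
    b1 = numeric(cfg$n_filters[1]),
    W2 = matrix(stats::rnorm(k * k * cfg$n_filters[1] * cfg$n_filters[2],
                             0, cfg$init_sd),
                k * k * cfg$n_filters[1], cfg$n_filters[2]),
    b2 = numeric(cfg$n_filters[2]),
    Wfc = matrix(stats::rnorm(n_classes * cnn_geometry(cfg)$d2, 0, cfg$init_sd),
                 n_classes, cnn_geometry(cfg)$d2),
    bfc = numeric(n_classes)))
}

# max pooling on flat channel matrices; records the flat source index of
# each output's argmax for backprop
pool_forward <- function(Cmat, pe) {
  v <- matrix(-Inf, nrow(pe$idx), ncol(pe$idx))
  Cvec <- as.vector(Cmat)
  v[pe$ok] <- Cvec[pe$idx[pe$ok]]
  arg <- max.col(v, ties.method = "first")
  rows <- seq_len(nrow(v))
  list(P = matrix(v[cbind(rows, arg)], pe$n, pe$ch),
       src = pe$idx[cbind(rows, arg)])
}

pool_backward <- function(dP, src, n, ch) {
  agg <- rowsum(as.vector(dP), src)
  dC <- numeric(n * ch)
  dC[as.integer(rownames(agg))] <- agg
  matrix(dC, n, ch)
}

fuse_forward <- function(Cmat, Pmat, basis) {
  if (is.null(basis)) return(as.vector(Pmat))
  x <- as.vector(Cmat)
  as.vector(Pmat) + as.vector(basis$V %*% crossprod(basis$V, x - basis$mu))
}

# Forward pass for one input map. `fusion` is list(b1, b2) of fusion bases
# (either may be NULL for the plain CNN). Returns probabilities and, when
# `cache = TRUE`, all intermediates needed by cnn_backward().
cnn_forward <- function(x, params, fusion, geom, cfg, cache = FALSE) {
  patches1 <- matrix(as.vector(x)[geom$l1$idx], nrow = nrow(geom$l1$idx))
  Z1 <- sweep(patches1 %*% params$W1, 2, params$b1, `+`)
  C1 <- pmax(Z1, 0)
  pf1 <- pool_forward(C1, geom$l1$pe)
  F1 <- fuse_forward(C1, pf1$P, fusion$b1)

  patches2 <- matrix(F1[geom$l2$idx], nrow = nrow(geom$l2$idx))
  Z2 <- sweep(patches2 %*% params$W2, 2, params$b2, `+`)
  C2 <- pmax(Z2, 0)
  pf2 <- pool_forward(C2, geom$l2$pe)
  F2 <- fuse_forward(C2, pf2$P, fusion$b2)

  logits <- as.vector(params$Wfc %*% F2 + params$bfc)
  probs <- softmax(logits)
  if (!cache) return(list(probs = probs, logits = logits))
  list(probs = probs, logits = logits, x = x,
       patches1 = patches1, Z1 = Z1, C1 = C1, pf1 = pf1, F1 = F1,
       patches2 = patches2, Z2 = Z2, C2 = C2, pf2 = pf2, F2 = F2)
}

# Backpropagation for one sample; returns gradients matching init_cnn_params.
cnn_backward <- function(fw, y_onehot, params, fusion, geom) {
  dlogits <- fw$probs - y_onehot
  dWfc <- tcrossprod(dlogits, fw$F2)
  dbfc <- dlogits
  dF2 <- as.vector(crossprod(params$Wfc, dlogits))

  # through fusion 2: dP2 = dF2 (reshaped); dC2 += V V' dF2
  n2 <- nrow(fw$C2); ch2 <- ncol(fw$C2)
  dC2 <- pool_backward(dF2, fw$pf2$src, n2, ch2)
  if (!is.null(fusion$b2)) {
    V <- fusion$b2$V
    dC2 <- dC2 + matrix(V %*% crossprod(V, dF2), n2, ch2)
  }
  dZ2 <- dC2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$patches2, dZ2)
  db2 <- colSums(dZ2)

  # to fused layer-1 output (input of conv2): scatter patch gradients
  dF1 <- scatter_add(geom$l2$scat, as.vector(tcrossprod(dZ2, params$W2)))

  n1 <- nrow(fw$C1); ch1 <- ncol(fw$C1)
  dC1 <- pool_backward(dF1, fw$pf1$src, n1, ch1)
  if (!is.null(fusion$b1)) {
    V <- fusion$b1$V
    dC1 <- dC1 + matrix(V %*% crossprod(V, dF1), n1, ch1)
  }
  dZ1 <- dC1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$patches1, dZ1)
  db1 <- colSums(dZ1)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wfc = dWfc, bfc = dbfc)
}

# Fit the two frozen fusion bases from a warm-up set of training maps,
# sequentially (the second basis sees conv-2 outputs computed with the
# first fusion already in place).
fit_fusion_bases <- function(maps, params, geom, cfg) {
  m <- cfg$fusion_components
  if (m < 1) return(list(b1 = NULL, b2 = NULL))
  C1s <- t(vapply(maps, function(x) {
    p <- matrix(as.vector(x)[geom$l1$idx], nrow = nrow(geom$l1$idx))
    as.vector(pmax(sweep(p %*% params$W1, 2, params$b1, `+`), 0))
  }, numeric(geom$d1)))
  b1 <- fit_fusion_basis(C1s, m)
  C2s <- t(vapply(maps, function(x) {
    fw <- cnn_forward(x, params, list(b1 = b1, b2 = NULL), geom, cfg,
                      cache = TRUE)
    as.vector(fw$C2)
  }, numeric(geom$d2)))
  list(b1 = b1, b2 = fit_fusion_basis(C2s, m))
}

## ---- training ------------------------------------------------------------

#' Train the (PCA-fused) convolutional classifier
#'
#' Splits the samples 75%/25% into training and test sets, fits the frozen
#' fusion bases on a warm-up subset of training maps, then runs mini-batch
#' SGD with cross-entropy loss, weight decay, and the epoch-loss
#' learning-rate rule. Training is deterministic for a fixed seed.
#'
#' @param inputs A `cnn_input_set` from [build_cnn_inputs()], or a plain
#'   list of input matrices.
#' @param labels Factor of class labels (taken from `inputs` when absent).
#' @param config A [cnn_config()].
#' @param seed Integer seed (split, initialisation, batch order).
#' @param fusion Use PCA fusion (`TRUE`, the modified network) or not
#'   (`FALSE`, the plain CNN).
#' @param split Fraction of samples used for training (default 0.75), or
#'   `1` to train on everything.
#' @param split_by `"sample"` (random epochs; the published protocol) or
#'   `"subject"` (all of a subject's samples stay on one side).
#' @return A `cnn_model`: parameters, fusion bases, per-iteration loss
#'   trajectory, per-epoch accuracy trajectory, split indices and final
#'   test performance.
#' @export
train_cnn <- function(inputs, labels = NULL, config = cnn_config(),
                      seed = 1, fusion = TRUE, split = 0.75,
                      split_by = c("sample", "subject")) {
  split_by <- match.arg(split_by)
  maps <- if (inherits(inputs, "cnn_input_set")) inputs$maps else inputs
  labels <- labels %||% inputs$labels
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("both classes must be present", call. = FALSE)
  n <- length(maps)
  stopifnot(length(labels) == n)

  train_idx <- with_seed(derive_seed(seed, "split"), {
    if (split >= 1) seq_len(n)
    else if (split_by == "subject" && inherits(inputs, "cnn_input_set")) {
      subj <- unique(inputs$subject_id)
      tr_subj <- sample(subj, max(2, round(split * length(subj))))
      which(inputs$subject_id %in% tr_subj)
    } else {
      unlist(lapply(levels(labels), function(lv) {
        idx <- which(labels == lv)
        sample(idx, max(1, round(split * length(idx))))
      }))
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(unique(labels[train_idx])) < 2) {
    stop("training split lost a class", call. = FALSE)
  }
  if (config$batch_size > length(train_idx)) {
    stop("batch size exceeds the training set", call. = FALSE)
  }

  geom <- cnn_geometry(config)
  params <- init_cnn_params(config, nlevels(labels),
                            seed = derive_seed(seed, "init"))
  fus <- if (fusion) {
    warm <- maps[train_idx[seq_len(min(config$warmup_samples,
                                       length(train_idx)))]]
    fit_fusion_bases(warm, params, geom, config)
  } else list(b1 = NULL, b2 = NULL)

  y_int <- as.integer(labels)
  onehots <- diag(nlevels(labels))
  lr <- config$learning_rate
  iters_per_epoch <- max(1, floor(length(train_idx) / config$batch_size))
  loss_traj <- numeric(config$max_iterations)
  acc_rows <- list()
  epoch_losses <- c()
  prev_epoch_loss <- NA_real_
  epoch_accum <- c()

  batch_rng <- derive_seed(seed, "batches")
  with_seed(batch_rng, {
    for (it in seq_len(config$max_iterations)) {
      batch <- sample(train_idx, config$batch_size)
      grads <- NULL
      loss <- 0
      for (i in batch) {
        fw <- cnn_forward(maps[[i]], params, fus, geom, config, cache = TRUE)
        loss <- loss + cross_entropy(onehots[y_int[i], ], fw$probs)
        g <- cnn_backward(fw, onehots[y_int[i], ], params, fus, geom)
        grads <- if (is.null(grads)) g else {
          purrr::map2(grads, g, `+`)
        }
      }
      grads <- purrr::map(grads, ~ .x / config$batch_size)
      loss <- loss / config$batch_size
      loss_traj[it] <- loss
      epoch_accum <- c(epoch_accum, loss)
      params <- sgd_step(params, grads, lr, config$weight_decay)

      if (it %% iters_per_epoch == 0) {
        epoch_loss <- mean(epoch_accum)
        lr <- adjust_learning_rate(lr, prev_epoch_loss, epoch_loss,
                                   config$loss_increase_threshold,
                                   config$lr_cut)
        prev_epoch_loss <- epoch_loss
        epoch_losses <- c(epoch_losses, epoch_loss)
        epoch_accum <- c()
      }
      if (it %% config$eval_every == 0 || it == config$max_iterations) {
        model_now <- list(params = params, fusion = fus, geom = geom,
                          config = config, levels = levels(labels))
        acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
          iteration = it, epoch = length(epoch_losses),
          loss = if (length(epoch_losses)) epoch_losses[length(epoch_losses)]
                 else mean(epoch_accum),
          lr = lr,
          train_acc = cnn_accuracy(model_now, maps[train_idx],
                                   labels[train_idx]),
          test_acc = if (length(test_idx)) {
            cnn_accuracy(model_now, maps[test_idx], labels[test_idx])
          } else NA_real_)
      }
    }
  })

  model <- structure(
    list(params = params, fusion = fus, geom = geom, config = config,
         levels = levels(labels), fused = fusion,
         loss_trajectory = tibble::tibble(iteration = seq_along(loss_traj),
                                          loss = loss_traj),
         epoch_trajectory = dplyr::bind_rows(acc_rows),
         train_idx = train_idx, test_idx = test_idx,
         labels = labels, seed = seed),
    class = "cnn_model")
  model
}

cnn_accuracy <- function(model, maps, labels) {
  pred <- predict_cnn(model, maps)
  mean(pred$label == as.character(labels))
}

#' Predict classes and scores from a trained network
#'
#' @param model A `cnn_model` from [train_cnn()].
#' @param inputs A `cnn_input_set` or list of input matrices.
#' @return Tibble with `label` (argmax class) and `score` (probability of
#'   the positive, low-SA class).
#' @export
predict_cnn <- function(model, inputs) {
  maps <- if (inherits(inputs, "cnn_input_set")) inputs$maps else inputs
  positive <- if ("low" %in% model$levels) "low" else model$levels[length(model$levels)]
  pos_i <- match(positive, model$levels)
  res <- vapply(maps, function(x) {
    if (!all(dim(x) == model$config$input_shape)) {
      stop("input map shape mismatch", call. = FALSE)
    }
    fw <- cnn_forward(x, model$params, model$fusion, model$geom, model$config)
    c(which.max(fw$probs), fw$probs[pos_i])
  }, numeric(2))
  tibble::tibble(label = model$levels[res[1, ]], score = res[2, ])
}

#' @export
print.cnn_model <- function(x, ...) {
  fin <- utils::tail(x$epoch_trajectory, 1)
  cat("<cnn_model> ", if (x$fused) "PCA-fused" else "plain",
      " CNN; ", nrow(x$loss_trajectory), " iterations",
      if (nrow(fin)) sprintf("; final train acc %.3f, test acc %.3f",
                             fin$train_acc, fin$test_acc),
      "\n", sep = "")
  invisible(x)
}

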