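# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# noiseless spec: tones only, so band powers follow A^2/2 exactly
quiet_spec <- function(duration = 30, ...) {
  synth_spec(duration = duration, pink_noise_sd = 0, line_noise_amp = 0,
             artifact_rate = 0, subject_sd_log = 0, region_sd_log = 0, ...)
}

# small realistic cohort for feature-level tests
fixture_cohort <- function() {
  memo("cohort", function() {
    generate_cohort(synth_spec(duration = 40, artifact_rate = 1),
                    n_high = 4, n_low = 4, seed = 11)
  })
}

fixture_features <- function() {
  memo("features", function() {
    purrr::map_dfr(fixture_cohort(), function(rec) {
      extract_features(remove_line_noise(rec))
    })
  })
}

# separable toy maps for classifier tests
toy_maps <- function(n_per_class = 30, seed = 5, shift = 0.4) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(s); on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    code
  }
  with_seed(seed, {
    labs <- rep(c("high", "low"), each = n_per_class)
    maps <- lapply(labs, function(cl) {
      m <- matrix(stats::runif(13 * 20, 0, 0.4), 13, 20)
      if (cl == "low") m[1:6, ] <- m[1:6, ] + shift
      m
    })
    list(maps = maps, labels = factor(labs))
  })
}

# O(N^2) direct-sum DFT oracle (independent of stats::fft)
dft_oracle <- function(x) {
  n <- length(x)
  w <- 0:(n - 1)
  E <- exp(-2i * pi * outer(w, w) / n)
  as.vector(E %*% x)
}

# exhaustive pairwise-ranking AUC oracle
auc_oracle <- function(labels, scores, positive = "low") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
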