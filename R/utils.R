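#' @importFrom rlang .data
#' @importFrom generics tidy glance augment
NULL

# Deterministic substream seed derivation. splitmix-style integer mixing keeps
# every derived seed inside the 32-bit range R accepts for set.seed().
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    kn <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    x <- (x * 48271 + kn * 16807 + 12345) %% 2147483647
  }
  as.integer(x %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}
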