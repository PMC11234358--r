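# Internal helpers: conditions, seeding, small checks.

fdta_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fusedta_error")))
}

fdta_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "fusedta_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package fans out from a single integer seed; each
#' random stream (entity generation, weight initialization, batching, ...)
#' gets its own sub-seed so that changing one stage never perturbs another.
#'
#' @param seed Master integer seed.
#' @param label Character stream label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is_count(seed, min = 0L), is.character(label), length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((seed * 48271 + h) %% 2147483647)
}

# Run code under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Glorot/fan-in uniform init used for every trainable matrix in the package.
init_matrix <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(x) {
  x <- exp(x - apply(x, 1L, max))
  x / rowSums(x)
}
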