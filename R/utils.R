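#' @importFrom stats rnorm runif qnorm
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-item child seeds, kept within 32-bit integer range.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

AXIS_NAMES <- c("x", "y", "z", "w")

axis_index <- function(axis, dimension) {
  idx <- match(axis, AXIS_NAMES[seq_len(dimension)])
  if (anyNA(idx)) {
    stop("invalid coordinate name(s) '", paste(axis[is.na(idx)], collapse = ", "),
         "' for dimension ", dimension, call. = FALSE)
  }
  idx
}

# Uniform random unit vectors (rows) via normalized standard normals.
random_unit_vectors <- function(n, d) {
  v <- matrix(rnorm(n * d), nrow = n, ncol = d)
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm < .Machine$double.eps
  while (any(zero)) { # astronomically rare; redraw degenerate rows
    v[zero, ] <- rnorm(sum(zero) * d)
    nrm <- sqrt(rowSums(v^2))
    zero <- nrm < .Machine$double.eps
  }
  v / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
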