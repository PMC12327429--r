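# Internal helpers: seeded evaluation, child-seed derivation, assertions.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed stream; stays below 2^31 - 1.
child_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7 + 1000003 * as.numeric(index) +
                130003 * as.numeric(salt)) %% 2147483563) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

# One-dimensional causal FIR convolution; output aligned to input (zero
# initial conditions), i.e. y[n] = sum_k h[k] x[n - k + 1].
causal_filter <- function(x, h) {
  y <- stats::filter(c(rep(0, length(h) - 1L), x), h, method = "convolution",
                     sides = 1L)
  as.numeric(y[length(h):(length(h) + length(x) - 1L)])
}

# Batched causal FIR filtering of the rows of M via FFT convolution.
# kern is one kernel vector (applied to every row) or a matrix of
# per-row kernels. Output row r equals causal_filter(M[r, ], kernel_r).
filter_rows_fft <- function(M, kern) {
  N <- ncol(M)
  R <- nrow(M)
  if (!is.matrix(kern)) kern <- matrix(kern, 1)
  L <- ncol(kern)
  nfft <- stats::nextn(N + L - 1, 2)
  X <- stats::mvfft(rbind(t(M), matrix(0, nfft - N, R)))
  if (nrow(kern) == 1L) {
    H <- stats::fft(c(kern[1, ], rep(0, nfft - L)))
    Y <- X * H
  } else {
    stopifnot(nrow(kern) == R)
    H <- stats::mvfft(rbind(t(kern), matrix(0, nfft - L, R)))
    Y <- X * H
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  t(y[seq_len(N), , drop = FALSE])
}
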