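# Internal numeric helpers shared across the data path.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-9 && x >= min
}

# Evaluate an expression with a private RNG stream so seeded fixture
# generation never disturbs (or is disturbed by) the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Linear convolution through the FFT; works for complex input.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2L)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                  stats::fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE) / nfft
  y[seq_len(n)]
}

# Short direct convolution with a complex kernel, output trimmed to length(x),
# tap l applied to x delayed by l-1 samples (causal).
conv_causal <- function(x, taps) {
  out <- rep(0 + 0i, length(x))
  for (l in seq_along(taps)) {
    if (l == 1L) out <- out + taps[l] * x
    else out[l:length(x)] <- out[l:length(x)] + taps[l] * x[seq_len(length(x) - l + 1L)]
  }
  out
}

# Vertex of the parabola through (-1, ym1), (0, y0), (1, yp1); clamped to
# [-1, 1]. Used for sub-bin/sub-sample refinement of discrete maxima.
parabolic_vertex <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps * max(abs(c(ym1, y0, yp1)), 1)) return(0)
  delta <- 0.5 * (ym1 - yp1) / den
  max(-1, min(1, delta))
}

fftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  c((h + 1L):n, 1L:h)
}

ifftshift_idx <- function(n) {
  h <- floor(n / 2)
  c((h + 1L):n, 1L:h)
}

shift_dim <- function(x, idx_fun) {
  d <- dim(x)
  if (is.null(d)) return(x[idx_fun(length(x))])
  out <- x
  for (k in seq_along(d)) {
    perm <- idx_fun(d[k])
    args <- rep(list(quote(expr = )), length(d))
    args[[k]] <- perm
    out <- do.call(`[`, c(list(out), args, list(drop = FALSE)))
  }
  out
}

fftshift <- function(x) shift_dim(x, fftshift_idx)
ifftshift <- function(x) shift_dim(x, ifftshift_idx)

# Orthonormal centered inverse DFT over every dimension of a matrix/array.
centered_ifft <- function(k) {
  d <- dim(k)
  if (is.null(d)) d <- length(k)
  x <- ifftshift(k)
  x <- stats::fft(x, inverse = TRUE) / sqrt(prod(d))
  fftshift(x)
}

centered_fft <- function(img) {
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  x <- ifftshift(img)
  x <- stats::fft(x) / sqrt(prod(d))
  fftshift(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
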