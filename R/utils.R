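# Internal numerical helpers: 2-D FFTs, centering, resampling, registration.
# Convention: spectra are kept in *centered* order (DC at floor(n/2)+1) so that
# pupil-sized sub-windows can be addressed by plain row/column arithmetic;
# `ifftshift2()` restores wrap-around order right before a transform.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# centre index of an n-point FFT grid (position of DC after fftshift)
fft_center <- function(n) floor(n / 2) + 1L

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

# centered frequency axis for n samples at spacing `pixel` (cycles per unit)
freq_axis <- function(n, pixel) (seq_len(n) - fft_center(n)) / (n * pixel)

# |f| map on a centered frequency grid
freq_radius <- function(n, df) {
  f <- (seq_len(n) - fft_center(n)) * df
  sqrt(outer(f^2, f^2, `+`))
}

# bilinear resize of a real matrix to `n_out` x `n_out` (same field of view)
bilinear_resize <- function(x, n_out) {
  n_in <- nrow(x)
  if (n_out == n_in) return(x)
  # map output pixel centers onto input pixel coordinates
  u <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5 - 1e-9
  i0 <- pmin(pmax(floor(u), 1L), n_in - 1L)
  w <- pmin(pmax(u - i0, 0), 1)
  out <- x[i0, ] * (1 - w) + x[i0 + 1L, ] * w
  out <- t(t(out[, i0]) * (1 - w) + t(out[, i0 + 1L]) * w)
  out
}

# rotate a matrix by `theta` radians about `center` (default: the DC pixel
# of a centered FFT grid), bilinear, constant fill
rotate_bilinear <- function(x, theta, fill = 0, center = NULL) {
  n1 <- nrow(x); n2 <- ncol(x)
  if (is.null(center)) center <- c(fft_center(n1), fft_center(n2))
  c1 <- center[1]; c2 <- center[2]
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  di <- g$i - c1; dj <- g$j - c2
  si <- c1 + cos(theta) * di + sin(theta) * dj
  sj <- c2 - sin(theta) * di + cos(theta) * dj
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  ok <- i0 >= 1 & i0 < n1 & j0 >= 1 & j0 < n2
  v <- rep(fill, n1 * n2)
  idx <- function(i, j) (j - 1L) * n1 + i
  xi <- as.vector(x)
  v[ok] <- xi[idx(i0[ok], j0[ok])] * (1 - wi[ok]) * (1 - wj[ok]) +
    xi[idx(i0[ok] + 1L, j0[ok])] * wi[ok] * (1 - wj[ok]) +
    xi[idx(i0[ok], j0[ok] + 1L)] * (1 - wi[ok]) * wj[ok] +
    xi[idx(i0[ok] + 1L, j0[ok] + 1L)] * wi[ok] * wj[ok]
  matrix(v, n1, n2)
}

# Integer-pixel registration by cross-correlation, then global-phase removal.
# Returns `x` aligned to `ref`; used to fix the FPM reconstruction gauge
# (global phase x integer shift) before any error metric.
align_complex <- function(x, ref) {
  X <- fft2(x); R <- fft2(ref)
  cc <- Mod(ifft2(R * Conj(X)))
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  s1 <- ij[1] - 1L; s2 <- ij[2] - 1L
  n1 <- nrow(x); n2 <- ncol(x)
  x <- x[((seq_len(n1) - 1L - s1) %% n1) + 1L, ((seq_len(n2) - 1L - s2) %% n2) + 1L]
  g <- sum(x * Conj(ref))
  if (Mod(g) > 0) x <- x * Conj(g) / Mod(g)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
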