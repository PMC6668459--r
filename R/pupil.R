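#' Pupil functions and Zernike wavefront analysis
#'
#' The pupil is the complex transfer function of one objective over its
#' NA-bounded spatial-frequency disk; its phase encodes the aberrations that
#' embedded pupil recovery (EPRY) estimates in situ. Zernike indexing follows
#' the Noll convention throughout: index 1 is piston, 2-3 tilt, 4 defocus,
#' 5-6 astigmatism, 11 primary spherical. (Counting defocus as "the fifth
#' coefficient" corresponds to a 0-based enumeration of the same ordering.)
#'
#' @name pupil
NULL

#' Construct a pupil on a spatial-frequency grid
#'
#' @param n Grid side in samples (the low-resolution tile size).
#' @param df Frequency spacing in 1/um (`1 / (n * pixel_um)`).
#' @param cutoff Pupil cutoff `NA / lambda` in 1/um.
#' @param values Optional complex matrix; defaults to the ideal circ function
#'   (amplitude 1 inside the disk).
#' @return Object of class `fpm_pupil` with `values` (complex, centered
#'   frequency order), `mask`, `df`, `cutoff`.
#' @export
make_pupil <- function(n, df, cutoff, values = NULL) {
  fr <- freq_radius(n, df)
  mask <- fr <= cutoff
  if (sum(mask) < 32) stopf("pupil disk is sampled by only %d pixels; enlarge the grid", sum(mask))
  if (is.null(values)) values <- matrix(as.complex(mask), n, n)
  else values[!mask] <- 0 + 0i
  structure(list(values = values, mask = mask, df = df, cutoff = cutoff, n = n),
            class = "fpm_pupil")
}

#' Ideal pupil for a configuration and tile size
#'
#' @param cfg An [optical_config()].
#' @param n Tile side in raw pixels (default `cfg$tile_um / cfg$pixel_um`).
#' @return An `fpm_pupil`.
#' @export
ideal_pupil <- function(cfg, n = round(cfg$tile_um / cfg$pixel_um)) {
  make_pupil(n, df = 1 / (n * cfg$pixel_um), cutoff = cfg$na_obj / cfg$lambda_um)
}

#' @export
print.fpm_pupil <- function(x, ...) {
  cat(sprintf("<fpm_pupil> %d x %d grid, cutoff %.4g 1/um (%d px across the disk)\n",
              x$n, x$n, x$cutoff, 2L * floor(x$cutoff / x$df)))
  invisible(x)
}

# Noll index -> (n, m); m signed (negative = sine mode)
noll_to_nm <- function(j) {
  if (j < 1 || j != round(j)) stopf("invalid Zernike index %g", j)
  n <- 0
  while (j > (n + 1) * (n + 2) / 2) n <- n + 1
  p <- j - n * (n + 1) / 2               # 1-based position within order n
  ms <- seq(n %% 2, n, by = 2)           # |m| ascending
  m_abs <- ms[ceiling((p + (n %% 2 == 0)) / ifelse(ms == 0, 1, 2))]
  # walk the order explicitly (robust to the parity bookkeeping above)
  seqm <- integer(0)
  for (ma in ms) seqm <- c(seqm, if (ma == 0) 0L else c(ma, ma))
  m_abs <- seqm[p]
  if (m_abs == 0) return(c(n = n, m = 0))
  # Noll: even j -> cosine (+m), odd j -> sine (-m)
  c(n = n, m = if (j %% 2 == 0) m_abs else -m_abs)
}

# radial polynomial R_n^|m|(rho)
zernike_radial <- function(n, m_abs, rho) {
  out <- 0
  for (k in 0:((n - m_abs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Zernike basis maps on a pupil disk
#'
#' Noll-indexed, Noll-normalized Zernike polynomials sampled on the pupil's
#' frequency disk (`rho = |f| / cutoff`). Maps are zero outside the disk and
#' numerically orthogonal over it.
#'
#' @param indices Integer vector of Noll indices (e.g. `1:15`).
#' @param pupil An `fpm_pupil` defining the grid, or a plain list with
#'   elements `n`, `df`, `cutoff`.
#' @return 3-D array `n x n x length(indices)`, dimnames on the mode axis.
#' @export
zernike_basis <- function(indices, pupil) {
  n <- pupil$n
  fr <- freq_radius(n, pupil$df)
  rho <- fr / pupil$cutoff
  mask <- rho <= 1
  if (sum(mask) < 32 * 32 / pi) stopf("pupil disk must be resolved by >= 32 samples across")
  fx <- (seq_len(n) - fft_center(n)) * pupil$df
  # azimuth of (row, col) -> (y, x): x runs along columns, y along rows
  theta <- outer(fx, fx, function(y, x) atan2(y, x))
  out <- array(0, dim = c(n, n, length(indices)),
               dimnames = list(NULL, NULL, paste0("Z", indices)))
  for (i in seq_along(indices)) {
    nm <- noll_to_nm(indices[i])
    nn <- nm[1]; m <- nm[2]
    norm <- if (m == 0) sqrt(nn + 1) else sqrt(2 * (nn + 1))
    z <- norm * zernike_radial(nn, abs(m), rho)
    if (m > 0) z <- z * cos(m * theta)
    if (m < 0) z <- z * sin(-m * theta)
    z[!mask] <- 0
    out[, , i] <- z
  }
  out
}

#' Quality-guided phase unwrapping
#'
#' Region-growing unwrap: pixels are absorbed in descending quality order
#' starting from the highest-quality seed, each unwrapped against its already
#' unwrapped neighbor of highest quality. Quality defaults to the pupil
#' amplitude where available (ties broken by descending amplitude), else to
#' local phase smoothness.
#'
#' @param phase Real matrix of wrapped phases (radians).
#' @param mask Logical matrix of valid pixels (default all).
#' @param quality Real matrix; larger = unwrapped earlier.
#' @return Unwrapped phase matrix (NA outside the mask).
#' @export
unwrap_phase <- function(phase, mask = NULL, quality = NULL) {
  n1 <- nrow(phase); n2 <- ncol(phase)
  if (is.null(mask)) mask <- matrix(TRUE, n1, n2)
  if (is.null(quality)) {
    # smoother local phase = higher quality
    wrap <- function(x) (x + pi) %% (2 * pi) - pi
    gy <- rbind(0, abs(wrap(diff(phase))))
    gx <- t(rbind(0, abs(wrap(diff(t(phase))))))
    quality <- -(gx + gy)
  }
  out <- matrix(NA_real_, n1, n2)
  done <- matrix(FALSE, n1, n2)
  seed <- which(mask & quality == max(quality[mask]))[1]
  out[seed] <- phase[seed]; done[seed] <- TRUE
  # frontier kept as vectors, selected by max quality (disk sizes are small)
  nb_off <- c(-1L, 1L, -n1, n1)
  frontier <- integer(0); fq <- numeric(0)
  push_neighbors <- function(p) {
    i <- (p - 1L) %% n1 + 1L
    for (o in nb_off) {
      q <- p + o
      if (o == -1L && i == 1L) next
      if (o == 1L && i == n1) next
      if (q < 1L || q > n1 * n2) next
      if (mask[q] && !done[q] && !(q %in% frontier)) {
        frontier <<- c(frontier, q); fq <<- c(fq, quality[q])
      }
    }
  }
  push_neighbors(seed)
  while (length(frontier) > 0) {
    k <- which.max(fq)
    p <- frontier[k]
    frontier <- frontier[-k]; fq <- fq[-k]
    # unwrap against the best done neighbor
    i <- (p - 1L) %% n1 + 1L
    best <- NA_integer_; bestq <- -Inf
    for (o in nb_off) {
      q <- p + o
      if (o == -1L && i == 1L) next
      if (o == 1L && i == n1) next
      if (q < 1L || q > n1 * n2) next
      if (done[q] && quality[q] > bestq) { best <- q; bestq <- quality[q] }
    }
    out[p] <- out[best] + (phase[p] - out[best] + pi) %% (2 * pi) - pi
    done[p] <- TRUE
    push_neighbors(p)
  }
  out
}

#' Fit Zernike coefficients to a pupil phase map
#'
#' Least-squares projection of the (internally unwrapped) phase onto the first
#' `K` Noll modes over the pupil support. A noise-free synthesized phase is
#' recovered to machine precision.
#'
#' @param pupil An `fpm_pupil` (its phase is fitted) or a real phase matrix.
#' @param K Number of modes (default 15).
#' @param grid Required when `pupil` is a plain matrix: an `fpm_pupil`-like
#'   list giving `n`, `df`, `cutoff`.
#' @param unwrap Unwrap the phase first (default TRUE).
#' @return Object of class `zernike_coeffs`: numeric vector of length `K`
#'   (radians) with attributes `K` and `indices`.
#' @export
fit_zernike <- function(pupil, K = 15, grid = NULL, unwrap = TRUE) {
  if (inherits(pupil, "fpm_pupil")) {
    phase <- Arg(pupil$values)
    quality <- Mod(pupil$values)
    grid <- pupil
  } else {
    phase <- pupil
    quality <- NULL
    if (is.null(grid)) stopf("grid must be supplied when fitting a plain phase matrix")
  }
  fr <- freq_radius(grid$n, grid$df)
  mask <- fr <= grid$cutoff
  if (K > sum(mask) / 4) stopf("K = %d exceeds the mode count supported by %d disk samples",
                               K, sum(mask))
  if (unwrap) phase <- unwrap_phase(phase, mask, quality)
  B <- zernike_basis(seq_len(K), grid)
  Bm <- matrix(B[rep(mask, K)], ncol = K)
  co <- qr.solve(Bm, phase[mask])
  structure(as.numeric(co), K = K, indices = seq_len(K), class = "zernike_coeffs")
}

#' @export
print.zernike_coeffs <- function(x, ...) {
  cat("<zernike_coeffs> (Noll, radians)\n")
  print(round(stats::setNames(as.numeric(x), paste0("Z", seq_along(x))), 4))
  invisible(x)
}

#' Synthesize a phase map from Zernike coefficients
#'
#' @param coeffs Numeric vector of Noll coefficients (radians).
#' @param pupil Grid definition (`fpm_pupil` or list with `n`, `df`, `cutoff`).
#' @return Real phase matrix (zero outside the disk).
#' @export
zernike_phase <- function(coeffs, pupil) {
  B <- zernike_basis(seq_along(coeffs), pupil)
  out <- matrix(0, pupil$n, pupil$n)
  for (i in seq_along(coeffs)) out <- out + coeffs[i] * B[, , i]
  out
}

#' Angular-spectrum defocus phase
#'
#' Phase kernel of free-space propagation by `dz_um`:
#' `phi(f) = 2 pi dz (sqrt(1/lambda^2 - |f|^2) - 1/lambda)`, anchored so the
#' on-axis (f = 0) phase is zero. Multiplying the pupil by `exp(1i * phi)`
#' refocuses the reconstruction by `dz_um`; in the small-NA limit it is the
#' familiar quadratic defocus `-pi lambda dz |f|^2`.
#'
#' @param dz_um Axial shift in um (|dz| <= 500).
#' @param cfg An [optical_config()].
#' @param pupil Grid definition (`fpm_pupil` or list with `n`, `df`, `cutoff`).
#' @return Real phase matrix in radians (zero outside the pupil disk).
#' @export
defocus_phase <- function(dz_um, cfg, pupil) {
  if (abs(dz_um) > 500) stopf("|dz| = %g um exceeds the supported 500 um", abs(dz_um))
  fr <- freq_radius(pupil$n, pupil$df)
  mask <- fr <= pupil$cutoff
  lam <- cfg$lambda_um
  kz <- sqrt(pmax(1 / lam^2 - fr^2, 0))
  phi <- 2 * pi * dz_um * (kz - 1 / lam)
  phi[!mask] <- 0
  phi
}

#' Rotation-invariant Zernike mode magnitudes
#'
#' Collapses each cos/sin azimuthal pair into its rotation-invariant magnitude
#' `sqrt(a^2 + b^2)`; rotationally symmetric modes (m = 0) pass through as
#' absolute values. Rotating the pupil phase leaves these magnitudes
#' unchanged, which makes them comparable across lens barrels mounted at
#' arbitrary rotations.
#'
#' @param coeffs A `zernike_coeffs` (or numeric vector, Noll order).
#' @return Data frame `n`, `m_abs`, `mode`, `magnitude_rad`.
#' @export
rotation_invariant_modes <- function(coeffs) {
  co <- as.numeric(coeffs)
  nm <- t(vapply(seq_along(co), noll_to_nm, numeric(2)))
  key <- paste(nm[, 1], abs(nm[, 2]))
  groups <- unique(key)
  names_tab <- c("0 0" = "piston", "1 1" = "tilt", "2 0" = "defocus",
                 "2 2" = "astigmatism", "3 1" = "coma", "3 3" = "trefoil",
                 "4 0" = "spherical", "4 2" = "secondary astigmatism",
                 "4 4" = "quadrafoil")
  out <- lapply(groups, function(g) {
    idx <- which(key == g)
    nmg <- nm[idx[1], ]
    data.frame(n = nmg[1], m_abs = abs(nmg[2]),
               mode = unname(names_tab[g] %||% g),
               magnitude_rad = sqrt(sum(co[idx]^2)))
  })
  do.call(rbind, out)
}

#' RMS wavefront difference between two pupils
#'
#' Root-mean-square of the piston-removed phase difference over the common
#' pupil support; invariant to a constant phase offset between the two.
#'
#' @param p1,p2 `fpm_pupil` objects on the same grid.
#' @return RMS difference in radians.
#' @export
rms_wavefront_diff <- function(p1, p2) {
  if (p1$n != p2$n || abs(p1$df - p2$df) > 1e-12)
    stopf("pupils live on different grids (%d/%g vs %d/%g)", p1$n, p1$df, p2$n, p2$df)
  supp <- p1$mask & p2$mask
  dphi <- Arg(p1$values[supp] * Conj(p2$values[supp]))
  piston <- Arg(sum(exp(1i * dphi)))
  dphi <- Arg(exp(1i * (dphi - piston)))
  sqrt(mean(dphi^2))
}
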