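#' Reconstruction configuration
#'
#' Tunable parameters of the EPRY phase-retrieval loop. The adaptive step
#' rule halves both step sizes whenever the epoch residual has failed to
#' improve by at least 1% for `adapt_patience` consecutive epochs.
#'
#' @param n_iters Number of epochs (full passes over all frames; default 30).
#' @param step_obj,step_pupil Initial object / pupil step sizes (default 1).
#' @param adapt_factor Multiplier applied on stagnation, in (0, 1) (default 0.5).
#' @param adapt_patience Stagnant epochs tolerated before shrinking (default 2).
#' @param upsample Spectral upsampling factor (default 4).
#' @param pupil_recovery Update the pupil jointly with the object (default TRUE).
#' @param pupil_reg Regularization weight `gamma` in `(0, 1]` of the pupil
#'   update denominator `(1 - gamma) |O|^2 + gamma max|O|^2` (default 0.01).
#'   Small values let weakly illuminated pupil regions (the rim, which the
#'   brightfield LED set barely reaches) keep pace with the bright center;
#'   `gamma = 1` gives the plain max-normalized update.
#' @param seed Optional integer seed (reconstruction is deterministic; kept
#'   for provenance).
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(n_iters = 30, step_obj = 1, step_pupil = 1,
                         adapt_factor = 0.5, adapt_patience = 2,
                         upsample = 4, pupil_recovery = TRUE, pupil_reg = 0.01,
                         seed = NULL) {
  if (adapt_factor <= 0 || adapt_factor >= 1) stopf("adapt_factor must be in (0, 1)")
  if (n_iters < 1 || step_obj <= 0 || step_pupil <= 0) stopf("invalid recon_config")
  if (pupil_reg <= 0 || pupil_reg > 1) stopf("pupil_reg must be in (0, 1]")
  structure(list(n_iters = n_iters, step_obj = step_obj, step_pupil = step_pupil,
                 adapt_factor = adapt_factor, adapt_patience = adapt_patience,
                 upsample = as.integer(upsample), pupil_recovery = pupil_recovery,
                 pupil_reg = pupil_reg, seed = seed),
            class = "recon_config")
}

# spectral bookkeeping shared by reconstruction and residual evaluation
.recon_geometry <- function(ds, upsample) {
  d <- dim(ds$frames)
  n_lo <- d[2]
  n_hr <- n_lo * upsample
  df <- 1 / (n_lo * ds$cfg$pixel_um)
  kpx <- round(ds$k_eff / df)
  list(n_lo = n_lo, n_hr = n_hr, df = df, kpx = kpx,
       c_hr = fft_center(n_hr), lo_idx = seq_len(n_lo) - fft_center(n_lo))
}

# initial object spectrum: bilinearly upsampled sqrt of the most axial frame,
# zero phase (deterministic, standard initialization)
.init_object_spectrum <- function(ds, geom) {
  j0 <- which.min(rowSums(ds$k_eff^2))
  amp <- sqrt(pmax(ds$frames[j0, , ], 0))
  fftshift2(fft2(bilinear_resize(amp, geom$n_hr) + 0i))
}

# One pass over all frames. Mutates nothing; returns updated state and the
# pre-update epoch residual sum( (sqrt(I) - |psi|)^2 ).
.epry_epoch <- function(Ohat, P, ds, geom, order, alpha, beta, upsample,
                        pupil_mask, update_pupil, pupil_reg = 0.01) {
  err <- 0
  up2 <- upsample^2
  for (j in order) {
    rows <- geom$c_hr + geom$kpx[j, 2] + geom$lo_idx
    cols <- geom$c_hr + geom$kpx[j, 1] + geom$lo_idx
    Psi <- Ohat[rows, cols] * P
    psi <- ifft2(ifftshift2(Psi))
    a <- Mod(psi)
    sq <- sqrt(pmax(ds$frames[j, , ], 0)) * up2      # forward scaling: see forward_fpm
    err <- err + sum((sq - a)^2)
    psi2 <- psi * (sq / pmax(a, 1e-12))
    dPsi <- fftshift2(fft2(psi2)) - Psi
    Owin <- Ohat[rows, cols]
    Ohat[rows, cols] <- Owin + alpha * Conj(P) * dPsi / max(Mod(P)^2)
    if (update_pupil) {
      aw2 <- Mod(Owin)^2
      P <- P + beta * Conj(Owin) * dPsi / ((1 - pupil_reg) * aw2 + pupil_reg * max(aw2))
      P[!pupil_mask] <- 0 + 0i
      amp <- Mod(P)
      over <- amp > 1.5                               # divergence guard
      if (any(over)) P[over] <- P[over] * (1.5 / amp[over])
    }
    if (any(is.na(Ohat[rows, cols])))
      stopf("EPRY overflow/NaN at frame %d", j)
  }
  list(Ohat = Ohat, P = P, err = err)
}

#' EPRY phase retrieval (embedded pupil function recovery)
#'
#' Iterative Fourier-ptychographic reconstruction: for each frame the
#' pupil-supported sub-spectrum at the frame's illumination shift is
#' extracted, propagated to the sensor, its magnitude replaced by the
#' measured `sqrt(I)`, and the mismatch fed back through the paired gradient
#' updates of the object spectrum and (optionally) the pupil:
#' `O <- O + alpha conj(P) dPsi / max|P|^2`,
#' `P <- P + beta conj(O) dPsi / max|O|^2`.
#' Frames are visited in ascending `|k|` order (most axial first); step sizes
#' shrink adaptively on residual stagnation. The recovered object is defined
#' up to a global phase and a sub-pixel shift; use the gauge alignment in the
#' test helpers before comparing against ground truth.
#'
#' @param ds An [fpm_dataset()] with at least 9 frames.
#' @param init_pupil Initial pupil (`fpm_pupil`); defaults to the ideal pupil.
#'   Fold a [defocus_phase()] kernel in here to seed computational refocusing.
#' @param rc A [recon_config()].
#' @return Object of class `fpm_recon`: `object` ([fpm_object()]), `pupil`,
#'   `residuals` (one per epoch, normalized by total measured energy),
#'   `delta_z_um` (NA unless set by [refocus_search()]), `cfg`.
#' @export
epry_reconstruct <- function(ds, init_pupil = NULL, rc = recon_config()) {
  d <- dim(ds$frames)
  if (d[1] < 9) stopf("EPRY needs >= 9 frames, got %d", d[1])
  if (d[2] != d[3]) stopf("frames must be square, got %d x %d", d[2], d[3])
  geom <- .recon_geometry(ds, rc$upsample)
  if (any(geom$c_hr + geom$kpx + max(abs(geom$lo_idx)) > geom$n_hr) ||
      any(geom$c_hr + geom$kpx - max(abs(geom$lo_idx)) < 1))
    stopf("k_eff inconsistent with cfg: spectrum window out of bounds")
  P0 <- init_pupil %||% ideal_pupil(ds$cfg, geom$n_lo)
  if (P0$n != geom$n_lo) stopf("init pupil grid %d does not match tile %d", P0$n, geom$n_lo)
  Ohat <- .init_object_spectrum(ds, geom)
  P <- P0$values
  order <- order(rowSums(ds$k_eff^2))
  total_I <- sum(ds$frames) * rc$upsample^4
  alpha <- rc$step_obj; beta <- rc$step_pupil
  residuals <- numeric(0)
  stagnant <- 0
  for (ep in seq_len(rc$n_iters)) {
    st <- .epry_epoch(Ohat, P, ds, geom, order, alpha, beta, rc$upsample,
                      P0$mask, rc$pupil_recovery, rc$pupil_reg)
    Ohat <- st$Ohat; P <- st$P
    residuals <- c(residuals, st$err / total_I)
    if (ep > 1) {
      if (residuals[ep] > residuals[ep - 1] * 0.99) stagnant <- stagnant + 1
      else stagnant <- 0
      if (stagnant >= rc$adapt_patience) {
        alpha <- alpha * rc$adapt_factor
        beta <- beta * rc$adapt_factor
        stagnant <- 0
      }
    }
  }
  obj <- ifft2(ifftshift2(Ohat))
  structure(list(
    object = fpm_object(obj, ds$cfg$pixel_um / rc$upsample),
    pupil = make_pupil(geom$n_lo, geom$df, P0$cutoff, values = P),
    residuals = residuals, delta_z_um = NA_real_, cfg = ds$cfg, rc = rc
  ), class = "fpm_recon")
}

#' @export
print.fpm_recon <- function(x, ...) {
  cat(sprintf("<fpm_recon> %d x %d object at %g um/px; %d epochs, final residual %.3g%s\n",
              nrow(x$object$values), ncol(x$object$values), x$object$pixel_um,
              length(x$residuals), utils::tail(x$residuals, 1),
              if (!is.na(x$delta_z_um)) sprintf("; dz = %g um", x$delta_z_um) else ""))
  invisible(x)
}

#' @export
plot.fpm_recon <- function(x, ...) {
  graphics::plot(seq_along(x$residuals), x$residuals, type = "b", log = "y",
                 xlab = "epoch", ylab = "normalized residual", ...)
  invisible(x)
}

#' Normalized reconstruction residual
#'
#' `sum_j sum_px (sqrt(I_j) - |psi_j(obj, pupil)|)^2 / sum_j sum_px I_j`:
#' zero iff the forward model reproduces every frame's magnitude. Invariant
#' to a global phase of the object. This is the quantity the blind refocus
#' search minimizes.
#'
#' @param ds An [fpm_dataset()].
#' @param obj An [fpm_object()] at the upsampled pixel.
#' @param pupil An `fpm_pupil` on the tile grid.
#' @return Non-negative scalar.
#' @export
reconstruction_residual <- function(ds, obj, pupil) {
  upsample <- round(ds$cfg$pixel_um / obj$pixel_um)
  geom <- .recon_geometry(ds, upsample)
  Ohat <- fftshift2(fft2(obj$values))
  err <- 0
  up2 <- upsample^2
  for (j in seq_len(dim(ds$frames)[1])) {
    rows <- geom$c_hr + geom$kpx[j, 2] + geom$lo_idx
    cols <- geom$c_hr + geom$kpx[j, 1] + geom$lo_idx
    psi <- ifft2(ifftshift2(Ohat[rows, cols] * pupil$values))
    err <- err + sum((sqrt(pmax(ds$frames[j, , ], 0)) - Mod(psi) / up2)^2)
  }
  err / sum(ds$frames)
}

#' Two-stage blind computational refocusing
#'
#' Stage 1 scans defocus candidates over `[-z_range_um, +z_range_um]` at
#' `coarse_step_um` spacing; each candidate is scored by the reconstruction
#' residual of a short (3-epoch, object-only) reconstruction whose pupil is
#' the ideal pupil times the candidate's [defocus_phase()] kernel. Stage 2
#' runs the full EPRY reconstruction seeded at the argmin, with the defocus
#' kernel folded into the initial pupil so embedded pupil recovery only has
#' to absorb the residual aberrations. On simulated data the estimate lands
#' within one coarse step of the true offset.
#'
#' @param ds An [fpm_dataset()].
#' @param z_range_um Half-range of the scan in um (<= 150).
#' @param coarse_step_um Scan step in um (default 5).
#' @param rc A [recon_config()] for the stage-2 reconstruction.
#' @param stage1_epochs Epochs per candidate in the scan (default 3).
#' @return List: `delta_z_um` (the argmin), `result` (the stage-2
#'   [epry_reconstruct()] output with `delta_z_um` set), `trace` (data frame
#'   `dz_um`, `residual`). Warns if the residual trace is not unimodal and
#'   returns the global argmin.
#' @export
refocus_search <- function(ds, z_range_um = 100, coarse_step_um = 5,
                           rc = recon_config(), stage1_epochs = 3) {
  if (z_range_um > 150) stopf("z_range_um must be <= 150 (characterized range)")
  geom <- .recon_geometry(ds, rc$upsample)
  P0 <- ideal_pupil(ds$cfg, geom$n_lo)
  Ohat0 <- .init_object_spectrum(ds, geom)
  order <- order(rowSums(ds$k_eff^2))
  candidates <- seq(-z_range_um, z_range_um, by = coarse_step_um)
  total_I <- sum(ds$frames) * rc$upsample^4
  resid <- vapply(candidates, function(dz) {
    P <- P0$values * exp(1i * defocus_phase(dz, ds$cfg, P0))
    Ohat <- Ohat0
    err <- NA_real_
    for (ep in seq_len(stage1_epochs)) {
      st <- .epry_epoch(Ohat, P, ds, geom, order, rc$step_obj, 0, rc$upsample,
                        P0$mask, update_pupil = FALSE)
      Ohat <- st$Ohat
      err <- st$err
    }
    err / total_I
  }, numeric(1))
  i_min <- which.min(resid)
  # unimodality check: warn when a second, competitive local minimum exists
  # (prominence above 5% of the trace range; numerical jitter is ignored)
  s <- sign(diff(resid))
  s <- s[s != 0]
  n_min <- sum(diff(s) > 0) + (length(s) > 0 && s[1] > 0)
  competitive <- resid <= min(resid) + 0.05 * max(diff(range(resid)), 1e-15)
  if (n_min > 1 && sum(diff(which(competitive)) > 1) > 0)
    warning("refocus residual trace is not unimodal; returning the global argmin")
  dz_hat <- candidates[i_min]
  init <- make_pupil(P0$n, P0$df, P0$cutoff,
                     values = P0$values * exp(1i * defocus_phase(dz_hat, ds$cfg, P0)))
  res <- epry_reconstruct(ds, init_pupil = init, rc = rc)
  res$delta_z_um <- dz_hat
  list(delta_z_um = dz_hat, result = res,
       trace = data.frame(dz_um = candidates, residual = resid))
}
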