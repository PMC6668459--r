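# Shared fixtures: everything is generated in code, sized for speed
# (small 64-px tiles; the acceptance tests use the full instrument tile).

test_cfg <- function(...) optical_config(...)

test_geometry <- function() {
  layout <- well_layout()
  list(cfg = optical_config(), layout = layout, grid = build_led_grid(layout))
}

# 7x7 per-well LED segment offsets (mm), centered on the well
segment_offsets <- function(pitch = 3, half = 3) {
  as.matrix(expand.grid(x = seq(-half * pitch, half * pitch, pitch),
                        y = seq(-half * pitch, half * pitch, pitch)))
}

# illumination wavevectors of the 7x7 segment, optionally brightfield-only
segment_k <- function(cfg, grid, brightfield = TRUE) {
  offs <- segment_offsets()
  k <- t(apply(offs, 1, function(o) illumination_wavevector(c(o[1], o[2]),
                                                            c(0, 0), grid, cfg)))
  if (brightfield) k <- k[sqrt(rowSums(k^2)) * cfg$lambda_um <= cfg$na_obj, ]
  k
}

# small consistent star acquisition: returns everything a recon test needs
star_acquisition <- function(n_lo = 64, upsample = 4, n_spokes = 16,
                             zernike = NULL, dz_um = 0, cfg = optical_config()) {
  geo <- test_geometry()
  obj <- siemens_star(n_spokes, phase_depth = 1, extent_um = n_lo * cfg$pixel_um,
                      pixel_um = cfg$pixel_um / upsample)
  pup <- ideal_pupil(cfg, n_lo)
  ph <- matrix(0, n_lo, n_lo)
  if (!is.null(zernike)) ph <- ph + zernike_phase(zernike, pup)
  if (dz_um != 0) ph <- ph + defocus_phase(dz_um, cfg, pup)
  ptrue <- make_pupil(n_lo, pup$df, pup$cutoff,
                      values = pup$values * exp(1i * ph))
  k <- segment_k(cfg, geo$grid)
  ds <- forward_fpm(obj, ptrue, k, cfg, upsample)
  list(obj = obj, pupil_true = ptrue, pupil_ideal = pup, ds = ds, k = k,
       cfg = cfg, grid = geo$grid, upsample = upsample, n_lo = n_lo,
       n_spokes = n_spokes)
}

# recovered-phase star read-out after gauge alignment to the truth
recovered_star_resolution <- function(res, acq) {
  rec <- fpmtools:::align_complex(res$object$values, acq$obj$values)
  star_resolution(Arg(rec), acq$n_spokes, acq$obj$pixel_um)
}

# piston/tilt-removed RMS between a recovered and a true pupil (difference
# map unwrapped, then the fitted piston+tilt plane subtracted)
pupil_error_rms <- function(p_rec, p_true) {
  supp <- p_rec$mask & p_true$mask
  d <- matrix(0, p_rec$n, p_rec$n)
  d[supp] <- Arg(p_rec$values[supp] * Conj(p_true$values[supp]))
  u <- unwrap_phase(d, supp)
  B <- zernike_basis(1:3, p_rec)
  Bm <- cbind(B[, , 1][supp], B[, , 2][supp], B[, , 3][supp])
  resid <- u[supp] - Bm %*% qr.solve(Bm, u[supp])
  sqrt(mean(resid^2))
}
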