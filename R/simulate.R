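#' Complex object (high-resolution transmission map)
#'
#' @param values Complex matrix, object-side transmission.
#' @param pixel_um Pixel pitch in um.
#' @return Object of class `fpm_object`.
#' @export
fpm_object <- function(values, pixel_um) {
  structure(list(values = values, pixel_um = pixel_um), class = "fpm_object")
}

#' @export
print.fpm_object <- function(x, ...) {
  cat(sprintf("<fpm_object> %d x %d at %g um/px (%g um field)\n",
              nrow(x$values), ncol(x$values), x$pixel_um, nrow(x$values) * x$pixel_um))
  invisible(x)
}

#' Phase-only Siemens star resolution target
#'
#' A radial spoke target whose local spatial period shrinks linearly with
#' radius: at radius `r` the full azimuthal period is `2 pi r / n_spoke_pairs`
#' um, so resolution can be read off as the smallest radius at which the
#' spokes remain resolved. The phase alternates between 0 and `phase_depth`
#' inside a disk of diameter `0.9 * extent_um`; the amplitude is 1 everywhere
#' (a pure phase target, like a pattern etched into glass).
#'
#' @param n_spoke_pairs Number of full azimuthal periods (default 40).
#' @param phase_depth Phase step in radians (default 1).
#' @param extent_um Field side in um (default 110).
#' @param pixel_um Pixel pitch in um (default 0.1).
#' @return An [fpm_object()].
#' @export
siemens_star <- function(n_spoke_pairs = 40, phase_depth = 1,
                         extent_um = 110, pixel_um = 0.1) {
  if (n_spoke_pairs < 4) stopf("need at least 4 spoke pairs")
  n <- round(extent_um / pixel_um)
  if (n < 128) stopf("extent/pixel = %d; the star needs >= 128 samples", n)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_um
  x <- outer(rep(1, n), ax)              # x along columns
  y <- outer(rev(ax), rep(1, n))         # y up along rows
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  spoke <- (th %% (2 * pi / n_spoke_pairs)) < (pi / n_spoke_pairs)
  ph <- ifelse(spoke & r <= 0.45 * extent_um, phase_depth, 0)
  fpm_object(exp(1i * ph), pixel_um)
}

#' Field of phase microbeads
#'
#' Non-overlapping spherical beads (default 2 um diameter) placed by seeded
#' rejection sampling; each bead adds a phase equal to `phase_contrast` times
#' its normalized chord thickness, mimicking polystyrene microspheres in
#' buffer.
#'
#' @param n_beads Number of beads.
#' @param bead_diameter_um Bead diameter in um (default 2).
#' @param phase_contrast Peak phase per bead in radians (default 1).
#' @param extent_um Field side in um.
#' @param pixel_um Pixel pitch in um.
#' @param seed Integer seed; identical seeds give identical fields.
#' @param max_tries Rejection-sampling cap per bead.
#' @return An [fpm_object()] with attribute `centers_um`.
#' @export
bead_field <- function(n_beads, bead_diameter_um = 2, phase_contrast = 1,
                       extent_um = 110, pixel_um = 0.1, seed = 1,
                       max_tries = 2000) {
  n <- round(extent_um / pixel_um)
  set.seed(seed)
  rad <- bead_diameter_um / 2
  lim <- 0.45 * extent_um - rad
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < n_beads) {
    cand <- (stats::runif(2) * 2 - 1) * lim
    ok <- nrow(centers) == 0 ||
      all(sqrt(rowSums((t(t(centers) - cand))^2)) >= bead_diameter_um)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > max_tries * max(n_beads, 1))
      stopf("could not place %d beads without overlap; lower the density", n_beads)
  }
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_um
  ph <- matrix(0, n, n)
  if (n_beads > 0) for (b in seq_len(nrow(centers))) {
    dx2 <- outer(rep(1, n), (ax - centers[b, 1])^2)
    dy2 <- outer((rev(ax) - centers[b, 2])^2, rep(1, n))
    r2 <- dx2 + dy2
    ph <- ph + phase_contrast * sqrt(pmax(1 - r2 / rad^2, 0))
  }
  out <- fpm_object(exp(1i * ph), pixel_um)
  attr(out, "centers_um") <- centers
  out
}

#' Cell-like phase phantom
#'
#' Smooth blobs (cytoplasm) with denser nuclei, built from seeded Gaussian
#' bumps. A stand-in for adherent cell monolayers: it shares their smooth,
#' low-contrast phase character but none of their fine organellar texture.
#'
#' @param n_cells Number of cells.
#' @param extent_um,pixel_um Field geometry in um.
#' @param phase_scale Peak cytoplasm phase in radians (default 1.5).
#' @param seed Integer seed.
#' @return An [fpm_object()].
#' @export
cell_phantom <- function(n_cells = 5, extent_um = 110, pixel_um = 0.1,
                         phase_scale = 1.5, seed = 1) {
  n <- round(extent_um / pixel_um)
  set.seed(seed)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_um
  ph <- matrix(0, n, n)
  lim <- 0.4 * extent_um
  for (i in seq_len(n_cells)) {
    c0 <- (stats::runif(2) * 2 - 1) * lim
    rc <- stats::runif(1, 6, 12)            # cell radius, um
    rn <- rc * stats::runif(1, 0.25, 0.4)   # nucleus
    d2 <- outer((rev(ax) - c0[2])^2, rep(1, n)) + outer(rep(1, n), (ax - c0[1])^2)
    ph <- ph + phase_scale * (0.6 * exp(-d2 / (2 * (rc / 2)^2)) +
                                0.4 * exp(-d2 / (2 * (rn / 2)^2)))
  }
  fpm_object(exp(1i * ph), pixel_um)
}

#' FPM dataset: intensity stack plus per-frame illumination wavevectors
#'
#' The sole input contract of reconstruction: `frames` is an
#' `n_frames x H x W` array of non-negative intensities at the raw (sensor)
#' sampling, `k_eff` the matching per-frame spatial-frequency pairs in 1/um.
#'
#' @param frames 3-D numeric array `n_frames x H x W`.
#' @param k_eff Numeric matrix `n_frames x 2` (1/um); `|k| * lambda < 1`.
#' @param cfg An [optical_config()].
#' @param provenance Optional list of simulation or acquisition metadata.
#' @return Object of class `fpm_dataset`.
#' @export
fpm_dataset <- function(frames, k_eff, cfg, provenance = list()) {
  if (length(dim(frames)) != 3) stopf("frames must be n_frames x H x W")
  if (dim(frames)[1] != nrow(k_eff)) stopf("frame count %d does not match k_eff rows %d",
                                           dim(frames)[1], nrow(k_eff))
  if (dim(frames)[1] < 1) stopf("need at least one frame")
  if (min(frames) < 0) stopf("intensities must be non-negative")
  if (any(sqrt(rowSums(k_eff^2)) * cfg$lambda_um >= 1))
    stopf("|k_eff| * lambda must be < 1 (direction-cosine bound)")
  structure(list(frames = frames, k_eff = as.matrix(k_eff), cfg = cfg,
                 provenance = provenance),
            class = "fpm_dataset")
}

#' @export
print.fpm_dataset <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fpm_dataset> %d frames of %d x %d px (%g um/px), NA_illum up to %.3f\n",
              d[1], d[2], d[3], x$cfg$pixel_um,
              max(sqrt(rowSums(x$k_eff^2))) * x$cfg$lambda_um))
  invisible(x)
}

#' Coherent FPM forward model
#'
#' For each illumination `k_j`: shift the object spectrum by `k_j` (rounded to
#' the common spectral grid), multiply by the pupil, inverse-transform, and
#' record the squared magnitude at the sensor sampling. Downsampling happens
#' by spectral cropping, which keeps this forward model the exact adjoint of
#' the reconstruction's spectrum updates. Intensities are normalized so a
#' unit-amplitude object under on-axis illumination through an ideal pupil
#' yields mean intensity 1.
#'
#' @param obj An [fpm_object()] at pixel `cfg$pixel_um / upsample`.
#' @param pupil An `fpm_pupil` on the low-resolution tile grid.
#' @param k_list Matrix `n x 2` of illumination spatial frequencies (1/um).
#' @param cfg An [optical_config()].
#' @param upsample Integer ratio of sensor pixel to object pixel (>= 2).
#' @return An [fpm_dataset()]; provenance records the rounded pixel shifts.
#' @export
forward_fpm <- function(obj, pupil, k_list, cfg, upsample = cfg$upsample) {
  if (upsample < 2) stopf("upsample must be >= 2")
  if (abs(obj$pixel_um * upsample - cfg$pixel_um) > 1e-9)
    stopf("object pixel %g um is not cfg pixel / upsample", obj$pixel_um)
  n_hr <- nrow(obj$values)
  n_lo <- n_hr / upsample
  if (n_lo != round(n_lo)) stopf("object side %d is not a multiple of upsample", n_hr)
  n_lo <- as.integer(n_lo)
  if (pupil$n != n_lo) stopf("pupil grid %d does not match tile size %d", pupil$n, n_lo)
  df <- 1 / (n_hr * obj$pixel_um)          # == 1 / (n_lo * cfg$pixel_um)
  k_list <- rbind(k_list)
  kpx <- round(k_list / df)
  c_hr <- fft_center(n_hr); c_lo <- fft_center(n_lo)
  lo_idx <- seq_len(n_lo) - c_lo
  Ohat <- fftshift2(fft2(obj$values))
  frames <- array(0, dim = c(nrow(k_list), n_lo, n_lo))
  for (j in seq_len(nrow(k_list))) {
    rows <- c_hr + kpx[j, 2] + lo_idx      # rows index fy
    cols <- c_hr + kpx[j, 1] + lo_idx
    if (min(rows, cols) < 1 || max(rows, cols) > n_hr)
      stopf("k[%d] = (%.3g, %.3g) 1/um falls outside the simulated spectrum", j,
            k_list[j, 1], k_list[j, 2])
    Psi <- Ohat[rows, cols] * pupil$values
    psi <- ifft2(ifftshift2(Psi))
    frames[j, , ] <- (Mod(psi) / upsample^2)^2
  }
  fpm_dataset(frames, k_list, cfg,
              provenance = list(type = "simulation", upsample = upsample,
                                k_px = kpx, df = df))
}

#' Sensor noise and repeated exposures
#'
#' Applies the consumer-CMOS noise model to every frame of a dataset:
#' Poisson shot noise at `photons_per_unit` photons per intensity unit,
#' additive Gaussian read noise, and one static horizontal-band fixed pattern
#' that repeats identically across all repeats and illuminations (the
#' band-like pattern that digital averaging cannot remove but
#' [remove_static_pattern()] can). Returns `n_repeats` noisy exposures per
#' illumination, in photon units.
#'
#' @param ds An [fpm_dataset()].
#' @param photons_per_unit Photons per intensity unit (default 2000).
#' @param read_noise_sd Read noise standard deviation in photons (default 5).
#' @param band_pattern_amp Peak amplitude of the static band pattern in
#'   photons (default 0 = off).
#' @param n_repeats Exposures per illumination (default 1).
#' @param seed Integer seed; all randomness flows through it.
#' @return List of [frame_sequence()] objects, one per illumination, with
#'   attributes `band_pattern` (the injected truth) and `scale`
#'   (`photons_per_unit`).
#' @export
add_sensor_noise <- function(ds, photons_per_unit = 2000, read_noise_sd = 5,
                             band_pattern_amp = 0, n_repeats = 1, seed = 1) {
  if (photons_per_unit <= 0 || read_noise_sd < 0 || band_pattern_amp < 0 ||
      n_repeats < 1) stopf("noise scales must be positive")
  d <- dim(ds$frames)
  set.seed(seed)
  band <- if (band_pattern_amp > 0) {
    # smooth static row profile: band-like structure along the row axis
    prof <- stats::filter(stats::rnorm(d[2] + 20), rep(1 / 7, 7), circular = TRUE)
    prof <- as.numeric(prof)[seq_len(d[2])]
    band_pattern_amp * outer(prof / max(abs(prof)), rep(1, d[3]))
  } else matrix(0, d[2], d[3])
  # photons_per_unit = Inf disables shot noise (frames kept in intensity units)
  shot_off <- is.infinite(photons_per_unit)
  scale <- if (shot_off) 1 else photons_per_unit
  out <- vector("list", d[1])
  for (j in seq_len(d[1])) {
    lam <- ds$frames[j, , ] * scale
    reps <- array(0, dim = c(n_repeats, d[2], d[3]))
    for (r in seq_len(n_repeats)) {
      shot <- if (shot_off) lam else matrix(stats::rpois(length(lam), lam), d[2], d[3])
      noise <- if (read_noise_sd > 0)
        matrix(stats::rnorm(length(lam), 0, read_noise_sd), d[2], d[3]) else 0
      reps[r, , ] <- shot + noise + band
    }
    out[[j]] <- frame_sequence(reps, illumination = j)
  }
  attr(out, "band_pattern") <- band
  attr(out, "scale") <- scale
  attr(out, "k_eff") <- ds$k_eff
  attr(out, "cfg") <- ds$cfg
  out
}

#' Simulate every well of a plate acquisition
#'
#' Runs the full forward chain per well: illumination wavevectors from the
#' plan via meniscus ray tracing at the tile center, a per-well aberrated
#' pupil drawn from lens-population Zernike statistics, a per-well defocus
#' offset mimicking plate warp, and the coherent forward model. Defaults
#' reflect the measured lens population (astigmatism sigma 0.88 rad,
#' spherical sigma 0.25 rad) and plate-depth spread (sigma 17 um).
#'
#' @param objects Named list of [fpm_object()], one per simulated well
#'   (names are well IDs from the layout, e.g. `"A1"`).
#' @param plan An [schedule_parallel_illumination()] result.
#' @param grid,layout,cfg Geometry as elsewhere.
#' @param model A [meniscus_model()]; `NULL` for no liquid.
#' @param pupils Optional named list of `fpm_pupil`s; drawn if `NULL`.
#' @param dz_offsets_um Optional named numeric; drawn if `NULL`.
#' @param sigma_astig,sigma_spherical,sigma_dz_um Draw statistics.
#' @param upsample Forward-model upsampling.
#' @param seed Integer seed.
#' @return Named list of [fpm_dataset()]s; each carries `truth` (object,
#'   pupil, dz, led ids) in its provenance.
#' @export
simulate_well_plate <- function(objects, plan, grid, layout, cfg, model = NULL,
                                pupils = NULL, dz_offsets_um = NULL,
                                sigma_astig = 0.88, sigma_spherical = 0.25,
                                sigma_dz_um = 17, upsample = cfg$upsample,
                                seed = 1) {
  wells <- names(objects)
  if (is.null(wells)) stopf("objects must be a named list keyed by well ID")
  missing_w <- setdiff(wells, layout$centers$well)
  if (length(missing_w)) stopf("unknown well ID %s", missing_w[1])
  set.seed(seed)
  n_lo <- nrow(objects[[1]]$values) / upsample
  draws <- draw_pupil_population(length(wells), cfg, n = n_lo,
                                 sigma_astig = sigma_astig,
                                 sigma_spherical = sigma_spherical)
  if (is.null(dz_offsets_um)) {
    dz_offsets_um <- stats::setNames(pmin(pmax(stats::rnorm(length(wells), 0,
                                                            sigma_dz_um), -50), 50), wells)
  }
  out <- vector("list", length(wells)); names(out) <- wells
  for (i in seq_along(wells)) {
    w <- wells[i]
    wc <- layout$centers[layout$centers$well == w, ]
    pm <- plan$per_well_map
    rows <- pm[pm$well == w & !is.na(pm$led_id), ]
    leds <- grid$positions[match(rows$led_id, grid$positions$id), ]
    k_eff <- t(vapply(seq_len(nrow(leds)), function(j) {
      led_rel <- c(leds$x_mm[j] - wc$x_mm, leds$y_mm[j] - wc$y_mm)
      if (is.null(model)) illumination_wavevector(led_rel, c(0, 0), grid, cfg)
      else trace_illumination(led_rel, c(0, 0), grid, model, cfg)
    }, numeric(2)))
    # brightfield-only rule: drop frames beyond the objective acceptance cone
    bf <- sqrt(rowSums(k_eff^2)) * cfg$lambda_um <= cfg$na_obj + 1e-9
    k_eff <- k_eff[bf, , drop = FALSE]
    pupil <- if (!is.null(pupils)) pupils[[w]] else {
      p <- ideal_pupil(cfg, n_lo)
      if (any(draws[i, ] != 0))
        p <- make_pupil(n_lo, p$df, p$cutoff,
                        values = p$values * exp(1i * zernike_phase(draws[i, ], p)))
      p
    }
    dz <- dz_offsets_um[[w]] %||% 0
    pupil_eff <- make_pupil(n_lo, pupil$df, pupil$cutoff,
                            values = pupil$values *
                              exp(1i * defocus_phase(dz, cfg, pupil)))
    ds <- forward_fpm(objects[[w]], pupil_eff, k_eff, cfg, upsample)
    ds$provenance$truth <- list(object = objects[[w]], pupil = pupil, dz_um = dz,
                                led_id = rows$led_id[bf], frame = rows$frame[bf],
                                zernike = draws[i, ])
    out[[w]] <- ds
  }
  attr(out, "dz_offsets_um") <- dz_offsets_um
  attr(out, "zernike_draws") <- draws
  out
}

#' Draw a lens population of Zernike coefficient vectors
#'
#' Astigmatism (Noll 5, 6) is drawn so the rotation-invariant magnitude has
#' the requested standard deviation; spherical (Noll 11) is drawn directly.
#'
#' @param n_lenses Number of lenses.
#' @param cfg An [optical_config()] (unused beyond validation, kept for
#'   signature symmetry).
#' @param n Pupil grid side (unused; draws are grid-free).
#' @param sigma_astig,sigma_spherical Population standard deviations (radians).
#' @return Matrix `n_lenses x 15` of Noll coefficients.
#' @export
draw_pupil_population <- function(n_lenses, cfg, n = NULL,
                                  sigma_astig = 0.88, sigma_spherical = 0.25) {
  draws <- matrix(0, n_lenses, 15)
  draws[, 5] <- stats::rnorm(n_lenses, 0, sigma_astig / sqrt(2))
  draws[, 6] <- stats::rnorm(n_lenses, 0, sigma_astig / sqrt(2))
  draws[, 11] <- stats::rnorm(n_lenses, 0, sigma_spherical)
  draws
}
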