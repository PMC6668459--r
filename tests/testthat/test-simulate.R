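# Phantoms, coherent forward model, sensor noise, whole-plate simulation

test_that("Siemens star: phase-only, correct local period, identity at zero depth", {
  star <- siemens_star(n_spoke_pairs = 40, phase_depth = 1, extent_um = 110,
                       pixel_um = 0.4)
  expect_equal(Mod(star$values), matrix(1, 275, 275))
  # local full period at r = 8 um with 40 pairs: 2 pi 8 / 40 = 1.257 um
  n <- nrow(star$values)
  r_px <- 8 / 0.4
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  c0 <- fpmtools:::fft_center(n)
  v <- Arg(star$values[cbind(round(c0 - r_px * sin(th)),
                             round(c0 + r_px * cos(th)))])
  # count phase transitions around the ring: 2 per period -> 80
  expect_equal(sum(abs(diff(v)) > 0.5), 80, tolerance = 2)
  expect_equal(2 * pi * 8 / 40, 1.257, tolerance = 1e-3)
  # zero depth -> uniform object
  flat <- siemens_star(40, phase_depth = 0, extent_um = 110, pixel_um = 0.4)
  expect_equal(flat$values, matrix(1 + 0i, 275, 275))
  expect_error(siemens_star(2), "spoke pairs")
  expect_error(siemens_star(40, extent_um = 10, pixel_um = 0.4), "128")
})

test_that("bead field: reproducible, non-overlapping, linear in phase contrast", {
  b1 <- bead_field(12, extent_um = 40, pixel_um = 0.2, seed = 5)
  b2 <- bead_field(12, extent_um = 40, pixel_um = 0.2, seed = 5)
  expect_identical(b1$values, b2$values)
  ctr <- attr(b1, "centers_um")
  expect_equal(nrow(ctr), 12)
  d <- as.matrix(stats::dist(ctr))
  expect_true(all(d[upper.tri(d)] >= 2))
  # no beads -> uniform field
  expect_equal(bead_field(0, extent_um = 40, pixel_um = 0.2)$values[1, 1], 1 + 0i)
  # mean phase scales linearly with contrast
  m1 <- mean(Arg(bead_field(12, phase_contrast = 0.4, extent_um = 40,
                            pixel_um = 0.2, seed = 5)$values))
  m2 <- mean(Arg(bead_field(12, phase_contrast = 0.8, extent_um = 40,
                            pixel_um = 0.2, seed = 5)$values))
  expect_equal(m2 / m1, 2, tolerance = 1e-9)
  # unplaceable density errors with advice
  expect_error(bead_field(500, extent_um = 20, pixel_um = 0.2, max_tries = 20),
               "density")
})

test_that("forward model: uniform object, Parseval energy, featureless darkfield", {
  cfg <- optical_config()
  n_lo <- 64; up <- 4
  pup <- ideal_pupil(cfg, n_lo)
  uniform <- fpm_object(matrix(1 + 0i, n_lo * up, n_lo * up), cfg$pixel_um / up)
  ds <- forward_fpm(uniform, pup, rbind(c(0, 0)), cfg, up)
  expect_equal(ds$frames[1, , ], matrix(1, n_lo, n_lo), tolerance = 1e-12)
  # Parseval: mean intensity of the on-axis frame equals the pupil-filtered
  # spectral energy (direct summation in both domains)
  acq <- star_acquisition(n_lo = 64)
  j0 <- which.min(rowSums(acq$k^2))
  expect_equal(unname(acq$k[j0, ]), c(0, 0))
  Ohat <- fpmtools:::fftshift2(fpmtools:::fft2(acq$obj$values))
  n_hr <- nrow(Ohat); c_hr <- fpmtools:::fft_center(n_hr)
  idx <- seq_len(n_lo) - fpmtools:::fft_center(n_lo)
  Psi <- Ohat[c_hr + idx, c_hr + idx] * acq$pupil_true$values
  spectral_mean <- sum(Mod(Psi)^2) / (up^4 * n_lo^4)
  expect_equal(mean(acq$ds$frames[j0, , ]), spectral_mean, tolerance = 1e-9)
  # darkfield of a featureless object carries essentially no energy
  k_df <- c(0.9, 0) * cfg$na_obj / cfg$lambda_um * 2    # outside the pupil
  ds_df <- forward_fpm(uniform, pup, rbind(k_df), cfg, up)
  expect_lt(sum(ds_df$frames), 1e-12 * sum(ds$frames))
  # out-of-spectrum illumination errors (upsample 2 leaves physical k that
  # the simulated spectrum cannot host)
  uniform2 <- fpm_object(matrix(1 + 0i, n_lo * 2, n_lo * 2), cfg$pixel_um / 2)
  expect_error(forward_fpm(uniform2, pup, rbind(c(1.6, 0)), cfg, 2),
               "outside the simulated spectrum")
})

test_that("forward model at k = 0 equals direct low-pass filtering of the field", {
  # oracle: direct convolution (spectral product) on a 64-px grid
  cfg <- optical_config()
  n_lo <- 32; up <- 2
  obj <- bead_field(4, extent_um = n_lo * cfg$pixel_um,
                    pixel_um = cfg$pixel_um / up, seed = 2)
  pup <- ideal_pupil(cfg, n_lo)
  ds <- forward_fpm(obj, pup, rbind(c(0, 0)), cfg, up)
  # oracle path: filter the full field, then subsample
  n_hr <- nrow(obj$values)
  H <- matrix(0, n_hr, n_hr)
  c_hr <- fpmtools:::fft_center(n_hr)
  idx <- seq_len(n_lo) - fpmtools:::fft_center(n_lo)
  H[c_hr + idx, c_hr + idx] <- pup$values
  filt <- fpmtools:::ifft2(fpmtools:::ifftshift2(
    fpmtools:::fftshift2(fpmtools:::fft2(obj$values)) * H))
  sub <- filt[seq(1, n_hr, up), seq(1, n_hr, up)]
  expect_equal(ds$frames[1, , ], Mod(sub)^2, tolerance = 1e-9)
})

test_that("sensor noise: identity case, shot-noise law, static band pattern", {
  cfg <- optical_config()
  n_lo <- 100; up <- 2
  uniform <- fpm_object(matrix(1 + 0i, n_lo * up, n_lo * up), cfg$pixel_um / up)
  pup <- ideal_pupil(cfg, n_lo)
  ds <- forward_fpm(uniform, pup, rbind(c(0, 0), c(0.05, 0), c(0, 0.05)), cfg, up)
  # all noise amplitudes zero -> identity
  clean <- add_sensor_noise(ds, photons_per_unit = Inf, read_noise_sd = 0,
                            band_pattern_amp = 0, n_repeats = 1, seed = 1)
  expect_equal(clean[[1]]$repeats[1, , ], ds$frames[1, , ])
  # shot-noise law: pixel variance ~ mean / photons_per_unit at 1e4 samples
  noisy <- add_sensor_noise(ds, photons_per_unit = 2000, read_noise_sd = 0,
                            band_pattern_amp = 0, n_repeats = 1, seed = 7)
  x <- noisy[[1]]$repeats[1, , ] / 2000
  expect_equal(stats::var(as.numeric(x)), mean(x) / 2000, tolerance = 0.05)
  # identical seeds -> bit-identical output
  noisy2 <- add_sensor_noise(ds, photons_per_unit = 2000, read_noise_sd = 0,
                             band_pattern_amp = 0, n_repeats = 1, seed = 7)
  expect_identical(noisy[[1]]$repeats, noisy2[[1]]$repeats)
  # the band pattern is static: identical across repeats and illuminations
  banded <- add_sensor_noise(ds, photons_per_unit = Inf, read_noise_sd = 0,
                             band_pattern_amp = 10, n_repeats = 2, seed = 7)
  expect_equal(banded[[1]]$repeats[1, , ], banded[[1]]$repeats[2, , ])
  expect_equal(banded[[1]]$repeats[1, , ] - ds$frames[1, , ],
               banded[[2]]$repeats[1, , ] - ds$frames[2, , ])
})

test_that("band pattern estimated from different repeats is identical, and rows are banded", {
  cfg <- optical_config()
  n_lo <- 64; up <- 2
  uniform <- fpm_object(matrix(1 + 0i, n_lo * up, n_lo * up), cfg$pixel_um / up)
  pup <- ideal_pupil(cfg, n_lo)
  ds <- forward_fpm(uniform, pup, rbind(c(0, 0), c(0.05, 0), c(0, 0.05)), cfg, up)
  banded <- add_sensor_noise(ds, photons_per_unit = 1000, read_noise_sd = 0,
                             band_pattern_amp = 20, n_repeats = 2, seed = 3)
  band <- attr(banded, "band_pattern")
  # horizontal bands: constant along rows
  expect_equal(band, outer(band[, 1], rep(1, n_lo)))
  expect_equal(max(abs(band)), 20)
})

test_that("whole-plate simulation reduces to forward_fpm and keeps the plan bookkeeping", {
  geo <- test_geometry()
  cfg <- geo$cfg
  n_lo <- 32; up <- 2
  plan <- schedule_parallel_illumination(geo$grid, geo$layout, cfg, m = 8)
  obj <- bead_field(3, extent_um = n_lo * cfg$pixel_um, pixel_um = cfg$pixel_um / up,
                    seed = 4)
  sims <- simulate_well_plate(list(D6 = obj), plan, geo$grid, geo$layout, cfg,
                              model = NULL, sigma_astig = 0, sigma_spherical = 0,
                              dz_offsets_um = c(D6 = 0), upsample = up, seed = 9)
  ds <- sims$D6
  # frame -> LED mapping matches the plan exactly
  pm <- plan$per_well_map
  expected_leds <- pm$led_id[pm$well == "D6" & !is.na(pm$led_id)]
  expect_true(all(ds$provenance$truth$led_id %in% expected_leds))
  # zero aberration, no liquid, dz = 0: identical to forward_fpm directly
  wc <- geo$layout$centers[geo$layout$centers$well == "D6", ]
  leds <- geo$grid$positions[match(ds$provenance$truth$led_id,
                                   geo$grid$positions$id), ]
  k <- t(vapply(seq_len(nrow(leds)), function(j)
    illumination_wavevector(c(leds$x_mm[j] - wc$x_mm, leds$y_mm[j] - wc$y_mm),
                            c(0, 0), geo$grid, cfg), numeric(2)))
  direct <- forward_fpm(obj, ideal_pupil(cfg, n_lo), k, cfg, up)
  expect_equal(ds$frames, direct$frames, tolerance = 1e-12)
  # brightfield-only rule: all retained frames are inside the acceptance cone
  expect_true(all(sqrt(rowSums(ds$k_eff^2)) * cfg$lambda_um <= cfg$na_obj + 1e-9))
})

test_that("lens population draws reproduce the configured aberration statistics", {
  set.seed(11)
  draws <- draw_pupil_population(96, optical_config())
  astig <- sqrt(draws[, 5]^2 + draws[, 6]^2)
  # rotation-invariant astigmatism magnitude RMS ~ 0.88, spherical sd ~ 0.25
  expect_equal(sqrt(mean(astig^2)), 0.88, tolerance = 0.25)
  expect_equal(stats::sd(draws[, 11]), 0.25, tolerance = 0.25)
  expect_true(all(draws[, c(1:4, 7:10, 12:15)] == 0))
})

test_that("simulation randomness is fully seeded: identical seeds, identical datasets", {
  geo <- test_geometry()
  plan <- schedule_parallel_illumination(geo$grid, geo$layout, geo$cfg, m = 8)
  # 96-px tile so the pupil disk is resolved well enough for the Zernike draws
  obj <- cell_phantom(2, extent_um = 38.4, pixel_um = 0.2, seed = 1)
  s1 <- simulate_well_plate(list(A1 = obj), plan, geo$grid, geo$layout, geo$cfg,
                            upsample = 2, seed = 21)
  s2 <- simulate_well_plate(list(A1 = obj), plan, geo$grid, geo$layout, geo$cfg,
                            upsample = 2, seed = 21)
  expect_identical(s1$A1$frames, s2$A1$frames)
  expect_identical(attr(s1, "dz_offsets_um"), attr(s2, "dz_offsets_um"))
})
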