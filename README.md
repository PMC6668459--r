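# fpmtools

Parallel Fourier ptychographic microscopy (FPM) for 96-well plates, as a
desk-scale R toolkit.

High-throughput plate imagers that put one miniature microscope under every
well face plate warp (wells drift out of the ±5 µm depth of focus),
lens-to-lens aberrations of plastic-molded objectives, and a liquid meniscus
that bends the illumination. FPM solves all three computationally: a shared
LED array illuminates the plate from a sequence of angles, each angle shifts
the sample spectrum across the objective's NA-bounded passband, and phase
retrieval fuses the low-resolution intensity frames into a high-resolution
complex (amplitude + phase) image while *embedded pupil function recovery*
(EPRY) estimates each objective's aberrations in situ. Defocus is just the
quadratic aberration term, so refocusing becomes a search over the pupil's
angular-spectrum kernel

φ(f) = 2π·δz·(√(1/λ² − |f|²) − 1/λ),

extending the effective depth of focus from ±5 µm to tens of micrometers.

The package implements the full computational pipeline — and a coherent
forward simulator with a sensor-noise model, so everything runs and is
tested without an instrument:

| area | functions |
|---|---|
| illumination geometry & parallel scheduling | `build_led_grid()`, `acceptance_radius()`, `schedule_parallel_illumination()` |
| meniscus ray calibration | `meniscus_model()`, `refract()`, `trace_illumination()`, `angle_drift_map()` |
| synthetic data | `siemens_star()`, `bead_field()`, `cell_phantom()`, `forward_fpm()`, `add_sensor_noise()`, `simulate_well_plate()` |
| reconstruction | `epry_reconstruct()`, `reconstruction_residual()`, `refocus_search()` |
| wavefront analysis | `zernike_basis()`, `fit_zernike()`, `defocus_phase()`, `rotation_invariant_modes()`, `rms_wavefront_diff()` |
| denoising / z-stacks | `average_frames()`, `remove_static_pattern()`, `denoise_dataset()`, `select_sharpest_plane()` |
| mosaicking | `partition_fov()`, `align_tile_gauge()`, `feather_blend()` |
| metrics | `star_resolution()`, `fwhm_resolution()`, `theoretical_optics()` |
| archives & CLI | `write_archive()`, `read_archive()`, `validate_archive()`, `cli_simulate()`, `cli_reconstruct()`, `fpm_cli()` |

A thin command-line front end ships in `inst/cli/fpmtools` with subcommands
`simulate`, `denoise`, `calibrate`, `reconstruct`, `refocus`, `stitch`,
`analyze`, `validate`.

## Worked example

Simulate a phase-only Siemens star tile under the default geometry
(533 nm, NA 0.23, LED array at 33 mm with 3 mm pitch), reconstruct it with
EPRY, and read out the resolution:

```r
library(fpmtools)

cfg    <- optical_config()                  # 533 nm, NA 0.23, 4x, 0.4 um px
layout <- well_layout()                     # 96 wells, 9 mm pitch
grid   <- build_led_grid(layout)
grid
#> <led_grid> 1120 LEDs, pitch 3 mm, h = 33 mm, segment 18 mm

# brightfield subset of one well's 7 x 7 LED segment
offs <- as.matrix(expand.grid(x = seq(-9, 9, 3), y = seq(-9, 9, 3)))
k <- t(apply(offs, 1, function(o)
  illumination_wavevector(c(o[1], o[2]), c(0, 0), grid, cfg)))
k <- k[sqrt(rowSums(k^2)) * cfg$lambda_um <= cfg$na_obj, ]   # 21 frames

# 25.6 um tile (64 raw px), 16-spoke star, defocused by +30 um
star  <- siemens_star(16, phase_depth = 1, extent_um = 25.6, pixel_um = 0.1)
pupil <- ideal_pupil(cfg, 64)
p30   <- make_pupil(64, pupil$df, pupil$cutoff,
                    values = pupil$values * exp(1i * defocus_phase(30, cfg, pupil)))
ds    <- forward_fpm(star, p30, k, cfg, upsample = 4)

# blind two-stage refocusing + EPRY
rf <- refocus_search(ds, z_range_um = 100, coarse_step_um = 5,
                     rc = recon_config(n_iters = 30, upsample = 4))
rf$delta_z_um
#> [1] 30
star_resolution(Arg(rf$result$object$values), 16, pixel_um = 0.1)
#> <resolution_report> 0.628 um (siemens_star, threshold 0.3)
```

The search recovers the injected 30 µm defocus exactly (coarse step 5 µm)
and the restored phase resolves the star at 0.63 µm — against a native
single-LED read-out of several micrometers, and well inside the synthetic
aperture's λ/(2·(NA_obj + NA_illum)) ≈ 0.62 µm coherent limit. Skipping the
defocus correction on the same data (pupil fixed to the ideal one) degrades
the read-out to 2.3 µm:

```r
plain <- epry_reconstruct(ds, rc = recon_config(n_iters = 30, upsample = 4,
                                                pupil_recovery = FALSE))
star_resolution(Arg(plain$object$values), 16, pixel_um = 0.1)$resolution_um
#> [1] 2.33656
```

The design's closed-form optics are one call away:

```r
theoretical_optics(cfg, grid)
#>   lateral_resolution_um axial_resolution_um coherent_area_width_um
#> 1              1.413609            10.07561                140.712
```

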