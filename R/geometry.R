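#' Optical configuration of one mini-microscope
#'
#' Bundles the fixed optical constants shared by every computation in the
#' pipeline: illumination wavelength, objective numerical aperture,
#' magnification, object-side pixel pitch, per-well field of view and the
#' mechanical distances of the finite-conjugate design. Lengths at this
#' surface are in the units conventional for each quantity (nm for the
#' wavelength, mm for mechanical distances, um for pixels); internal
#' computations use um.
#'
#' @param wavelength_nm Illumination wavelength in nm (default 533).
#' @param na_obj Objective numerical aperture (default 0.23).
#' @param magnification Lateral magnification (default 4).
#' @param pixel_um Object-side pixel pitch of the raw frames in um (default 0.4).
#' @param fov_mm Length-2 vector, per-well field of view in mm (default
#'   `c(1.1, 0.85)`).
#' @param object_to_sensor_mm Fixed object-to-sensor distance in mm (default 48).
#' @param working_distance_mm Objective working distance in mm (default 4).
#' @param tile_um Side of the square reconstruction tile in um (default 110).
#' @param upsample Default spectral upsampling factor of reconstructions
#'   (default 4, i.e. 0.1 um reconstruction pixel).
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength_nm = 533, na_obj = 0.23, magnification = 4,
                           pixel_um = 0.4, fov_mm = c(1.1, 0.85),
                           object_to_sensor_mm = 48, working_distance_mm = 4,
                           tile_um = 110, upsample = 4) {
  if (na_obj <= 0 || na_obj >= 1) stopf("na_obj must lie in (0, 1), got %g", na_obj)
  if (any(fov_mm <= 0)) stopf("fov_mm must be positive")
  if (wavelength_nm <= 0 || pixel_um <= 0) stopf("wavelength and pixel must be positive")
  lambda_um <- wavelength_nm / 1000
  # Nyquist guard for the chosen upsampling: the reconstruction pixel must
  # resolve the widest synthetic passband the design can produce (2 NA_obj).
  if (pixel_um / upsample > lambda_um / (4 * na_obj)) {
    stopf("pixel %g um / upsample %d undersamples the synthetic passband (needs <= %.3g um)",
          pixel_um, upsample, lambda_um / (4 * na_obj))
  }
  structure(list(
    wavelength_nm = wavelength_nm, lambda_um = lambda_um, na_obj = na_obj,
    magnification = magnification, pixel_um = pixel_um, fov_mm = fov_mm,
    object_to_sensor_mm = object_to_sensor_mm,
    working_distance_mm = working_distance_mm,
    tile_um = tile_um, upsample = upsample
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> lambda %g nm, NA %.2f, %gx, pixel %g um, FOV %g x %g mm\n",
              x$wavelength_nm, x$na_obj, x$magnification, x$pixel_um,
              x$fov_mm[1], x$fov_mm[2]))
  invisible(x)
}

#' Multi-well plate layout
#'
#' Rectangular lattice of well centers. The default is the standard 96-well
#' plate: 8 rows by 12 columns at 9 mm pitch. Coordinates place the origin at
#' the plate center with x along the 12-well axis.
#'
#' @param n_rows,n_cols Number of well rows / columns (defaults 8 and 12).
#' @param pitch_mm Well-to-well separation in mm (default 9).
#' @param well_radius_mm Well radius in mm (default 3.4).
#' @return An object of class `well_layout` with a `centers` data frame
#'   (`well`, `row`, `col`, `x_mm`, `y_mm`).
#' @export
well_layout <- function(n_rows = 8, n_cols = 12, pitch_mm = 9, well_radius_mm = 3.4) {
  if (n_rows < 1 || n_cols < 1) stopf("layout needs at least one well")
  if (pitch_mm <= 0) stopf("well pitch must be positive")
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  centers <- data.frame(
    well = paste0(LETTERS[g$row], g$col),
    row = g$row, col = g$col,
    x_mm = (g$col - (n_cols + 1) / 2) * pitch_mm,
    y_mm = ((n_rows + 1) / 2 - g$row) * pitch_mm,
    stringsAsFactors = FALSE
  )
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
                 well_radius_mm = well_radius_mm, centers = centers),
            class = "well_layout")
}

#' @export
print.well_layout <- function(x, ...) {
  cat(sprintf("<well_layout> %d x %d wells at %g mm pitch\n",
              x$n_rows, x$n_cols, x$pitch_mm))
  invisible(x)
}

#' Build the shared LED illumination array
#'
#' Constructs the LED lattice as the union, over all wells, of a square
#' segment of side `segment_width_mm` centered on each well, on a common grid
#' of pitch `led_pitch_mm`, deduplicated. For the default 96-well geometry
#' (9 mm well pitch, 3 mm LED pitch, 18 mm segments) this yields the 40 x 28 =
#' 1120-element array; segment sharing between neighboring mini-microscopes is
#' what reduces the count from 96 x 49.
#'
#' The lattice is anchored at the corner well center, so every LED coordinate
#' is an integer multiple of the LED pitch relative to that origin.
#'
#' @param layout A [well_layout()].
#' @param led_pitch_mm LED-to-LED separation in mm (default 3).
#' @param segment_width_mm Side of the per-well LED segment in mm (default 18).
#' @param height_mm Vertical clearance of the LED plane above the sample in mm
#'   (default 33).
#' @param emitter_um LED emitter size in um (default 250); sets the coherent
#'   area width via [theoretical_optics()].
#' @return An object of class `led_grid` with a `positions` data frame
#'   (`id`, `ix`, `iy`, `x_mm`, `y_mm`), where `ix`, `iy` index the lattice.
#' @export
build_led_grid <- function(layout, led_pitch_mm = 3, segment_width_mm = 18,
                           height_mm = 33, emitter_um = 250) {
  if (segment_width_mm < layout$pitch_mm)
    stopf("segment width (%g mm) must be >= well pitch (%g mm)",
          segment_width_mm, layout$pitch_mm)
  if (height_mm <= 0) stopf("LED height must be positive")
  half <- segment_width_mm / 2
  chk <- c(segment_width = segment_width_mm, well_pitch = layout$pitch_mm)
  bad <- abs(chk / led_pitch_mm - round(chk / led_pitch_mm)) > 1e-9
  if (any(bad))
    stopf("led_pitch (%g mm) must divide %s (%g mm)", led_pitch_mm,
          names(chk)[bad][1], chk[bad][1])
  # lattice indices relative to the corner well (row n_rows, col 1 -> most
  # negative x, most negative y)
  x0 <- min(layout$centers$x_mm); y0 <- min(layout$centers$y_mm)
  k <- round(half / led_pitch_mm)
  off <- seq(-k, k)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  ix <- integer(0); iy <- integer(0)
  cw <- layout$centers
  for (w in seq_len(nrow(cw))) {
    wx <- round((cw$x_mm[w] - x0) / led_pitch_mm)
    wy <- round((cw$y_mm[w] - y0) / led_pitch_mm)
    g <- expand.grid(ix = wx + off, iy = wy + off)
    key <- paste(g$ix, g$iy)
    new <- !vapply(key, exists, logical(1), envir = keys)
    for (kk in key[new]) assign(kk, TRUE, envir = keys)
    ix <- c(ix, g$ix[new]); iy <- c(iy, g$iy[new])
  }
  ord <- order(iy, ix)
  positions <- data.frame(id = seq_along(ix), ix = ix[ord], iy = iy[ord],
                          x_mm = x0 + ix[ord] * led_pitch_mm,
                          y_mm = y0 + iy[ord] * led_pitch_mm)
  structure(list(positions = positions, led_pitch_mm = led_pitch_mm,
                 segment_width_mm = segment_width_mm, height_mm = height_mm,
                 emitter_um = emitter_um, origin_mm = c(x0, y0)),
            class = "led_grid")
}

#' @export
print.led_grid <- function(x, ...) {
  cat(sprintf("<led_grid> %d LEDs, pitch %g mm, h = %g mm, segment %g mm\n",
              nrow(x$positions), x$led_pitch_mm, x$height_mm, x$segment_width_mm))
  invisible(x)
}

#' Closed-form LED count for a rectangular layout
#'
#' `((n_cols - 1) * well_pitch + segment_width) / led_pitch + 1` columns times
#' the analogous row count; cross-checked against brute-force enumeration in
#' the test suite.
#'
#' @inheritParams build_led_grid
#' @return Integer LED count.
#' @export
led_count_closed_form <- function(layout, led_pitch_mm = 3, segment_width_mm = 18) {
  nc <- ((layout$n_cols - 1) * layout$pitch_mm + segment_width_mm) / led_pitch_mm + 1
  nr <- ((layout$n_rows - 1) * layout$pitch_mm + segment_width_mm) / led_pitch_mm + 1
  as.integer(round(nc) * round(nr))
}

#' Fraction of an LED segment shared with neighboring mini-microscopes
#'
#' With per-well LED segments of side `segment_width_mm` on a well lattice of
#' pitch `well_pitch_mm`, only a `(well_pitch/segment_width)^2` fraction of
#' each segment is exclusive to its well; the rest is reused by adjacent
#' units. The default geometry (9 mm pitch, 18 mm segments) shares 75%.
#'
#' @param well_pitch_mm Well pitch in mm.
#' @param segment_width_mm Segment side in mm.
#' @return Shared-area fraction in `[0, 1)`.
#' @export
segment_reuse_fraction <- function(well_pitch_mm, segment_width_mm) {
  if (well_pitch_mm <= 0) stopf("well pitch must be positive")
  if (segment_width_mm < well_pitch_mm)
    stopf("invalid geometry: segment width (%g mm) < well pitch (%g mm)",
          segment_width_mm, well_pitch_mm)
  1 - (well_pitch_mm / segment_width_mm)^2
}

#' Free-space illumination spatial frequency
#'
#' Direction cosines of the LED-to-field-point ray divided by the wavelength:
#' the spatial-frequency shift a tilted plane wave imparts to the object
#' spectrum, ignoring any liquid above the sample (see [trace_illumination()]
#' for the meniscus-corrected version).
#'
#' @param led_xy_mm LED lateral position, length-2 in mm.
#' @param field_xy_mm Field point lateral position, length-2 in mm.
#' @param grid A [build_led_grid()] (supplies the LED height).
#' @param cfg An [optical_config()].
#' @return Length-2 numeric `(fx, fy)` in 1/um; `|f| * lambda < 1` always.
#' @export
illumination_wavevector <- function(led_xy_mm, field_xy_mm, grid, cfg) {
  h <- grid$height_mm
  if (h <= 0) stopf("field point must lie below the LED plane (h > 0)")
  d <- c(field_xy_mm[1] - led_xy_mm[1], field_xy_mm[2] - led_xy_mm[2], -h)
  d <- d / sqrt(sum(d^2))
  d[1:2] / cfg$lambda_um
}

#' LED-plane radius of an acceptance cone
#'
#' Radius, on the LED plane, of the cone of directions reaching a well center
#' within illumination NA `na_illum_max`: `h * tan(asin(na))`. Used to verify
#' that at most one lit LED falls inside each objective's acceptance cone in a
#' parallel illumination pattern.
#'
#' @param grid A [build_led_grid()].
#' @param cfg An [optical_config()].
#' @param na_illum_max Maximum illumination NA (default: the objective NA,
#'   i.e. the brightfield cone).
#' @return Radius in mm.
#' @export
acceptance_radius <- function(grid, cfg, na_illum_max = cfg$na_obj) {
  if (na_illum_max >= 1 || na_illum_max < 0) stopf("na_illum_max must lie in [0, 1)")
  grid$height_mm * tan(asin(na_illum_max))
}

#' Schedule parallel multi-well illumination
#'
#' Builds the batch of illumination patterns that lights the whole plate while
#' guaranteeing that each well sees at most one source inside its acceptance
#' cone per frame. Patterns are the `m^2` lattice-shift classes of the LED
#' grid: pattern `(a, b)` lights every LED whose lattice indices are congruent
#' to `(a, b) mod m`, so lit sources are `m` LED pitches apart on each axis.
#'
#' Each (frame, well) is assigned the lit LED inside that well's segment, or
#' none: with `m` larger than the segment width in pitches there is at most
#' one. Frames with an assignment are the ones used for reconstruction; for
#' the default `m = 8` each well is assigned in 49 of the 64 frames (its 7 x 7
#' segment) and idles in the remaining padding frames.
#'
#' @param grid A [build_led_grid()].
#' @param layout The [well_layout()] the grid was built for.
#' @param cfg An [optical_config()].
#' @param m Source-to-source separation in LED pitches (default 8).
#' @param na_illum_max Acceptance-cone NA used for validation (default
#'   `cfg$na_obj`, the brightfield cone).
#' @return An `illumination_plan`: `patterns` (list of LED id vectors),
#'   `per_well_map` (data frame `frame`, `well`, `led_id` with `NA` for idle
#'   frames), and `m`.
#' @export
schedule_parallel_illumination <- function(grid, layout, cfg, m = 8,
                                           na_illum_max = cfg$na_obj) {
  r_acc <- acceptance_radius(grid, cfg, na_illum_max)
  if (m * grid$led_pitch_mm <= 2 * r_acc)
    stopf("m = %d gives source separation %g mm <= twice the acceptance radius (%g mm)",
          m, m * grid$led_pitch_mm, 2 * r_acc)
  pos <- grid$positions
  half_seg <- grid$segment_width_mm / 2 + 1e-9
  classes <- expand.grid(a = 0:(m - 1), b = 0:(m - 1))
  patterns <- list()
  frames_ab <- list()
  for (i in seq_len(nrow(classes))) {
    sel <- pos$id[pos$ix %% m == classes$a[i] & pos$iy %% m == classes$b[i]]
    if (length(sel) == 0) next           # shift class misses the finite array
    patterns[[length(patterns) + 1]] <- sel
    frames_ab[[length(frames_ab) + 1]] <- c(classes$a[i], classes$b[i])
  }
  # per-well assignment + exhaustive re-verification of the cone invariant
  cw <- layout$centers
  map <- vector("list", length(patterns))
  for (f in seq_along(patterns)) {
    lit <- pos[match(patterns[[f]], pos$id), ]
    led_id <- rep(NA_integer_, nrow(cw))
    for (w in seq_len(nrow(cw))) {
      dx <- lit$x_mm - cw$x_mm[w]; dy <- lit$y_mm - cw$y_mm[w]
      in_cone <- which(sqrt(dx^2 + dy^2) <= r_acc + 1e-9)
      if (length(in_cone) > 1)
        stopf("constraint violation: frame %d, well %s sees LEDs %d and %d inside its acceptance cone",
              f, cw$well[w], lit$id[in_cone[1]], lit$id[in_cone[2]])
      in_seg <- which(abs(dx) <= half_seg & abs(dy) <= half_seg)
      if (length(in_seg) >= 1) {
        # nearest-to-center tie-break (only reachable for small m)
        led_id[w] <- lit$id[in_seg[which.min(dx[in_seg]^2 + dy[in_seg]^2)]]
      }
    }
    map[[f]] <- data.frame(frame = f, well = cw$well, led_id = led_id,
                           stringsAsFactors = FALSE)
  }
  structure(list(patterns = patterns, per_well_map = do.call(rbind, map),
                 m = m, na_illum_max = na_illum_max),
            class = "illumination_plan")
}

#' @export
print.illumination_plan <- function(x, ...) {
  used <- sum(!is.na(x$per_well_map$led_id)) / length(unique(x$per_well_map$well))
  cat(sprintf("<illumination_plan> m = %d: %d patterns, %g assigned frames per well\n",
              x$m, length(x$patterns), used))
  invisible(x)
}

#' Export an illumination plan as a frame/LED table
#'
#' @param plan An [schedule_parallel_illumination()] result.
#' @param grid The matching [build_led_grid()].
#' @return Data frame `frame`, `led_id`, `x_mm`, `y_mm`, one row per lit LED
#'   per frame.
#' @export
plan_table <- function(plan, grid) {
  rows <- lapply(seq_along(plan$patterns), function(f) {
    p <- grid$positions[match(plan$patterns[[f]], grid$positions$id), ]
    data.frame(frame = f, led_id = p$id, x_mm = p$x_mm, y_mm = p$y_mm)
  })
  do.call(rbind, rows)
}
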