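#' Liquid column and meniscus model of a well
#'
#' Describes the refractive layers between the LED array and the sample: the
#' air gap, the liquid medium (culture buffer, ~3 mm for a 100-200 uL fill),
#' and optionally the plate bottom. The air-liquid interface is either flat or
#' a spherical cap pinned at the well wall; a concave-up meniscus (negative
#' cap radius) acts as a weak concave lens that magnifies the parallax of the
#' LED positions across the field of view.
#'
#' @param liquid_index Refractive index of the liquid (default 1.33).
#' @param liquid_depth_mm Liquid depth at the well center in mm (default 3).
#' @param plate_bottom_index Refractive index of the plate bottom (default
#'   1.53, cyclic olefin copolymer).
#' @param plate_bottom_thickness_um Plate bottom thickness in um (default 0 =
#'   slab refraction off; the sample is modeled at the top of the bottom).
#' @param well_radius_mm Well radius in mm (default 3.4).
#' @param surface_shape `"flat"` or `"spherical_cap"`.
#' @param cap_radius_mm Signed radius of curvature of the cap in mm; negative
#'   means concave-up (liquid lower at the center). `|cap_radius_mm|` must be
#'   at least the well radius.
#' @return An object of class `meniscus_model`.
#' @export
meniscus_model <- function(liquid_index = 1.33, liquid_depth_mm = 3,
                           plate_bottom_index = 1.53,
                           plate_bottom_thickness_um = 0,
                           well_radius_mm = 3.4,
                           surface_shape = c("flat", "spherical_cap"),
                           cap_radius_mm = -10) {
  surface_shape <- match.arg(surface_shape)
  if (liquid_index < 1 || plate_bottom_index < 1) stopf("refractive indices must be >= 1")
  if (liquid_depth_mm <= 0) stopf("liquid depth must be positive")
  if (surface_shape == "spherical_cap" && abs(cap_radius_mm) < well_radius_mm)
    stopf("|cap_radius_mm| (%g) must be >= well_radius_mm (%g)",
          abs(cap_radius_mm), well_radius_mm)
  structure(list(liquid_index = liquid_index, liquid_depth_mm = liquid_depth_mm,
                 plate_bottom_index = plate_bottom_index,
                 plate_bottom_thickness_um = plate_bottom_thickness_um,
                 well_radius_mm = well_radius_mm, surface_shape = surface_shape,
                 cap_radius_mm = cap_radius_mm),
            class = "meniscus_model")
}

#' @export
print.meniscus_model <- function(x, ...) {
  cat(sprintf("<meniscus_model> n = %g, depth %g mm, surface %s%s\n",
              x$liquid_index, x$liquid_depth_mm, x$surface_shape,
              if (x$surface_shape == "spherical_cap")
                sprintf(" (R = %g mm)", x$cap_radius_mm) else ""))
  invisible(x)
}

# liquid surface height above the sample plane at lateral radius r (mm),
# and its radial slope dz/dr
surface_height <- function(model, r) {
  if (model$surface_shape == "flat") return(list(z = rep(model$liquid_depth_mm, length(r)),
                                                 slope = rep(0, length(r))))
  Rc <- abs(model$cap_radius_mm)
  r <- pmin(r, Rc - 1e-9)
  sag <- Rc - sqrt(Rc^2 - r^2)
  if (model$cap_radius_mm < 0) {       # concave-up: lowest at the center
    list(z = model$liquid_depth_mm + sag, slope = r / sqrt(Rc^2 - r^2))
  } else {
    list(z = model$liquid_depth_mm - sag, slope = -r / sqrt(Rc^2 - r^2))
  }
}

#' Refract a ray at an interface (Snell's law, vector form)
#'
#' @param direction Unit propagation vector of the incoming ray.
#' @param surface_normal Unit normal pointing into the incidence medium
#'   (i.e. `sum(direction * surface_normal) < 0`).
#' @param n1,n2 Refractive indices of the incidence / transmission media.
#' @return Unit direction of the refracted ray. Errors on total internal
#'   reflection rather than clamping.
#' @export
refract <- function(direction, surface_normal, n1, n2) {
  d <- direction / sqrt(sum(direction^2))
  nn <- surface_normal / sqrt(sum(surface_normal^2))
  ci <- -sum(d * nn)
  if (ci <= 0) stopf("ray does not travel into the surface (direction . normal must be < 0)")
  eta <- n1 / n2
  st2 <- eta^2 * (1 - ci^2)
  if (st2 > 1) stopf("total internal reflection: n1 sin(theta1) = %.4f > n2 = %.4f",
                     n1 * sqrt(1 - ci^2), n2)
  ct <- sqrt(1 - st2)
  t <- eta * d + (eta * ci - ct) * nn
  t / sqrt(sum(t^2))
}

# Trace LED -> meniscus surface -> (optional plate slab) -> sample plane for a
# candidate surface point s = (x, y); returns landing point and in-liquid ray.
.trace_forward <- function(s, led_xyz, model) {
  sh <- surface_height(model, sqrt(sum(s^2)))
  S <- c(s, sh$z)
  d1 <- S - led_xyz
  d1 <- d1 / sqrt(sum(d1^2))
  # surface normal pointing up into the air side
  r <- sqrt(sum(s^2))
  if (r < 1e-12 || model$surface_shape == "flat") {
    nrm <- c(0, 0, 1)
  } else {
    nrm <- c(-sh$slope * s[1] / r, -sh$slope * s[2] / r, 1)
    nrm <- nrm / sqrt(sum(nrm^2))
  }
  d2 <- refract(d1, nrm, 1, model$liquid_index)
  t_mm <- model$plate_bottom_thickness_um / 1000
  if (t_mm > 0) {
    # through the liquid to the plate top, then through the slab to the sample
    P <- S + d2 * ((t_mm - S[3]) / d2[3])
    d3 <- refract(d2, c(0, 0, 1), model$liquid_index, model$plate_bottom_index)
    land <- P + d3 * ((0 - P[3]) / d3[3])
    list(land = land[1:2], dir = d3, n_last = model$plate_bottom_index)
  } else {
    land <- S + d2 * ((0 - S[3]) / d2[3])
    list(land = land[1:2], dir = d2, n_last = model$liquid_index)
  }
}

#' Illumination spatial frequency through the liquid column
#'
#' Solves, by bounded 2-D root finding on the meniscus-surface intersection
#' point, the ray that leaves the LED, refracts at the (possibly curved)
#' air-liquid interface, and lands on the requested field point. Returns the
#' effective spatial-frequency shift at the sample: the lateral direction
#' cosines of the final ray times `n / lambda_vacuum`, which is exactly the
#' grating shift the reconstruction must use. Tangential frequency is
#' continuous across flat interfaces, so with a flat surface the result
#' reduces to the flat-slab Snell formula, and with all indices set to 1 it
#' equals [illumination_wavevector()].
#'
#' @param led_xy_mm LED lateral position in mm (well-centered coordinates).
#' @param field_xy_mm Field point lateral position in mm, inside the well.
#' @param grid A [build_led_grid()] (LED height).
#' @param model A [meniscus_model()].
#' @param cfg An [optical_config()].
#' @param tol_mm Root-finder tolerance on the landing error (default 1e-6 mm).
#' @param max_iter Iteration cap (default 100).
#' @return Length-2 `(fx, fy)` in 1/um.
#' @export
trace_illumination <- function(led_xy_mm, field_xy_mm, grid, model, cfg,
                               tol_mm = 1e-6, max_iter = 100) {
  if (sqrt(sum(field_xy_mm^2)) > model$well_radius_mm)
    stopf("field point lies outside the well footprint")
  ray <- .trace_ray(led_xy_mm, field_xy_mm, grid, model, tol_mm, max_iter)
  ray$n_last * ray$dir[1:2] / cfg$lambda_um
}

# shared solver: damped Newton on the surface intersection point with a
# finite-difference Jacobian, bounded to the well footprint
.trace_ray <- function(led_xy_mm, field_xy_mm, grid, model, tol_mm = 1e-6,
                       max_iter = 100) {
  led_xyz <- c(led_xy_mm[1], led_xy_mm[2], grid$height_mm)
  # initial guess: straight-line intersection with the nominal surface plane
  z0 <- model$liquid_depth_mm
  tfrac <- (grid$height_mm - z0) / grid$height_mm
  s <- led_xyz[1:2] + tfrac * (field_xy_mm - led_xyz[1:2])
  bound <- model$well_radius_mm * 2
  h <- 1e-6
  for (it in seq_len(max_iter)) {
    f0 <- .trace_forward(s, led_xyz, model)$land - field_xy_mm
    if (sqrt(sum(f0^2)) < tol_mm)
      return(.trace_forward(s, led_xyz, model))
    fx <- .trace_forward(s + c(h, 0), led_xyz, model)$land - field_xy_mm
    fy <- .trace_forward(s + c(0, h), led_xyz, model)$land - field_xy_mm
    J <- cbind((fx - f0) / h, (fy - f0) / h)
    step <- tryCatch(-solve(J, f0), error = function(e) -f0)
    # damp and bound the step
    sl <- sqrt(sum(step^2))
    if (sl > 1) step <- step / sl
    s_new <- s + step
    if (sqrt(sum(s_new^2)) > bound) s_new <- s_new * bound / sqrt(sum(s_new^2))
    s <- s_new
  }
  res <- sqrt(sum((.trace_forward(s, led_xyz, model)$land - field_xy_mm)^2))
  stopf("meniscus ray tracing did not converge after %d iterations (residual %.3g mm)",
        max_iter, res)
}

#' Incidence-angle map across field positions (parallax)
#'
#' Traces one LED to each of several field points and reports the incidence
#' angle of the in-liquid ray at the sample, in degrees from the vertical.
#' The spread `max - min` quantifies the parallax effect: how much the
#' apparent source direction drifts across the field of view, amplified by a
#' concave meniscus.
#'
#' @param led_xy_mm LED lateral position in mm.
#' @param field_points_mm Matrix (n x 2) of field points in mm.
#' @inheritParams trace_illumination
#' @return Numeric vector of incidence angles in degrees, one per field point,
#'   with attribute `drift_deg = max - min`.
#' @export
angle_drift_map <- function(led_xy_mm, field_points_mm, grid, model, cfg,
                            tol_mm = 1e-6, max_iter = 100) {
  field_points_mm <- rbind(field_points_mm)
  if (nrow(field_points_mm) < 1) stopf("need at least one field point")
  ang <- vapply(seq_len(nrow(field_points_mm)), function(i) {
    ray <- .trace_ray(led_xy_mm, field_points_mm[i, ], grid, model, tol_mm, max_iter)
    acos(-ray$dir[3]) * 180 / pi
  }, numeric(1))
  attr(ang, "drift_deg") <- max(ang) - min(ang)
  ang
}

#' Relative tilt tolerance across a span of wells
#'
#' The finite-conjugate design tolerates only `delta_mm` of object-to-sensor
#' distance error; across `span_wells` wells at `well_pitch_mm` this is a
#' plate tilt of `atan(delta / (pitch * span))`. The default instrument
#' numbers (2 mm over 11 well pitches of 9 mm) give about 1 degree.
#'
#' @param delta_mm Allowed axial deviation in mm.
#' @param span_wells Number of well pitches spanned.
#' @param well_pitch_mm Well pitch in mm.
#' @return Tilt angle in degrees.
#' @export
spot_tolerance_tilt <- function(delta_mm, span_wells, well_pitch_mm = 9) {
  if (delta_mm < 0 || span_wells <= 0 || well_pitch_mm <= 0)
    stopf("inputs must be positive")
  atan(delta_mm / (well_pitch_mm * span_wells)) * 180 / pi
}
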