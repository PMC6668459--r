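#' Partition a field of view into overlapping reconstruction tiles
#'
#' The FOV is divided on a regular lattice with center-to-center spacing
#' `tile_um`; each tile box is then extended symmetrically so neighboring
#' boxes share about `overlap` of a tile width (rounded up to whole pixels),
#' with edge tiles clipped to the image. For the full per-well FOV of
#' 1.1 x 0.85 mm with 110 um tiles this yields the 10 x 8 = 80-tile grid.
#'
#' @param fov_mm Length-2 FOV in mm (x, y).
#' @param tile_um Tile pitch in um (<= min FOV).
#' @param overlap Nominal overlap fraction in `[0, 0.5)` (default 0.05).
#' @param pixel_um Pixel pitch in um.
#' @return Object of class `tile_grid`: `tiles` data frame (`tile`, `row`,
#'   `col`, `x0`, `x1`, `y0`, `y1`; 1-based inclusive pixel indices, x along
#'   columns), `image_px`, `overlap_px`.
#' @export
partition_fov <- function(fov_mm, tile_um, overlap = 0.05, pixel_um) {
  if (overlap < 0 || overlap >= 0.5) stopf("overlap must be in [0, 0.5)")
  W <- round(fov_mm[1] * 1000 / pixel_um)
  H <- round(fov_mm[2] * 1000 / pixel_um)
  t_px <- round(tile_um / pixel_um)
  if (t_px > min(W, H)) stopf("tile (%d px) larger than FOV (%d x %d px)", t_px, W, H)
  ext <- ceiling(overlap * t_px / 2)    # each side; neighbors share 2*ext
  n_cols <- ceiling(W / t_px)
  n_rows <- ceiling(H / t_px)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  x0 <- pmax((g$col - 1L) * t_px + 1L - ext, 1L)
  x1 <- pmin(g$col * t_px + ext, W)
  y0 <- pmax((g$row - 1L) * t_px + 1L - ext, 1L)
  y1 <- pmin(g$row * t_px + ext, H)
  tiles <- data.frame(tile = seq_len(nrow(g)), row = g$row, col = g$col,
                      x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  structure(list(tiles = tiles, image_px = c(W, H), overlap_px = 2L * ext,
                 tile_px = t_px, n_rows = n_rows, n_cols = n_cols,
                 pixel_um = pixel_um),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d px (+%d px overlap) covering %d x %d px\n",
              x$n_rows, x$n_cols, x$tile_px, x$overlap_px,
              x$image_px[1], x$image_px[2]))
  invisible(x)
}

# feather weight of one tile box: distance to the nearest box edge + 1
.feather_weight <- function(x0, x1, y0, y1) {
  wx <- pmin(seq(x0, x1) - x0, x1 - seq(x0, x1)) + 1
  wy <- pmin(seq(y0, y1) - y0, y1 - seq(y0, y1)) + 1
  outer(wy, wx, pmin)
}

#' Feather-blend complex tiles into a mosaic
#'
#' Per-pixel weighted average of complex tile values with weights
#' proportional to each tile's distance to its own box edge (a feather ramp),
#' normalized so weights sum to one everywhere. Blending happens in the
#' complex domain (amplitude and phase together), which avoids 2-pi seam
#' artifacts that blending wrapped phase would create. Exact passthrough
#' wherever only one tile contributes.
#'
#' @param tiles List of complex matrices, one per row of `grid$tiles`, with
#'   matching box sizes (rows = y, columns = x).
#' @param grid A [partition_fov()] result.
#' @return Complex matrix `H x W`.
#' @export
feather_blend <- function(tiles, grid) {
  tb <- grid$tiles
  missing <- setdiff(tb$tile, seq_along(tiles)[!vapply(tiles, is.null, logical(1))])
  if (length(tiles) < nrow(tb) || length(missing))
    stopf("missing tile image for tile index %s",
          paste(utils::head(c(missing, setdiff(seq_len(nrow(tb)), seq_along(tiles))), 3),
                collapse = ", "))
  W <- grid$image_px[1]; H <- grid$image_px[2]
  acc <- matrix(0 + 0i, H, W)
  wacc <- matrix(0, H, W)
  for (i in seq_len(nrow(tb))) {
    t <- tiles[[tb$tile[i]]]
    ny <- tb$y1[i] - tb$y0[i] + 1L; nx <- tb$x1[i] - tb$x0[i] + 1L
    if (nrow(t) != ny || ncol(t) != nx)
      stopf("tile %d image is %d x %d but its box is %d x %d",
            tb$tile[i], nrow(t), ncol(t), ny, nx)
    w <- .feather_weight(tb$x0[i], tb$x1[i], tb$y0[i], tb$y1[i])
    ys <- tb$y0[i]:tb$y1[i]; xs <- tb$x0[i]:tb$x1[i]
    acc[ys, xs] <- acc[ys, xs] + t * w
    wacc[ys, xs] <- wacc[ys, xs] + w
  }
  if (any(wacc == 0)) stopf("tile grid does not cover the image")
  acc / wacc
}

#' Remove per-tile global phases before blending
#'
#' Each tile of an FPM mosaic is reconstructed independently and therefore
#' carries its own arbitrary global phase. This aligns the gauge: the first
#' tile anchors it, and every subsequent tile (row-major) is multiplied by
#' the unit-modulus constant that maximizes agreement with the already
#' aligned mosaic over the overlap region.
#'
#' @param tiles List of complex tile images (as for [feather_blend()]).
#' @param grid A [partition_fov()] result with overlapping tiles.
#' @return List of gauge-aligned tiles; attribute `gauges` holds the applied
#'   unit phasors. Warns (and applies identity) on a zero-energy overlap.
#' @export
align_tile_gauge <- function(tiles, grid) {
  tb <- grid$tiles
  if (nrow(tb) < 2) return(tiles)
  W <- grid$image_px[1]; H <- grid$image_px[2]
  canvas <- matrix(NA_complex_, H, W)
  gauges <- complex(real = rep(1, nrow(tb)))
  for (i in seq_len(nrow(tb))) {
    ys <- tb$y0[i]:tb$y1[i]; xs <- tb$x0[i]:tb$x1[i]
    t <- tiles[[tb$tile[i]]]
    if (i > 1) {
      prev <- canvas[ys, xs]
      ok <- !is.na(prev)
      ip <- sum(prev[ok] * Conj(t[ok]))
      if (!any(ok) || Mod(ip) < 1e-12 * sum(ok)) {
        warning(sprintf("zero-energy overlap for tile %d; identity gauge applied", tb$tile[i]))
      } else {
        gauges[i] <- ip / Mod(ip)
        t <- t * gauges[i]
      }
      tiles[[tb$tile[i]]] <- t
    }
    reg <- canvas[ys, xs]
    reg[is.na(reg)] <- t[is.na(reg)]
    canvas[ys, xs] <- reg
  }
  attr(tiles, "gauges") <- gauges
  tiles
}

#' Crop a high-resolution object into tile images
#'
#' Helper for simulator round trips: cuts the boxes of `grid` (defined at raw
#' pixel pitch) out of an upsampled object or image.
#'
#' @param values Matrix (complex or real), `H*u x W*u`.
#' @param grid A [partition_fov()] result.
#' @param upsample Pixels per raw pixel in `values` (default 1).
#' @return List of tile matrices in `grid$tiles` order.
#' @export
crop_tiles <- function(values, grid, upsample = 1) {
  tb <- grid$tiles
  lapply(seq_len(nrow(tb)), function(i) {
    ys <- ((tb$y0[i] - 1L) * upsample + 1L):(tb$y1[i] * upsample)
    xs <- ((tb$x0[i] - 1L) * upsample + 1L):(tb$x1[i] * upsample)
    values[ys, xs]
  })
}
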