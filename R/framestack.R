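#' Repeated exposures under one illumination
#'
#' @param repeats 3-D array `n_repeats x H x W` acquired under identical
#'   illumination.
#' @param illumination Illumination identifier (frame index or LED id).
#' @param z_um Optional stage position.
#' @return Object of class `frame_sequence`.
#' @export
frame_sequence <- function(repeats, illumination = NA, z_um = NA_real_) {
  if (length(dim(repeats)) == 2) repeats <- array(repeats, dim = c(1, dim(repeats)))
  if (length(dim(repeats)) != 3 || dim(repeats)[1] < 1)
    stopf("repeats must be a non-empty n_repeats x H x W array")
  structure(list(repeats = repeats, illumination = illumination, z_um = z_um),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$repeats)
  cat(sprintf("<frame_sequence> %d repeats of %d x %d (illumination %s)\n",
              d[1], d[2], d[3], as.character(x$illumination)))
  invisible(x)
}

#' Digital frame averaging
#'
#' Per-pixel mean over repeated exposures of the same field; white noise
#' shrinks as `1/sqrt(n)`.
#'
#' @param seq A [frame_sequence()].
#' @return Averaged image matrix.
#' @export
average_frames <- function(seq) {
  if (!inherits(seq, "frame_sequence")) seq <- frame_sequence(seq)
  d <- dim(seq$repeats)
  if (d[1] == 1) return(seq$repeats[1, , ])
  apply(seq$repeats, c(2, 3), mean)
}

#' Estimate and remove the static fixed pattern
#'
#' Two-stage estimate of the sensor's static band pattern (the horizontal
#' structure of consumer-grade CMOS readout). Stage 1 isolates what is static
#' across illuminations: the per-pixel median of the illumination-averaged
#' frames after removing each frame's mean. Stage 2 exploits the pattern's
#' band structure, projecting the median image onto its row profile, which
#' suppresses whatever object content survives the median (in-focus
#' brightfield images change only mildly with illumination angle, so some
#' always does). The estimate is subtracted from every repeat of every
#' sequence. Needs at least 3 distinct illuminations to be identifiable.
#'
#' @param seqs List of [frame_sequence()]s under distinct illuminations.
#' @param band_axis `"rows"` (default) applies the band projection along
#'   rows; `"none"` keeps the raw per-pixel median (for non-banded patterns).
#' @return List with `sequences` (corrected, same structure) and `pattern`
#'   (the estimated static image).
#' @export
remove_static_pattern <- function(seqs, band_axis = c("rows", "none")) {
  band_axis <- match.arg(band_axis)
  if (length(seqs) < 3)
    stopf("static pattern is unidentifiable from %d illumination(s); need >= 3",
          length(seqs))
  avgs <- lapply(seqs, average_frames)
  centered <- lapply(avgs, function(a) a - mean(a))
  stack <- simplify2array(centered)               # H x W x n
  pattern <- apply(stack, c(1, 2), stats::median)
  if (band_axis == "rows")
    pattern <- outer(rowMeans(pattern), rep(1, ncol(pattern)))
  corrected <- lapply(seqs, function(s) {
    s$repeats <- sweep(s$repeats, c(2, 3), pattern)
    s
  })
  list(sequences = corrected, pattern = pattern)
}

#' Average and pattern-correct a noisy acquisition
#'
#' Convenience wrapper for the two-stage denoising of a simulated or recorded
#' acquisition: average the repeats of every illumination, estimate and
#' subtract the static pattern, and reassemble an [fpm_dataset()] (negative
#' pixels clipped to zero).
#'
#' @param noisy Output of [add_sensor_noise()] (carries `k_eff`, `cfg`,
#'   `scale` as attributes).
#' @return An [fpm_dataset()] in the forward model's intensity units.
#' @export
denoise_dataset <- function(noisy) {
  fixed <- remove_static_pattern(noisy)
  scale <- attr(noisy, "scale")
  imgs <- lapply(fixed$sequences, average_frames)
  d <- dim(imgs[[1]])
  frames <- array(0, dim = c(length(imgs), d[1], d[2]))
  for (j in seq_along(imgs)) frames[j, , ] <- pmax(imgs[[j]], 0) / scale
  fpm_dataset(frames, attr(noisy, "k_eff"), attr(noisy, "cfg"),
              provenance = list(type = "denoised",
                                pattern = fixed$pattern, scale = scale))
}

#' Select the sharpest plane of a z-stack
#'
#' Argmax of the normalized gradient energy (Tenengrad-style:
#' mean squared finite-difference gradient divided by squared mean
#' intensity); ties break to the lowest z. Used for the fluorescence-like
#' channel where depth of field cannot be extended computationally.
#'
#' @param zstack List of image matrices.
#' @param z_um Numeric vector of stage positions, same length.
#' @return List `z_um`, `image`, `scores`.
#' @export
select_sharpest_plane <- function(zstack, z_um) {
  if (length(zstack) < 2) stopf("need at least 2 planes")
  if (length(zstack) != length(z_um)) stopf("z positions must match the stack")
  scores <- vapply(zstack, function(im) {
    gx <- diff(t(im)); gy <- diff(im)
    (mean(gx^2) + mean(gy^2)) / max(mean(im)^2, 1e-24)
  }, numeric(1))
  ord <- order(z_um)
  scores_o <- scores[ord]
  best <- ord[which.max(scores_o)]      # which.max takes the first = lowest z
  list(z_um = z_um[best], image = zstack[[best]], scores = scores)
}
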