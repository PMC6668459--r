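#' Dataset archives on disk
#'
#' An archive is a directory with a fixed schema mirroring the pipeline's
#' logical layout:
#'
#' ```
#' archive/
#'   config.yaml            optical configuration + schema version
#'   plan.csv               frame, led_id, x_mm, y_mm (lit LEDs per frame)
#'   wells/<ID>/frames.tif  multi-page float TIFF, one page per frame
#'   wells/<ID>/frames_scale.csv   per-page offset/scale (TIFF stores [0,1])
#'   wells/<ID>/k_eff.csv   frame, fx, fy (1/um)
#'   recon/<ID>/...         amplitude/phase/pupil TIFFs, residuals.csv,
#'                          delta_z.txt (written by [cli_reconstruct()])
#' ```
#'
#' Images are stored as 32-bit float TIFF normalized to `[0, 1]` with the
#' affine scale recorded in a sidecar, so float payloads round-trip at
#' single precision.
#'
#' @name archive
NULL

ARCHIVE_SCHEMA_VERSION <- "1"

.write_image_stack <- function(stack, dir, name) {
  # stack: n x H x W
  n <- dim(stack)[1]
  pages <- vector("list", n)
  sc <- data.frame(page = seq_len(n), offset = 0, scale = 1)
  for (j in seq_len(n)) {
    im <- stack[j, , ]
    lo <- min(im); hi <- max(im)
    s <- if (hi > lo) hi - lo else 1
    sc$offset[j] <- lo; sc$scale[j] <- s
    pages[[j]] <- (im - lo) / s
  }
  tiff::writeTIFF(pages, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(sc, file.path(dir, paste0(name, "_scale.csv")), row.names = FALSE)
}

.read_image_stack <- function(dir, name) {
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- utils::read.csv(file.path(dir, paste0(name, "_scale.csv")))
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_along(pages)) out[j, , ] <- pages[[j]] * sc$scale[j] + sc$offset[j]
  out
}

#' Write an acquisition archive
#'
#' @param path Directory to create (must not exist or be empty).
#' @param datasets Named list of [fpm_dataset()]s keyed by well ID.
#' @param cfg The shared [optical_config()].
#' @param plan_df Optional [plan_table()] data frame.
#' @return `path`, invisibly.
#' @export
write_archive <- function(path, datasets, cfg, plan_df = NULL) {
  if (dir.exists(path) && length(dir(path))) stopf("archive path %s is not empty", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = ARCHIVE_SCHEMA_VERSION,
               units = list(length = "um", frequency = "1/um", plate = "mm"),
               optical_config = cfg[setdiff(names(cfg), "lambda_um")])
  yaml::write_yaml(meta, file.path(path, "config.yaml"))
  if (!is.null(plan_df))
    utils::write.csv(plan_df, file.path(path, "plan.csv"), row.names = FALSE)
  for (w in names(datasets)) {
    wd <- file.path(path, "wells", w)
    dir.create(wd, recursive = TRUE, showWarnings = FALSE)
    ds <- datasets[[w]]
    .write_image_stack(ds$frames, wd, "frames")
    utils::write.csv(data.frame(frame = seq_len(nrow(ds$k_eff)),
                                fx = ds$k_eff[, 1], fy = ds$k_eff[, 2]),
                     file.path(wd, "k_eff.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an acquisition archive
#'
#' @param path Archive directory.
#' @param wells Optional character vector of well IDs (default: all present).
#' @return List with `cfg`, `plan` (or NULL), and `datasets` (named list of
#'   [fpm_dataset()]s).
#' @export
read_archive <- function(path, wells = NULL) {
  meta <- yaml::read_yaml(file.path(path, "config.yaml"))
  oc <- meta$optical_config
  cfg <- optical_config(wavelength_nm = oc$wavelength_nm, na_obj = oc$na_obj,
                        magnification = oc$magnification, pixel_um = oc$pixel_um,
                        fov_mm = unlist(oc$fov_mm),
                        object_to_sensor_mm = oc$object_to_sensor_mm,
                        working_distance_mm = oc$working_distance_mm,
                        tile_um = oc$tile_um, upsample = oc$upsample)
  plan <- NULL
  if (file.exists(file.path(path, "plan.csv")))
    plan <- utils::read.csv(file.path(path, "plan.csv"))
  present <- basename(list.dirs(file.path(path, "wells"), recursive = FALSE))
  wells <- wells %||% present
  datasets <- stats::setNames(lapply(wells, function(w) {
    wd <- file.path(path, "wells", w)
    if (!dir.exists(wd)) stopf("well %s not present in archive", w)
    frames <- .read_image_stack(wd, "frames")
    ke <- utils::read.csv(file.path(wd, "k_eff.csv"))
    fpm_dataset(frames, as.matrix(ke[, c("fx", "fy")]), cfg,
                provenance = list(type = "archive", path = path))
  }), wells)
  list(cfg = cfg, plan = plan, datasets = datasets)
}

#' Validate an archive against the schema
#'
#' @param path Archive directory.
#' @return Data frame `item`, `problem`; zero rows means valid. Validation is
#'   a pure report (a fixpoint: validating twice yields identical reports).
#' @export
validate_archive <- function(path) {
  problems <- list()
  note <- function(item, problem) problems[[length(problems) + 1]] <<-
    data.frame(item = item, problem = problem, stringsAsFactors = FALSE)
  if (!dir.exists(path)) {
    note(path, "archive directory does not exist")
    return(do.call(rbind, problems))
  }
  cfg_file <- file.path(path, "config.yaml")
  if (!file.exists(cfg_file)) note("config.yaml", "missing")
  else {
    meta <- tryCatch(yaml::read_yaml(cfg_file), error = function(e) NULL)
    if (is.null(meta)) note("config.yaml", "unparseable")
    else {
      if (is.null(meta$schema_version)) note("config.yaml", "schema_version attribute absent")
      if (is.null(meta$optical_config)) note("config.yaml", "optical_config absent")
      if (is.null(meta$units)) note("config.yaml", "units attribute absent")
    }
  }
  wells_dir <- file.path(path, "wells")
  wells <- if (dir.exists(wells_dir)) basename(list.dirs(wells_dir, recursive = FALSE)) else character(0)
  if (!length(wells)) note("wells/", "no well groups present")
  for (w in wells) {
    wd <- file.path(wells_dir, w)
    fr <- file.path(wd, "frames.tif"); ke <- file.path(wd, "k_eff.csv")
    if (!file.exists(fr)) { note(paste0("wells/", w), "frames.tif missing"); next }
    if (!file.exists(ke)) { note(paste0("wells/", w), "k_eff.csv missing"); next }
    pages <- tiff::readTIFF(fr, all = TRUE)
    n_frames <- if (is.list(pages)) length(pages) else 1L
    n_k <- nrow(utils::read.csv(ke))
    if (n_frames != n_k)
      note(paste0("wells/", w),
           sprintf("frame count mismatch: %d frames vs %d k_eff rows (frames %s)",
                   n_frames, n_k,
                   paste(utils::head(setdiff(seq_len(max(n_frames, n_k)),
                                             seq_len(min(n_frames, n_k))), 5),
                         collapse = ",")))
  }
  out <- if (length(problems)) do.call(rbind, problems)
  else data.frame(item = character(0), problem = character(0))
  out
}
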