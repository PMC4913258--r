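#' Calibrated photon-count image stack
#'
#' `ld_stack()` wraps a 3D array of nonnegative photon counts together with
#' its physical calibration and acquisition metadata.  The array is indexed
#' `[y, x, z]` (row, column, plane).  Pixel indices are 0-based in physical
#' terms: the centre of pixel `i` (0-based) lies at `i * pixel_size_um`.
#'
#' @param voxels numeric 3D array of counts, dimension `(ny, nx, nz)`.  A
#'   matrix is promoted to a single-plane stack.
#' @param pixel_size_um lateral pixel size in micrometres (default 0.098).
#' @param z_step_um axial plane spacing in micrometres (default 0.3).
#' @param dwell_time_s pixel dwell time in seconds (default 9.6e-6).
#' @param dead_time_s detector dead time in seconds (default 0, i.e. no
#'   saturation).
#' @param power_factor dimensionless relative laser power at acquisition.
#' @return an object of class `ld_stack`.
#' @examples
#' s <- ld_stack(array(rpois(4 * 4 * 2, 5), c(4, 4, 2)))
#' dim(s$voxels)
#' @export
ld_stack <- function(voxels, pixel_size_um = 0.098, z_step_um = 0.3,
                     dwell_time_s = 9.6e-6, dead_time_s = 0,
                     power_factor = 1) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(voxels < 0, na.rm = TRUE)) {
    stop("stack voxel counts must be nonnegative", call. = FALSE)
  }
  if (pixel_size_um <= 0 || z_step_um <= 0 || dwell_time_s <= 0) {
    stop("calibration fields must be positive", call. = FALSE)
  }
  if (power_factor <= 0) stop("power_factor must be positive", call. = FALSE)
  structure(
    list(
      voxels = voxels,
      pixel_size_um = pixel_size_um,
      z_step_um = z_step_um,
      dwell_time_s = dwell_time_s,
      dead_time_s = dead_time_s,
      power_factor = power_factor,
      log = character()
    ),
    class = "ld_stack"
  )
}

#' @export
print.ld_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ld_stack> %d x %d px, %d plane(s) | %.3f um/px lateral, %.2f um z-step\n",
    d[2], d[1], d[3], x$pixel_size_um, x$z_step_um
  ))
  cat(sprintf(
    "  counts: min %.3g, max %.3g | dwell %.3g s, dead time %.3g s, power %.3g\n",
    min(x$voxels), max(x$voxels), x$dwell_time_s, x$dead_time_s,
    x$power_factor
  ))
  invisible(x)
}

#' @export
dim.ld_stack <- function(x) dim(x$voxels)

#' Voxel volume of a stack in cubic micrometres
#' @param stack an [ld_stack()].
#' @return scalar voxel volume (um^3).
#' @export
voxel_volume_um3 <- function(stack) {
  stack$pixel_size_um^2 * stack$z_step_um
}

# Replace voxels, append a log line, keep metadata.
stack_update <- function(stack, voxels, note) {
  stack$voxels <- voxels
  stack$log <- c(stack$log, note)
  stack
}

#' Write a stack as multi-page 16-bit TIFF
#'
#' One page per z-plane, 16-bit unsigned counts.  The calibration and
#' acquisition metadata are stored in a JSON sidecar (`<path>.json`)
#' alongside the image.  Values above 65535 are clipped with a warning.
#'
#' @param stack an [ld_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- round(stack$voxels)
  if (any(v > 65535)) {
    warning("counts above 65535 clipped when writing 16-bit TIFF")
    v[v > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(
      pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
      dwell_time_s = stack$dwell_time_s, dead_time_s = stack$dead_time_s,
      power_factor = stack$power_factor
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' Calibration is recovered from the JSON sidecar (`<path>.json`) when
#' present; otherwise defaults are used.
#'
#' @param path TIFF file path.
#' @return an [ld_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  cal <- list()
  if (file.exists(paste0(path, ".json"))) {
    cal <- tryCatch(jsonlite::read_json(paste0(path, ".json"),
                                        simplifyVector = TRUE),
                    error = function(e) list())
  }
  ld_stack(
    v,
    pixel_size_um = cal$pixel_size_um %||% 0.098,
    z_step_um = cal$z_step_um %||% 0.3,
    dwell_time_s = cal$dwell_time_s %||% 9.6e-6,
    dead_time_s = cal$dead_time_s %||% 0,
    power_factor = cal$power_factor %||% 1
  )
}

#' Write / read integer label masks as 16-bit TIFF
#' @param mask integer label matrix (0 = background).
#' @param path file path.
#' @return `path` (write) or an integer matrix (read), invisibly for write.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
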