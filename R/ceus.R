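#' Contrast-enhanced ultrasound sequence
#'
#' Container for a time-ordered stack of 2D intensity frames with physical
#' calibration. Frames are stored as a 3D array ordered `(t, z, x)` so that
#' temporal operations (Casorati reshaping, trail analysis) act on the
#' fastest-varying dimension.
#'
#' @param frames numeric 3D array `(t, z, x)` of finite intensities.
#' @param pixel_size pixel pitch in mm, isotropic in `z` and `x`.
#' @param frame_rate acquisition frame rate in Hz.
#' @param roi_mask optional logical `(z, x)` matrix restricting analysis.
#' @param nonneg if `TRUE`, reject negative intensities (raw/rendered data);
#'   filtered sequences are signed residuals and use `FALSE`.
#' @return An object of class `ceus_sequence`.
#' @export
ceus_sequence <- function(frames, pixel_size, frame_rate, roi_mask = NULL,
                          nonneg = FALSE) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!all(is.finite(frames))) stop("frames must be finite")
  if (nonneg && any(frames < 0)) stop("raw CEUS intensities must be >= 0")
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_rate), frame_rate > 0)
  if (!is.null(roi_mask)) {
    roi_mask <- as.matrix(roi_mask) != 0
    if (!all(dim(roi_mask) == dim(frames)[2:3]))
      stop("roi_mask must match the (z, x) frame shape")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate, roi_mask = roi_mask),
            class = "ceus_sequence")
}

#' @export
print.ceus_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ceus_sequence> %d frames of %d x %d px | %.0f um pixels | %g Hz\n",
              d[1], d[2], d[3], x$pixel_size * 1000, x$frame_rate))
  cat(sprintf("  intensity range [%.3g, %.3g]%s\n",
              min(x$frames), max(x$frames),
              if (is.null(x$roi_mask)) "" else " | ROI mask set"))
  invisible(x)
}

#' @export
dim.ceus_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[1]

#' Extract one frame as a (z, x) matrix
#' @param seq a [ceus_sequence()].
#' @param t frame index (1-based).
#' @export
get_frame <- function(seq, t) {
  stopifnot(t >= 1, t <= n_frames(seq))
  seq$frames[t, , ]
}

#' Write a sequence as multi-page 32-bit TIFF with a YAML sidecar
#'
#' Intensities are rescaled to `[0, 1]` for TIFF storage; the scale factor,
#' offset and calibration are recorded in `<path>.yaml` so that
#' [read_ceus_tiff()] round-trips the data.
#'
#' @param seq a [ceus_sequence()].
#' @param path output TIFF path.
#' @export
write_ceus_tiff <- function(seq, path) {
  lo <- min(seq$frames); hi <- max(seq$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(seq)),
                  function(t) (seq$frames[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size = seq$pixel_size, frame_rate = seq$frame_rate,
               intensity_offset = lo, intensity_scale = scale,
               n_frames = n_frames(seq))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a sequence written by [write_ceus_tiff()]
#' @param path TIFF path (expects `<path>.yaml` sidecar).
#' @export
read_ceus_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), nz, nx))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * meta$intensity_scale + meta$intensity_offset
  ceus_sequence(frames, meta$pixel_size, meta$frame_rate)
}

# pixels-by-frames Casorati matrix
casorati <- function(seq) {
  d <- dim(seq$frames)
  matrix(aperm(seq$frames, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
}

# inverse of casorati(): rebuild the (t, z, x) array
uncasorati <- function(C, nz, nx) {
  aperm(array(C, dim = c(nz, nx, ncol(C))), c(3, 1, 2))
}
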