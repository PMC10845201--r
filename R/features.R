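#' Build the spatio-temporal stack for trail analysis
#'
#' Moving microbubbles trace continuous tubes through the 3D `(t, z, x)`
#' stack; the orientation of each tube encodes instantaneous velocity. This
#' step crops a motion-free segment and thresholds the intensities to mark
#' the voxels accepted as MB signal.
#'
#' @param seq a (clutter-filtered) [ceus_sequence()].
#' @param segment integer `c(start, end)` frame interval (1-based inclusive);
#'   defaults to the full sequence.
#' @param detect_quantile quantile of the positive voxel intensities used as
#'   the detection threshold. Voxels at or above it enter the MB mask;
#'   `detect_quantile = 1` yields an empty mask.
#' @return object of class `parm_stack`: `voxels` (t, z, x array over the
#'   segment), `mb_mask` (logical, same shape), calibration and segment.
#' @export
build_stack <- function(seq, segment = NULL, detect_quantile = 0.95) {
  stopifnot(inherits(seq, "ceus_sequence"))
  nt <- n_frames(seq)
  if (is.null(segment)) segment <- c(1L, nt)
  stopifnot(length(segment) == 2, segment[1] >= 1, segment[2] <= nt,
            segment[2] > segment[1])
  voxels <- seq$frames[segment[1]:segment[2], , , drop = FALSE]
  if (!is.null(seq$roi_mask)) {
    roi3 <- aperm(array(seq$roi_mask, dim = c(dim(voxels)[2:3], dim(voxels)[1])),
                  c(3, 1, 2))
    voxels[!roi3] <- 0
  }
  pos <- voxels[voxels > 0]
  if (detect_quantile >= 1 || !length(pos)) {
    mask <- array(FALSE, dim = dim(voxels))
  } else {
    thr <- stats::quantile(pos, detect_quantile, names = FALSE)
    mask <- voxels >= thr
  }
  if (!any(mask)) warning("empty MB mask: no voxels pass the detection threshold")
  structure(list(voxels = voxels, mb_mask = mask,
                 pixel_size = seq$pixel_size,
                 frame_interval = 1 / seq$frame_rate,
                 segment = as.integer(segment)),
            class = "parm_stack")
}

#' @export
print.parm_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<parm_stack> frames %d..%d (%d x %d x %d), %d masked voxels\n",
              x$segment[1], x$segment[2], d[1], d[2], d[3], sum(x$mb_mask)))
  invisible(x)
}

#' Structure-tensor orientation of microbubble trails
#'
#' Estimates, at every masked voxel, the principal axis of the local tubular
#' structure in the `(t, z, x)` stack from the 3D structure tensor of
#' Gaussian-derivative gradients averaged in a Gaussian window. The trail
#' axis is the eigenvector of the smallest eigenvalue; coherence
#' `(lambda2 - lambda3) / (lambda2 + lambda3)` in `[0, 1]` scores how
#' tube-like the neighbourhood is. The eigenvector sign is fixed so the time
#' component is non-negative, which makes the in-plane components point along
#' the physical flow direction.
#'
#' @param stack a [build_stack()] result with at least `2 * window_sigma`
#'   frames.
#' @param gradient_sigma Gaussian-derivative scale, voxels.
#' @param window_sigma tensor-averaging window scale, voxels.
#' @param time_scale anisotropy factor: voxels per frame used to place the
#'   time axis on the spatial metric (1 = frames treated as pixels).
#' @param mask optional logical array overriding `stack$mb_mask`.
#' @return data frame of class `parm_orientations` with voxel indices
#'   (`voxel` linear, `t`, `z`, `x`), unit axis (`u_t`, `u_z`, `u_x`,
#'   `u_t >= 0`) and `coherence`. Zero-gradient voxels are dropped.
#' @export
tensor_orientation <- function(stack, gradient_sigma = 1, window_sigma = 2,
                               time_scale = 1, mask = NULL) {
  stopifnot(inherits(stack, "parm_stack"),
            gradient_sigma > 0, window_sigma > 0, time_scale > 0)
  d <- dim(stack$voxels)
  if (d[1] < 2 * window_sigma)
    stop("stack too short for the tensor window")
  if (is.null(mask)) mask <- stack$mb_mask
  idx <- which(mask)
  if (!length(idx)) stop("no masked voxels to orient")
  m <- .st_orient_cpp(as.numeric(stack$voxels), as.integer(d),
                      gradient_sigma, window_sigma, time_scale,
                      as.integer(idx))
  ai <- arrayInd(idx, d)
  out <- data.frame(voxel = idx, t = ai[, 1], z = ai[, 2], x = ai[, 3],
                    u_t = m[, 1], u_z = m[, 2], u_x = m[, 3],
                    coherence = m[, 4])
  out <- out[is.finite(out$coherence), , drop = FALSE]
  attr(out, "time_scale") <- time_scale
  attr(out, "gradient_sigma") <- gradient_sigma
  attr(out, "window_sigma") <- window_sigma
  class(out) <- c("parm_orientations", "data.frame")
  out
}

#' Convert trail orientations into velocity feature points
#'
#' For each accepted voxel the per-frame displacement follows from the axis
#' slope: `v_x = time_scale * u_x / u_t` pixels per frame (likewise `v_z`),
#' converted to mm/s with the calibration. Near-horizontal tubes
#' (`u_t` below a floor, implying speed above `v_max`) are clipped to
#' `v_max` and flagged.
#'
#' @param stack the [build_stack()] result the orientations came from.
#' @param orientations a [tensor_orientation()] result.
#' @param v_max speed ceiling in mm/s; defaults to
#'   `0.5 * (pixel_size / frame_interval) * (4 * window_sigma + 1)`, the
#'   fastest trail the tensor window can follow.
#' @param min_coherence minimum tube-ness confidence in `[0, 1]`; voxels
#'   below it are rejected (this is also the guard against distorted,
#'   overlapping-MB voxels).
#' @return data frame of class `parm_points` with columns `t_index` (absolute
#'   frame), `x`, `z` (mm), `speed` (mm/s), `direction` (radians in
#'   `(-pi, pi]` from +x toward +z), `coherence`, `intensity`, `clipped`,
#'   and `voxel` (linear index into the stack, used to split the sequence).
#' @export
extract_feature_points <- function(stack, orientations, v_max = NULL,
                                   min_coherence = 0.5) {
  stopifnot(inherits(stack, "parm_stack"), inherits(orientations, "parm_orientations"))
  a <- attr(orientations, "time_scale")
  ws <- attr(orientations, "window_sigma")
  px_per_s <- stack$pixel_size / stack$frame_interval
  if (is.null(v_max)) v_max <- 0.5 * px_per_s * (4 * ws + 1)
  o <- orientations[orientations$coherence >= min_coherence, , drop = FALSE]
  if (!nrow(o)) stop("no MB signal: all voxels rejected by the coherence gate")
  ut <- o$u_t
  floor_ut <- 1e-8
  fast <- ut < floor_ut
  ut[fast] <- floor_ut
  vx <- a * o$u_x / ut * px_per_s
  vz <- a * o$u_z / ut * px_per_s
  speed <- sqrt(vx^2 + vz^2)
  clipped <- fast | speed > v_max
  speed <- pmin(speed, v_max)
  direction <- atan2(vz, vx)
  direction[direction <= -pi] <- pi
  out <- data.frame(
    t_index = stack$segment[1] + o$t - 1L,
    x = (o$x - 0.5) * stack$pixel_size,
    z = (o$z - 0.5) * stack$pixel_size,
    speed = speed, direction = direction,
    coherence = o$coherence,
    intensity = stack$voxels[cbind(o$t, o$z, o$x)],
    clipped = clipped, voxel = o$voxel)
  attr(out, "calibration") <- list(pixel_size = stack$pixel_size,
                                   frame_interval = stack$frame_interval)
  attr(out, "v_max") <- v_max
  attr(out, "segment") <- stack$segment
  class(out) <- c("parm_points", "data.frame")
  out
}

#' Write feature points to CSV
#' @param points a `parm_points` data frame.
#' @param path output CSV path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points[, c("t_index", "z", "x", "speed", "direction",
                              "coherence", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}
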