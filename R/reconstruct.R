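#' Parameters of the radial-fluctuation (SRRF-style) reconstruction
#'
#' Defaults: ring radius 8 (input
#' pixels), radiality magnification 3, and 8 axes in the ring.
#'
#' @param ring_radius gradient-sampling ring radius in input pixels (> 0).
#' @param magnification integer output magnification (>= 1).
#' @param ring_axes number of gradient samples on the ring (even, >= 4).
#' @param temporal_mode `"mean"` (temporal radiality average) or
#'   `"variance"`.
#' @export
srrf_params <- function(ring_radius = 8, magnification = 3, ring_axes = 8,
                        temporal_mode = c("mean", "variance")) {
  temporal_mode <- match.arg(temporal_mode)
  stopifnot(ring_radius > 0, magnification >= 1,
            ring_axes >= 4, ring_axes %% 2 == 0)
  structure(list(ring_radius = ring_radius,
                 magnification = as.integer(magnification),
                 ring_axes = as.integer(ring_axes),
                 temporal_mode = temporal_mode),
            class = "srrf_params")
}

#' Radiality transform of a single frame
#'
#' For each pixel of the magnified grid, the image gradient is sampled at
#' `ring_axes` points on a ring of `ring_radius` input pixels; radiality
#' measures how strongly those gradients converge toward the ring center
#' (inward-pointing gradients whose line passes near the center score high,
#' outward ones score negative), floored at zero. True emitter centers light
#' up as peaks markedly narrower than the input point-spread function.
#'
#' @param frame 2D `(z, x)` intensity matrix, at least
#'   `2 * ring_radius + 1` pixels in each dimension.
#' @param params an [srrf_params()].
#' @return magnified radiality matrix (`dim(frame) * magnification`).
#' @export
radiality_frame <- function(frame, params = srrf_params()) {
  frame <- as.matrix(frame)
  if (any(dim(frame) < 2 * params$ring_radius + 1))
    stop("frame smaller than the sampling ring")
  .radiality_frame_cpp(frame, params$ring_radius,
                       params$magnification, params$ring_axes)
}

#' Super-resolved map from a (sub)sequence via temporal radiality
#'
#' Applies [radiality_frame()] to every frame and aggregates over time with
#' the configured mode (mean by default); the result is normalized to
#' `[0, 1]`.
#'
#' @param seq a [ceus_sequence()], typically one per-pattern subsequence.
#' @param params an [srrf_params()].
#' @param pattern_index label stored with the map (integer or "composite").
#' @param normalize rescale the aggregated map to `[0, 1]` (default); set
#'   `FALSE` to keep raw radiality units (needed when maps from different
#'   subsequences must stay mutually comparable).
#' @return object of class `sr_map`: `grid` (magnified, in `[0, 1]`),
#'   `pixel_size` (input / magnification, mm), `pattern_index`, `params`.
#' @export
srrf_reconstruct <- function(seq, params = srrf_params(), pattern_index = NA,
                             normalize = TRUE) {
  stopifnot(inherits(seq, "ceus_sequence"))
  d <- dim(seq$frames)
  if (any(d[2:3] < 2 * params$ring_radius + 1))
    stop("frames smaller than the sampling ring")
  mode <- if (params$temporal_mode == "mean") 0L else 1L
  grid <- .srrf_stack_cpp(as.numeric(seq$frames), as.integer(d),
                          params$ring_radius, params$magnification,
                          params$ring_axes, mode)
  mx <- max(grid)
  if (mx == 0) warning("all-zero subsequence: returning a zero map")
  if (normalize && mx > 0) grid <- grid / mx
  structure(list(grid = grid,
                 pixel_size = seq$pixel_size / params$magnification,
                 pattern_index = pattern_index, params = params),
            class = "sr_map")
}

#' @export
print.sr_map <- function(x, ...) {
  cat(sprintf("<sr_map> %d x %d @ %.1f um/px (pattern %s)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size * 1000,
              as.character(x$pattern_index)))
  invisible(x)
}

#' Pixel-wise maximum composite of super-resolved maps
#' @param maps list of `sr_map` objects on the same grid.
#' @export
composite_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- Reduce(pmax, lapply(maps, function(m) m$grid))
  structure(list(grid = grid, pixel_size = maps[[1]]$pixel_size,
                 pattern_index = "composite", params = maps[[1]]$params),
            class = "sr_map")
}

#' Write / read a super-resolved map as 32-bit TIFF with YAML sidecar
#' @param map an `sr_map`.
#' @param path output TIFF path.
#' @export
write_sr_map <- function(map, path) {
  tiff::writeTIFF(pmin(pmax(map$grid, 0), 1), path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size = map$pixel_size,
                        pattern_index = as.character(map$pattern_index),
                        ring_radius = map$params$ring_radius,
                        magnification = map$params$magnification,
                        ring_axes = map$params$ring_axes,
                        temporal_mode = map$params$temporal_mode),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Conventional ULM reconstruction (localization + tracking baseline)
#'
#' Minimal localization-microscopy comparator: per-frame local maxima above a
#' threshold are refined to sub-pixel positions by intensity-weighted
#' centroids, linked frame-to-frame by greedy nearest-neighbour association
#' within `linking_radius`, and short tracks are discarded. Density and mean
#' speed maps are accumulated on the magnified grid. This baseline is
#' deliberately simple; its failure under overlapping microbubbles is the
#' regime the pattern-based pipeline is designed to avoid.
#'
#' @param seq a [ceus_sequence()].
#' @param detect_threshold absolute intensity threshold for local maxima;
#'   default is the 98% quantile of positive intensities.
#' @param linking_radius maximum per-frame displacement, pixels.
#' @param min_track_len minimum number of frames per retained track.
#' @param magnification output grid magnification.
#' @param window half-width of the centroid window, pixels.
#' @return list with `tracks` (data frame `track_id, frame, x_mm, z_mm`),
#'   `track_speeds` (mm/s per track), `density` and `speed` maps.
#' @export
ulm_reconstruct <- function(seq, detect_threshold = NULL, linking_radius = 2,
                            min_track_len = 5, magnification = 3, window = 2) {
  stopifnot(inherits(seq, "ceus_sequence"))
  d <- dim(seq$frames)
  if (is.null(detect_threshold)) {
    pos <- seq$frames[seq$frames > 0]
    detect_threshold <- if (length(pos))
      stats::quantile(pos, 0.98, names = FALSE) else Inf
  }
  detections <- lapply(seq_len(d[1]), function(t)
    localize_frame(seq$frames[t, , ], detect_threshold, window))

  # greedy nearest-neighbour linking
  tracks <- list()          # finished
  active <- list()          # each: list(points = matrix(z, x), frames)
  for (t in seq_len(d[1])) {
    det <- detections[[t]]
    used <- rep(FALSE, nrow(det))
    keep <- logical(length(active))
    if (length(active) && nrow(det)) {
      heads <- t(vapply(active, function(a) a$points[nrow(a$points), ],
                        numeric(2)))
      dm <- outer(heads[, 1], det[, 1], "-")^2 + outer(heads[, 2], det[, 2], "-")^2
      repeat {
        m <- which.min(dm)
        if (!length(m) || !is.finite(dm[m]) || dm[m] > linking_radius^2) break
        ai <- (m - 1) %% nrow(dm) + 1
        di <- (m - 1) %/% nrow(dm) + 1
        active[[ai]]$points <- rbind(active[[ai]]$points, det[di, ])
        active[[ai]]$frames <- c(active[[ai]]$frames, t)
        keep[ai] <- TRUE; used[di] <- TRUE
        dm[ai, ] <- Inf; dm[, di] <- Inf
      }
    }
    tracks <- c(tracks, active[!keep])
    active <- active[keep]
    for (i in which(!used))
      active[[length(active) + 1]] <- list(points = det[i, , drop = FALSE],
                                           frames = t)
  }
  tracks <- c(tracks, active)
  tracks <- Filter(function(a) length(a$frames) >= min_track_len, tracks)

  px <- seq$pixel_size; fr <- seq$frame_rate
  mz <- d[2] * magnification; mx <- d[3] * magnification
  density <- matrix(0, mz, mx); speed_acc <- matrix(0, mz, mx)
  rows <- list(); speeds <- numeric(length(tracks))
  for (i in seq_along(tracks)) {
    p <- tracks[[i]]$points
    step <- sqrt(rowSums(diff(p)^2))
    speeds[i] <- mean(step) * px * fr
    rows[[i]] <- data.frame(track_id = i, frame = tracks[[i]]$frames,
                            x_mm = (p[, 2] + 0.5) * px, z_mm = (p[, 1] + 0.5) * px)
    iz <- pmin(pmax(floor((p[, 1] + 0.5) * magnification) + 1, 1), mz)
    ix <- pmin(pmax(floor((p[, 2] + 0.5) * magnification) + 1, 1), mx)
    for (j in seq_along(iz)) {
      density[iz[j], ix[j]] <- density[iz[j], ix[j]] + 1
      speed_acc[iz[j], ix[j]] <- speed_acc[iz[j], ix[j]] + speeds[i]
    }
  }
  speed_map <- ifelse(density > 0, speed_acc / pmax(density, 1), 0)
  tracks_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(),
               x_mm = numeric(), z_mm = numeric())
  list(tracks = tracks_df, track_speeds = speeds,
       density = density, speed = speed_map)
}

# local maxima above threshold, refined by intensity-weighted centroid;
# returns matrix with columns (z, x) in continuous pixel-centre coordinates
localize_frame <- function(frame, threshold, window) {
  nz <- nrow(frame); nx <- ncol(frame)
  if (nz < 3 || nx < 3) return(matrix(numeric(), 0, 2))
  core <- frame[2:(nz - 1), 2:(nx - 1)]
  is_max <- core > threshold
  # strict on one half-plane, non-strict on the other, so a plateau from an
  # exactly half-pixel-centred blob yields a single detection
  for (o in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
    is_max <- is_max & core > frame[2:(nz - 1) + o[1], 2:(nx - 1) + o[2]]
  }
  for (o in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    is_max <- is_max & core >= frame[2:(nz - 1) + o[1], 2:(nx - 1) + o[2]]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(), 0, 2))
  out <- matrix(0, nrow(idx), 2)
  for (i in seq_len(nrow(idx))) {
    z0 <- idx[i, 1] + 1; x0 <- idx[i, 2] + 1
    zi <- max(1, z0 - window):min(nz, z0 + window)
    xi <- max(1, x0 - window):min(nx, x0 + window)
    w <- frame[zi, xi]
    w <- pmax(w, 0)
    s <- sum(w)
    out[i, ] <- c(sum(zi * rowSums(w)), sum(xi * colSums(w))) / s - 1
  }
  out
}
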