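#' Streamline specification for the synthetic microbubble phantom
#'
#' A streamline is a polyline in the imaging plane along which microbubbles
#' (MBs) are advected at constant speed. Together with [acquisition_spec()]
#' it defines a ground-truth flow phantom emulating the chaotic, overlapping
#' MB trails of tumor microcirculation at a desk scale.
#'
#' @param control_points numeric matrix with columns `(x, z)` in mm, at least
#'   two rows; the centerline polyline.
#' @param speed advection speed along the path, mm/s (> 0).
#' @param direction_sign `+1` to traverse the polyline as given, `-1` reversed.
#' @param mb_rate expected MB entries per second (Poisson arrivals, >= 0).
#' @param lumen_sigma lateral jitter of MB paths around the centerline, mm.
#'   Each MB gets one constant perpendicular offset, so its speed is exactly
#'   `speed` regardless of jitter.
#' @return object of class `streamline_spec`.
#' @export
streamline_spec <- function(control_points, speed, direction_sign = 1,
                            mb_rate = 20, lumen_sigma = 0) {
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 2, nrow(control_points) >= 2,
            is.numeric(speed), speed > 0, mb_rate >= 0, lumen_sigma >= 0,
            direction_sign %in% c(-1, 1))
  structure(list(control_points = control_points, speed = speed,
                 direction_sign = direction_sign, mb_rate = mb_rate,
                 lumen_sigma = lumen_sigma),
            class = "streamline_spec")
}

#' Acquisition specification for the synthetic simulator
#'
#' Defaults reproduce the nominal acquisition used throughout: 1,500 frames
#' at 500 Hz on a 128 x 128 grid of 50 um pixels, a 100 um Gaussian PSF
#' stand-in, rank-2 multiplicatively strong tissue clutter and mild additive
#' noise.
#'
#' @param frame_rate frames per second (Hz).
#' @param n_frames number of frames (>= 2).
#' @param n_z,n_x grid size in pixels.
#' @param pixel_size pixel pitch in mm (isotropic).
#' @param psf_sigma Gaussian PSF standard deviation in mm.
#' @param noise_sigma additive Gaussian noise sd, relative to the mean
#'   intensity of the clean sequence.
#' @param clutter_rank number of low-rank tissue-clutter components (>= 0);
#'   the Casorati rank of the added clutter equals this exactly.
#' @param clutter_amplitude clutter scale relative to the peak MB intensity.
#' @param rng_seed integer seed making the whole simulation reproducible.
#' @export
acquisition_spec <- function(frame_rate = 500, n_frames = 1500,
                             n_z = 128, n_x = 128, pixel_size = 0.05,
                             psf_sigma = 0.1, noise_sigma = 0.1,
                             clutter_rank = 2, clutter_amplitude = 10,
                             rng_seed = 1L) {
  stopifnot(frame_rate > 0, n_frames >= 2, n_z >= 4, n_x >= 4,
            pixel_size > 0, psf_sigma > 0, noise_sigma >= 0,
            clutter_rank >= 0, clutter_amplitude >= 0)
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 n_z = as.integer(n_z), n_x = as.integer(n_x),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma,
                 clutter_rank = as.integer(clutter_rank),
                 clutter_amplitude = clutter_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_spec")
}

# cumulative arc length and interpolation helpers for a polyline
polyline_geometry <- function(pts) {
  d <- diff(pts)
  seg_len <- sqrt(rowSums(d^2))
  if (any(seg_len == 0)) {
    keep <- c(TRUE, seg_len > 0)
    pts <- pts[keep, , drop = FALSE]
    d <- diff(pts); seg_len <- sqrt(rowSums(d^2))
  }
  list(pts = pts, seg_len = seg_len, cum = c(0, cumsum(seg_len)),
       total = sum(seg_len),
       tangents = d / seg_len)
}

# position and unit tangent at arc length s (vectorized over s)
polyline_at <- function(geom, s) {
  i <- findInterval(s, geom$cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(geom$seg_len))
  rem <- s - geom$cum[i]   # arc length into segment i
  pos <- geom$pts[i, , drop = FALSE] + geom$tangents[i, , drop = FALSE] * rem
  list(pos = pos, tan = geom$tangents[i, , drop = FALSE])
}

#' Sample microbubble trajectories along one streamline
#'
#' MB entries follow a Poisson process with rate `spec$mb_rate` over the
#' acquisition duration; each MB advances along the polyline at
#' `spec$speed` and disappears at the path end. Frame `t` is timestamped
#' `(t - 1) / frame_rate`.
#'
#' @param spec a [streamline_spec()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list of per-MB data frames with columns
#'   `t_index, x, z, vx, vz` (mm and mm/s).
#' @export
sample_streamline <- function(spec, acq, seed = acq$rng_seed) {
  pts <- spec$control_points
  if (spec$direction_sign < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  ext_x <- acq$n_x * acq$pixel_size
  ext_z <- acq$n_z * acq$pixel_size
  if (any(pts[, 1] < 0 | pts[, 1] > ext_x | pts[, 2] < 0 | pts[, 2] > ext_z))
    stop("streamline control points fall outside the field of view")
  geom <- polyline_geometry(pts)
  duration <- acq$n_frames / acq$frame_rate
  traj <- withr::with_seed(seed, {
    n_mb <- stats::rpois(1, spec$mb_rate * duration)
    if (n_mb == 0) {
      list()
    } else {
      entry <- sort(stats::runif(n_mb, 0, duration))
      offset <- if (spec$lumen_sigma > 0)
        stats::rnorm(n_mb, 0, spec$lumen_sigma) else numeric(n_mb)
      frame_time <- (seq_len(acq$n_frames) - 1) / acq$frame_rate
      lapply(seq_len(n_mb), function(m) {
        s <- spec$speed * (frame_time - entry[m])
        live <- s >= 0 & s <= geom$total
        if (!any(live)) return(NULL)
        at <- polyline_at(geom, s[live])
        normal <- cbind(-at$tan[, 2], at$tan[, 1])   # left-hand normal
        pos <- at$pos + normal * offset[m]
        data.frame(t_index = which(live),
                   x = pos[, 1], z = pos[, 2],
                   vx = spec$speed * at$tan[, 1],
                   vz = spec$speed * at$tan[, 2])
      })
    }
  })
  Filter(Negate(is.null), traj)
}

#' Render microbubble trajectories into a CEUS sequence
#'
#' Each MB sample becomes a Gaussian blob of `acq$psf_sigma` (unit amplitude
#' by default, optional per-MB log-normal variation); frames are sums of
#' blobs. No clutter or noise is added here -- see [add_clutter_and_noise()].
#'
#' @param trajectories list of trajectory lists as returned by
#'   [sample_streamline()]; one element per streamline.
#' @param acq an [acquisition_spec()].
#' @param amp_sdlog sd of per-MB log-normal amplitude variation (0 = off).
#' @param seed seed used only when `amp_sdlog > 0`.
#' @param centerlines optional list of streamline control-point matrices used
#'   to rasterize ground-truth centerline masks (defaults to none).
#' @param centerline_radius dilation radius for the masks, mm.
#' @return list with `seq` (a [ceus_sequence()]) and `truth` (events data
#'   frame with `t_index, x, z, vx, vz, streamline, mb_id`, plus
#'   `centerline_masks`).
#' @export
render_sequence <- function(trajectories, acq, amp_sdlog = 0,
                            seed = acq$rng_seed, centerlines = NULL,
                            centerline_radius = NULL) {
  if (acq$psf_sigma < acq$pixel_size / 4)
    warning("psf_sigma < pixel_size/4: PSF undersampled on this grid")
  # accept either one streamline's trajectory list (elements are data frames)
  # or a list of such lists, one per streamline
  if (any(vapply(trajectories, is.data.frame, logical(1))))
    trajectories <- list(trajectories)
  ev <- list(); k <- 0
  for (s in seq_along(trajectories)) {
    for (traj in trajectories[[s]]) {
      k <- k + 1
      traj$streamline <- s
      traj$mb_id <- k
      ev[[length(ev) + 1]] <- traj
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(t_index = integer(), x = numeric(), z = numeric(),
               vx = numeric(), vz = numeric(),
               streamline = integer(), mb_id = integer())
  ext_x <- acq$n_x * acq$pixel_size; ext_z <- acq$n_z * acq$pixel_size
  inside <- events$x >= 0 & events$x <= ext_x & events$z >= 0 & events$z <= ext_z
  events <- events[inside, , drop = FALSE]

  amps <- rep(1, nrow(events))
  if (amp_sdlog > 0 && nrow(events)) {
    mb <- unique(events$mb_id)
    a <- withr::with_seed(seed, stats::rlnorm(length(mb), 0, amp_sdlog))
    amps <- a[match(events$mb_id, mb)]
  }
  dims <- c(acq$n_frames, acq$n_z, acq$n_x)
  frames <- .stamp_gaussians_cpp(
    as.integer(dims), as.integer(events$t_index),
    events$z / acq$pixel_size - 0.5, events$x / acq$pixel_size - 0.5,
    amps, acq$psf_sigma / acq$pixel_size)
  dim(frames) <- dims

  masks <- NULL
  if (!is.null(centerlines)) {
    r <- if (is.null(centerline_radius)) acq$pixel_size else centerline_radius
    masks <- lapply(centerlines, centerline_mask, acq = acq, radius = r)
  }
  list(seq = ceus_sequence(frames, acq$pixel_size, acq$frame_rate, nonneg = TRUE),
       truth = list(events = events, streamline_labels = events$streamline,
                    centerline_masks = masks))
}

#' Binary mask of pixels within `radius` of a polyline centerline
#' @param centerline matrix of `(x, z)` control points, mm.
#' @param acq an [acquisition_spec()].
#' @param radius distance threshold in mm.
#' @export
centerline_mask <- function(centerline, acq, radius = acq$pixel_size) {
  geom <- polyline_geometry(as.matrix(centerline))
  s <- seq(0, geom$total, by = acq$pixel_size / 4)
  pts <- polyline_at(geom, s)$pos
  xc <- (seq_len(acq$n_x) - 0.5) * acq$pixel_size
  zc <- (seq_len(acq$n_z) - 0.5) * acq$pixel_size
  m <- matrix(FALSE, acq$n_z, acq$n_x)
  for (i in seq_len(nrow(pts))) {
    dz2 <- (zc - pts[i, 2])^2
    dx2 <- (xc - pts[i, 1])^2
    m <- m | outer(dz2, dx2, "+") <= radius^2
  }
  m
}

#' Add low-rank tissue clutter and additive noise
#'
#' Clutter is a sum of `clutter_rank` rank-1 components: a smooth positive
#' random spatial field times a slow sinusoidal temporal envelope, so the
#' Casorati rank of the added clutter is exactly `clutter_rank`. Noise is
#' i.i.d. Gaussian with sd `noise_sigma * mean(input intensity)`.
#'
#' @param seq clean [ceus_sequence()] from [render_sequence()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed.
#' @return corrupted [ceus_sequence()] (signed: noise may dip below zero
#'   where the signal is dark).
#' @export
add_clutter_and_noise <- function(seq, acq, seed = acq$rng_seed + 1L) {
  if (acq$clutter_rank == 0 && acq$noise_sigma == 0) return(seq)
  d <- dim(seq$frames)
  frames <- seq$frames
  peak <- max(frames)
  scale0 <- if (peak > 0) peak else 1
  withr::with_seed(seed, {
    if (acq$clutter_rank > 0) {
      tt <- (seq_len(d[1]) - 1) / acq$frame_rate
      for (k in seq_len(acq$clutter_rank)) {
        coarse <- matrix(stats::runif(64, 0.3, 1), 8, 8)
        sp <- bilinear_upsample(coarse, d[2], d[3])
        f <- stats::runif(1, 0.2, 2)
        ph <- stats::runif(1, 0, 2 * pi)
        env <- 0.5 + 0.5 * sin(2 * pi * f * tt + ph)
        comp <- acq$clutter_amplitude * scale0 *
          outer(env, as.vector(sp))
        dim(comp) <- d
        frames <- frames + comp
      }
    }
    if (acq$noise_sigma > 0) {
      sd <- acq$noise_sigma * mean(seq$frames)
      if (sd > 0)
        frames <- frames + array(stats::rnorm(prod(d), 0, sd), dim = d)
    }
  })
  ceus_sequence(frames, seq$pixel_size, seq$frame_rate, roi_mask = seq$roi_mask)
}

bilinear_upsample <- function(m, nz, nx) {
  zi <- seq(1, nrow(m), length.out = nz)
  xi <- seq(1, ncol(m), length.out = nx)
  z0 <- pmin(floor(zi), nrow(m) - 1); fz <- zi - z0
  x0 <- pmin(floor(xi), ncol(m) - 1); fx <- xi - x0
  out <- matrix(0, nz, nx)
  for (j in seq_len(nx)) {
    c0 <- m[, x0[j]] * (1 - fx[j]) + m[, x0[j] + 1] * fx[j]
    out[, j] <- c0[z0] * (1 - fz) + c0[z0 + 1] * fz
  }
  out
}

#' One-call synthetic CEUS acquisition
#'
#' Convenience wrapper: samples MB trajectories for every streamline,
#' renders the clean sequence, and corrupts it with clutter and noise.
#'
#' @param streamlines list of [streamline_spec()].
#' @param acq an [acquisition_spec()].
#' @param seed master seed; per-streamline seeds are derived from it.
#' @return list with `seq` (corrupted), `clean` (pre-clutter), and `truth`.
#' @export
simulate_ceus <- function(streamlines, acq, seed = acq$rng_seed) {
  trajs <- lapply(seq_along(streamlines), function(i)
    sample_streamline(streamlines[[i]], acq, seed = seed + 101L * i))
  rend <- render_sequence(trajs, acq,
                          centerlines = lapply(streamlines, function(s) {
                            p <- s$control_points
                            if (s$direction_sign < 0) p[rev(seq_len(nrow(p))), ] else p
                          }))
  noisy <- add_clutter_and_noise(rend$seq, acq, seed = seed + 7919L)
  list(seq = noisy, clean = rend$seq, truth = rend$truth)
}
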