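# shared phantom builders and a per-session cache so expensive simulations
# are computed once across test files

.parm_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.parm_test_cache[[key]])) .parm_test_cache[[key]] <- expr
  .parm_test_cache[[key]]
}

small_acq <- function(n_frames = 300, n_z = 64, n_x = 64, seed = 7, ...) {
  acquisition_spec(frame_rate = 500, n_frames = n_frames, n_z = n_z,
                   n_x = n_x, pixel_size = 0.05, psf_sigma = 0.1,
                   rng_seed = seed, ...)
}

# horizontal streamline at depth z_frac (fraction of the field height)
hline <- function(acq, z_frac, speed, sign = 1, rate = 15, lumen = 0) {
  w <- acq$n_x * acq$pixel_size
  h <- acq$n_z * acq$pixel_size
  streamline_spec(rbind(c(0.1, z_frac * h), c(w - 0.1, z_frac * h)),
                  speed = speed, direction_sign = sign, mb_rate = rate,
                  lumen_sigma = lumen)
}

vline <- function(acq, x_frac, speed, sign = 1, rate = 15) {
  w <- acq$n_x * acq$pixel_size
  h <- acq$n_z * acq$pixel_size
  streamline_spec(rbind(c(x_frac * w, 0.1), c(x_frac * w, h - 0.1)),
                  speed = speed, direction_sign = sign, mb_rate = rate)
}

# noise- and clutter-free single-streamline acquisition (velocimetry oracle)
clean_single_sim <- function(speed, n_frames = 300, seed = 3, rate = 15) {
  acq <- small_acq(n_frames = n_frames, seed = seed,
                   noise_sigma = 0, clutter_rank = 0)
  sim <- simulate_ceus(list(hline(acq, 0.5, speed, rate = rate)), acq,
                       seed = seed)
  list(acq = acq, sim = sim)
}

# dilute two-vessel phantom: sparse trails, no clutter, so pattern labels
# have near-perfect spatial purity (used for split/composite identities)
dilute_phantom <- function() {
  cached("dilute_two", {
    acq <- small_acq(n_frames = 500, n_z = 96, n_x = 96, seed = 7,
                     clutter_rank = 0)
    sls <- list(hline(acq, 0.3, 2, rate = 8),
                hline(acq, 0.6, 8, sign = -1, rate = 8))
    sim <- simulate_ceus(sls, acq, seed = 7)
    fp <- points_from_seq(sim$seq)
    model <- adaptive_kmeans(build_feature_space(fp$points), k_max = 10,
                             seed = 7)
    list(acq = acq, streamlines = sls, stack = fp$stack, points = fp$points,
         model = model)
  })
}

# isolated Gaussian blob frame on the (z, x) grid, centre in 0-based px coords
gauss_frame <- function(nz, nx, zc, xc, sig = 2, amp = 1) {
  amp * exp(-(outer(((1:nz) - 0.5 - zc)^2, ((1:nx) - 0.5 - xc)^2, "+")) /
              (2 * sig^2))
}

# hand-built pattern model for metric tests
fake_model <- function(centers, occupancy) {
  structure(list(K = nrow(centers), centers = centers,
                 labels = rep(seq_len(nrow(centers)), occupancy),
                 occupancy = occupancy, selection_scores = NA,
                 normalization = NULL, seed = 1L),
            class = "pattern_model")
}

# number of 26-connected components of a 3D logical array (oracle-style BFS)
n_components3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  remaining <- rep(TRUE, prod(d))
  remaining[-idx] <- FALSE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    queue <- which(remaining)[1]
    remaining[queue] <- FALSE
    while (length(queue)) {
      cur <- arrayInd(queue, d)
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        nb <- sweep(cur, 2, offs[i, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
        lin <- lin[remaining[lin]]
        remaining[lin] <- FALSE
        nxt <- c(nxt, lin)
      }
      queue <- unique(nxt)
    }
  }
  comp
}

# full feature pipeline on a filtered sequence
points_from_seq <- function(seq, detect_quantile = 0.95, min_coherence = 0.5) {
  st <- build_stack(seq, detect_quantile = detect_quantile)
  o <- tensor_orientation(st)
  list(stack = st,
       points = extract_feature_points(st, o, min_coherence = min_coherence))
}

# two/three-streamline study phantoms (distinct speed and direction),
# SVD-filtered with the fixed clutter cutoff; moderate desk scale
study_phantom <- function(n_streams, n_frames = 500, n_px = 96, seed = 7) {
  cached(sprintf("study_%d_%d_%d_%d", n_streams, n_frames, n_px, seed), {
    acq <- small_acq(n_frames = n_frames, n_z = n_px, n_x = n_px, seed = seed,
                     clutter_rank = 2)
    sls <- list(hline(acq, 0.3, 2, rate = 20),
                hline(acq, 0.6, 8, sign = -1, rate = 20),
                vline(acq, 0.5, 5, rate = 20))[seq_len(n_streams)]
    sim <- simulate_ceus(sls, acq, seed = seed)
    filt <- svd_filter(sim$seq, cutoff = 2)
    fp <- points_from_seq(filt)
    feats <- build_feature_space(fp$points)
    model <- adaptive_kmeans(feats, k_max = 10, seed = seed)
    list(acq = acq, streamlines = sls, sim = sim, filt = filt,
         stack = fp$stack, points = fp$points, feats = feats, model = model)
  })
}
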