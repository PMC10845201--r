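test_that("radiality localizes an isolated blob and sharpens the PSF", {
  zc <- 31.8; xc <- 30.2; sig <- 2
  f <- gauss_frame(64, 64, zc, xc, sig)
  # ring radius matched to the PSF flank (of the order of the PSF FWHM / 2)
  pr <- srrf_params(ring_radius = 3, magnification = 3, ring_axes = 8)
  r <- radiality_frame(f, pr)

  # default reconstruction settings
  d <- srrf_params()
  expect_equal(c(d$ring_radius, d$magnification, d$ring_axes), c(8, 3, 8))
  expect_equal(d$temporal_mode, "mean")

  # peak within 1 magnified pixel of the true center
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[1] - (zc * 3 + 0.5)), 1)
  expect_lt(abs(pk[2] - (xc * 3 + 0.5)), 1)

  # FWHM of the radiality peak is below the input FWHM
  prof_r <- r[, pk[2]] / max(r)
  fwhm_r <- sum(prof_r >= 0.5)
  prof_i <- f[, round(xc + 0.5)] / max(f)
  fwhm_i <- sum(prof_i >= 0.5) * 3      # input FWHM in magnified px
  expect_lt(fwhm_r, fwhm_i)

  # flat frame maps to zero
  expect_true(all(radiality_frame(matrix(4, 32, 32), pr) == 0))
})

test_that("radiality is offset-invariant and rotation-equivariant", {
  f <- gauss_frame(48, 48, 22.6, 27.1, 2) + gauss_frame(48, 48, 35, 12, 3)
  pr <- srrf_params(ring_radius = 3)
  r <- radiality_frame(f, pr)
  expect_equal(radiality_frame(f + 5, pr), r, tolerance = 1e-6)
  rot <- function(m) t(m[nrow(m):1, ])
  expect_equal(radiality_frame(rot(f), pr), rot(r), tolerance = 1e-6)
})

test_that("temporal aggregation and empty input behave as documented", {
  f <- gauss_frame(40, 40, 20.2, 19.7, 2)
  frames <- aperm(array(f, c(40, 40, 6)), c(3, 1, 2))
  seqc <- ceus_sequence(frames, 0.05, 500)
  pr <- srrf_params(ring_radius = 3)
  m <- srrf_reconstruct(seqc, pr)
  r1 <- radiality_frame(f, pr)
  expect_equal(m$grid, r1 / max(r1), tolerance = 1e-10)
  expect_equal(m$pixel_size, 0.05 / 3)

  z <- ceus_sequence(array(0, c(5, 40, 40)), 0.05, 500)
  expect_warning(mz <- srrf_reconstruct(z, pr), "zero")
  expect_true(all(mz$grid == 0))
})

test_that("SRRF centerline tracks a straight simulated vessel within 1 magnified pixel", {
  cs <- cached("clean_0.5", clean_single_sim(0.5 * 25, seed = 3))
  map <- srrf_reconstruct(cs$sim$seq, srrf_params(ring_radius = 3))
  true_z_mag <- 0.5 * cs$acq$n_z * cs$acq$pixel_size / map$pixel_size  # mag px
  g <- map$grid
  g[g < 0.3 * max(g)] <- 0   # centroid of the dominant ridge only
  # ridge position per column (intensity-weighted centroid over bright cols)
  col_ok <- which(apply(g, 2, max) > 0)
  ridge <- vapply(col_ok, function(j) sum(seq_len(nrow(g)) * g[, j]) /
                    sum(g[, j]), numeric(1))
  rms <- sqrt(mean((ridge - 0.5 - (true_z_mag - 0.5))^2))
  expect_lte(rms, 1)

  # composite of spatially disjoint per-pattern maps equals the unsplit map
  # (raw radiality units -- per-map normalization would rescale vessels --
  # on the dilute phantom, where the pattern supports are cleanly disjoint)
  dl <- dilute_phantom()
  subs <- split_sequence(dl$stack, dl$points, dl$model)
  maps <- lapply(subs, srrf_reconstruct, params = srrf_params(ring_radius = 3),
                 normalize = FALSE)
  whole_arr <- array(0, dim(dl$stack$voxels))
  whole_arr[dl$points$voxel] <- dl$stack$voxels[dl$points$voxel]
  whole <- srrf_reconstruct(ceus_sequence(whole_arr, dl$acq$pixel_size,
                                          dl$acq$frame_rate),
                            srrf_params(ring_radius = 3), normalize = FALSE)
  comp <- composite_map(maps)
  sel <- whole$grid > 0.1 * max(whole$grid)
  expect_gt(stats::cor(comp$grid[sel], whole$grid[sel]), 0.95)
})

test_that("the ULM baseline tracks isolated MBs and fails on overlap", {
  acq <- small_acq(n_frames = 200, seed = 3, noise_sigma = 0,
                   clutter_rank = 0)
  sim <- simulate_ceus(list(hline(acq, 0.5, 10, rate = 3)), acq, seed = 31)
  u <- ulm_reconstruct(sim$seq, min_track_len = 10)
  expect_gte(length(u$track_speeds), 1)
  expect_lt(min(abs(u$track_speeds - 10)) / 10, 0.1)

  # min_track_len beyond the movie -> no tracks
  u0 <- ulm_reconstruct(sim$seq, min_track_len = 10000)
  expect_equal(nrow(u0$tracks), 0)

  # two MBs crossing within the PSF: localization error at crossing frames
  # exceeds the isolated-MB error (the failure mode pattern splitting avoids)
  nt <- 41
  zc <- 12
  xa <- 10 + 0.5 * (0:(nt - 1))   # rightward
  xb <- 30 - 0.5 * (0:(nt - 1))   # leftward, crosses at frame ~21
  mk <- function(xs) {
    arr <- array(0, c(nt, 24, 48))
    for (t in 1:nt) arr[t, , ] <- gauss_frame(24, 48, zc, xs[t], 2)
    arr
  }
  both <- ceus_sequence(mk(xa) + mk(xb), 0.05, 500)
  alone <- ceus_sequence(mk(xa), 0.05, 500)
  err_at <- function(seqq, frame_sel) {
    det <- parm:::localize_frame(seqq$frames[frame_sel, , ], 0.2, 2)
    if (!nrow(det)) return(Inf)
    min(sqrt((det[, 1] + 0.5 - zc)^2 + (det[, 2] + 0.5 - xa[frame_sel])^2))
  }
  # frame 18: blobs overlap within the PSF but are not coincident, so the
  # merged detection is pulled away from either true position
  e_alone <- err_at(alone, 18)
  e_cross <- err_at(both, 18)
  expect_gt(e_cross, e_alone)
})
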