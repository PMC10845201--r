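test_that("Casorati decomposition is exact and orthonormal", {
  # rank-1 sequence: static image times a temporal envelope
  img <- matrix(stats::runif(24 * 24), 24, 24)
  env <- seq(1, 2, length.out = 40)
  frames <- aperm(outer(img, env), c(3, 1, 2))
  seq1 <- ceus_sequence(frames, 0.05, 500)
  dec <- casorati_svd(seq1)
  expect_equal(sum(dec$singular_values > 1e-9 * dec$singular_values[1]), 1)

  # orthonormality of spatial and temporal component sets
  acq <- small_acq(n_frames = 50, n_z = 24, n_x = 24, seed = 4,
                   clutter_rank = 2)
  sim <- simulate_ceus(list(hline(acq, 0.5, 5)), acq, seed = 4)
  dec2 <- casorati_svd(sim$seq)
  k <- sum(dec2$singular_values > 1e-9 * dec2$singular_values[1])
  expect_lt(max(abs(crossprod(dec2$temporal) - diag(50))), 1e-8)
  expect_lt(max(abs(crossprod(dec2$spatial[, 1:k]) - diag(k))), 1e-8)

  # full reconstruction recovers the input
  rec <- svd_reconstruct(dec2, seq_len(50))
  relerr <- sqrt(sum((rec$frames - sim$seq$frames)^2) / sum(sim$seq$frames^2))
  expect_lt(relerr, 1e-6)

  # an all-zero sequence decomposes without error
  z <- ceus_sequence(array(0, c(10, 8, 8)), 0.05, 500)
  expect_true(all(casorati_svd(z)$singular_values == 0))
})

test_that("SVD filter removes known-rank clutter and is a linear projection", {
  acq <- small_acq(n_frames = 400, seed = 11, clutter_rank = 3)
  sl <- hline(acq, 0.4, 5, rate = 15)
  sim <- cached("svd_clutter3", simulate_ceus(list(sl), acq, seed = 11))
  filt <- svd_filter(sim$seq, cutoff = 3)

  # residual energy in static background regions < 1% of pre-filter energy
  bg <- !centerline_mask(sl$control_points, acq, radius = 0.4)
  e_pre <- e_post <- 0
  for (t in seq_len(400)) {
    e_pre <- e_pre + sum(sim$seq$frames[t, , ][bg]^2)
    e_post <- e_post + sum(filt$frames[t, , ][bg]^2)
  }
  expect_lt(e_post / e_pre, 0.01)

  # identity reconstruction with no cutoff
  id <- svd_filter(sim$seq, cutoff = 0)
  relerr <- sqrt(sum((id$frames - sim$seq$frames)^2) / sum(sim$seq$frames^2))
  expect_lt(relerr, 1e-6)

  # linearity under intensity scaling with fixed cutoffs
  scaled <- sim$seq; scaled$frames <- 3.5 * scaled$frames
  f_scaled <- svd_filter(scaled, cutoff = 3)
  expect_equal(f_scaled$frames, 3.5 * filt$frames, tolerance = 1e-8)

  # cutoff at or past the number of components errors
  expect_error(svd_filter(sim$seq, cutoff = 400), "cutoff")
})

test_that("filtered dilute-MB sequences recover the clutter-free signal", {
  # dilute regime: trails are temporally sparse at every pixel, so little MB
  # energy lies in the slow clutter subspace
  acq <- small_acq(n_frames = 400, seed = 11, clutter_rank = 3)
  sim <- cached("svd_dilute",
                simulate_ceus(list(hline(acq, 0.4, 10, rate = 4)), acq,
                              seed = 11))
  filt <- svd_filter(sim$seq, cutoff = 3)
  expect_gt(stats::cor(as.vector(filt$frames), as.vector(sim$clean$frames)),
            0.95)
})

test_that("adaptive cutoff reports an elbow and contracts pure noise", {
  arr <- array(stats::rnorm(200 * 24 * 24), c(200, 24, 24))
  noise <- ceus_sequence(arr, 0.05, 500)
  filt <- svd_filter(noise, cutoff = "adaptive")
  expect_true(attr(filt, "cutoff") >= 1)
  expect_lt(sum(filt$frames^2), sum(noise$frames^2))
})

test_that("motion screening excludes shifted frames and segments the rest", {
  base <- matrix(stats::runif(48 * 48), 48, 48)
  frames <- array(0, c(100, 48, 48))
  for (t in 1:100) frames[t, , ] <- base + 0.01 * stats::rnorm(48 * 48)
  seq0 <- ceus_sequence(frames, 0.05, 500)

  # identical-statistics frames: no exclusions, one segment
  rep0 <- screen_motion(seq0, threshold = 0.8, min_segment = 10)
  expect_length(rep0$excluded_frames, 0)
  expect_equal(nrow(rep0$segments), 1)
  expect_equal(unname(rep0$segments[1, ]), c(1L, 100L))

  # one frame replaced by a 10-px shifted copy -> exclusions around it,
  # two retained segments
  shifted <- frames
  shifted[50, , ] <- rbind(base[39:48, ], base[1:38, ])
  rep1 <- screen_motion(ceus_sequence(shifted, 0.05, 500),
                        threshold = 0.8, min_segment = 10)
  expect_true(50 %in% rep1$excluded_frames)
  expect_equal(nrow(rep1$segments), 2)
  expect_true(all(rep1$frame_correlations[c(49, 50)] < 0.8))

  # an impossible threshold excludes nothing
  rep2 <- screen_motion(ceus_sequence(shifted, 0.05, 500), threshold = -1,
                        min_segment = 10)
  expect_length(rep2$excluded_frames, 0)

  # constant (zero-variance) frames get correlation 1 by convention
  const <- ceus_sequence(array(2, c(10, 8, 8)), 0.05, 500)
  repc <- screen_motion(const, threshold = 0.9, min_segment = 2)
  expect_true(all(repc$frame_correlations == 1))
})

test_that("segments exactly cover the retained frames on random reports", {
  withr::with_seed(42, {
    for (i in 1:20) {
      nt <- sample(30:120, 1)
      frames <- array(stats::runif(nt * 16 * 16), c(nt, 16, 16))
      # plant a few decorrelated frames
      for (b in sample(2:(nt - 1), sample(1:4, 1)))
        frames[b, , ] <- stats::runif(16 * 16)
      rep <- screen_motion(ceus_sequence(frames, 0.05, 500),
                           threshold = 0.5, min_segment = 5)
      covered <- unlist(apply(rep$segments, 1, function(s) s[1]:s[2],
                              simplify = FALSE))
      expect_setequal(covered, setdiff(seq_len(nt), rep$excluded_frames))
      if (nrow(rep$segments))
        expect_true(all(rep$segments[, 2] - rep$segments[, 1] + 1 >= 5))
      # no segment spans an excluded frame
      for (r in seq_len(nrow(rep$segments)))
        expect_false(any(rep$excluded_frames %in%
                           rep$segments[r, 1]:rep$segments[r, 2]))
    }
  })
})
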