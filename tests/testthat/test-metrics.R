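test_that("heterogeneity parameters follow their definitions", {
  # PD from a 3-4-5 triangle
  m <- fake_model(rbind(c(0, 0, 0), c(3, 4, 0)), c(50, 50))
  h <- heterogeneity(m)
  expect_equal(h$PC, 2)
  expect_equal(h$PD, 5)
  expect_equal(h$ratios, c(0.5, 0.5))
  expect_equal(h$PV, 0)

  # hand-computed sample variance for occupancy (90, 5, 5)
  m3 <- fake_model(diag(3), c(90, 5, 5))
  h3 <- heterogeneity(m3)
  expect_equal(h3$ratios, c(0.9, 0.05, 0.05))
  expect_equal(h3$PV, stats::var(c(0.9, 0.05, 0.05)))
  expect_equal(h3$PV, 0.24083333, tolerance = 1e-7)
  # population-variance variant
  expect_equal(heterogeneity(m3, ddof = 0)$PV, 0.24083333 * 2 / 3,
               tolerance = 1e-7)

  # K = 1 conventions
  h1 <- heterogeneity(fake_model(matrix(c(1, 0, 0), 1), 10))
  expect_equal(c(h1$PD, h1$PV), c(0, 0))
})

test_that("PV is zero iff ratios are equal and maximal at full concentration", {
  # exhaustive ratio grids for K = 2 and K = 3
  pv_of <- function(r) heterogeneity(fake_model(diag(length(r)),
                                                round(r * 1000)))$PV
  g2 <- seq(0.001, 0.999, by = 0.002)
  pv2 <- vapply(g2, function(r) stats::var(c(r, 1 - r)), numeric(1))
  expect_equal(g2[which.max(pv2)], g2[1])            # extreme ratio maximises
  expect_equal(min(pv2), pv2[which.min(abs(g2 - 0.5))])

  step <- 0.02
  g3 <- expand.grid(a = seq(step, 1 - step, step), b = seq(step, 1 - step, step))
  g3 <- g3[g3$a + g3$b < 1, ]
  pv3 <- apply(g3, 1, function(r) stats::var(c(r[1], r[2], 1 - r[1] - r[2])))
  corner <- which.max(pv3)
  expect_gte(max(g3[corner, ]), 1 - 2 * step)        # maximum sits at a corner
  eq <- which.min((g3$a - 1 / 3)^2 + (g3$b - 1 / 3)^2)
  expect_lt(pv3[eq], 5e-4)   # grid point nearest the exact equal split
  expect_equal(stats::var(c(1, 1, 1) / 3), 0)

  # PD is invariant under relabeling and isometries of the feature space
  cen <- rbind(c(0.2, 1, 0), c(0.9, -1, 0), c(0.5, 0, 1))
  m <- fake_model(cen, c(10, 20, 30))
  pd0 <- heterogeneity(m)$PD
  perm <- fake_model(cen[c(3, 1, 2), ], c(30, 10, 20))
  expect_equal(heterogeneity(perm)$PD, pd0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  iso <- fake_model(cen %*% R + 2.5, c(10, 20, 30))
  expect_equal(heterogeneity(iso)$PD, pd0, tolerance = 1e-12)
})

test_that("vessel graphs count branches and junctions like a pixel-graph oracle", {
  # straight vessel: one branch, no nodes, VT exactly 1
  m <- matrix(FALSE, 32, 64); m[16, 5:60] <- TRUE
  s <- structural_metrics(vessel_graph_from_skeleton(m))
  expect_equal(c(s$VN, s$NN, s$VT), c(1, 0, 1))

  # Y phantom: one junction, three branches
  y <- matrix(FALSE, 64, 64)
  y[32, 6:31] <- TRUE
  for (i in 0:25) { y[32 - i, 31 + i] <- TRUE; y[32 + i, 31 + i] <- TRUE }
  gy <- vessel_graph_from_skeleton(y)
  expect_equal(gy$n_nodes, 1)
  expect_equal(nrow(gy$branches), 3)

  # X phantom: brute-force connectivity oracle on the drawn skeleton
  x <- matrix(FALSE, 64, 64)
  for (i in -25:25) { x[32 + i, 32 + i] <- TRUE; x[32 - i, 32 + i] <- TRUE }
  gx <- vessel_graph_from_skeleton(x)
  expect_equal(gx$n_nodes, 1)
  expect_equal(nrow(gx$branches), 4)
  # oracle: remove the crossing pixel, count 8-connected components
  x2 <- x; x2[32, 32] <- FALSE
  expect_equal(nrow(gx$branches), n_components3d(array(x2, c(1, 64, 64))))

  # full-frame vessel mask: VD = 1
  full <- matrix(TRUE, 16, 16)
  gf <- vessel_graph_from_skeleton(skeletonize_mask(full),
                                   binary_mask = full)
  expect_equal(structural_metrics(gf)$VD, 1)

  # empty map: all counts zero
  ge <- build_vessel_graph(matrix(0, 32, 32))
  se <- structural_metrics(ge)
  expect_equal(c(se$VD, se$VN, se$NN, se$VT), c(0, 0, 0, 1))
})

test_that("tortuosity of a semicircular arc approaches pi/2", {
  r <- 40
  m <- matrix(FALSE, 120, 120)
  th <- seq(0, pi, length.out = 2000)
  m[cbind(round(60 + r * sin(th)), round(60 + r * cos(th)))] <- TRUE
  g <- vessel_graph_from_skeleton(skeletonize_mask(m))
  s <- structural_metrics(g)
  expect_equal(s$VN, 1)
  expect_lt(abs(s$VT - pi / 2) / (pi / 2), 0.05)
})

test_that("structural metrics are consistent under ROI cropping", {
  y <- matrix(FALSE, 64, 64)
  y[20, 5:40] <- TRUE; y[40, 5:40] <- TRUE
  g_full <- vessel_graph_from_skeleton(y, pixel_size = 0.02)
  s_full <- structural_metrics(g_full)
  # crop to the top half: only the first vessel remains
  crop <- y[1:32, ]
  g_crop <- vessel_graph_from_skeleton(crop, pixel_size = 0.02)
  s_crop <- structural_metrics(g_crop)
  expect_equal(s_crop$VN, 1)
  expect_equal(s_full$VN, 2)
  # density doubles when the ROI halves around the same vessel
  expect_equal(s_crop$VD, sum(y[1:32, ]) / (32 * 64))
  expect_equal(s_crop$VNP, 1 / (32 * 64))
  expect_equal(s_full$VNP, 2 / (64 * 64))
})

test_that("functional metrics: mean speed, entropy, circular variance", {
  mkp <- function(speed, direction) {
    p <- data.frame(speed = speed, direction = direction)
    class(p) <- c("parm_points", "data.frame")
    p
  }
  # constant speeds: zero entropy
  expect_equal(functional_metrics(mkp(rep(3, 50), rep(0, 50)),
                                  v_max = 10)$SE, 0)
  # exactly uniform over 16 bins: 4 bits
  speeds <- (seq_len(16) - 0.5) / 16 * 10
  f16 <- functional_metrics(mkp(speeds, rep(0, 16)), speed_bins = 16,
                            v_max = 10)
  expect_equal(f16$SE, 4)
  expect_equal(f16$MS, mean(speeds))
  # uniform directions: OV -> 1 within 3 / sqrt(n)
  n <- 4000
  dirs <- seq(-pi + 1e-6, pi, length.out = n)
  expect_lt(abs(functional_metrics(mkp(rep(1, n), dirs), v_max = 2)$OV - 1),
            3 / sqrt(n))
  # single point: SE = 0, OV = 0
  f1 <- functional_metrics(mkp(2, 0.3), v_max = 5)
  expect_equal(c(f1$SE, f1$OV), c(0, 0))
})

test_that("sentinel selection picks the fastest pattern", {
  ph <- study_phantom(2)
  subs <- split_sequence(ph$stack, ph$points, ph$model)
  maps <- lapply(seq_len(ph$model$K), function(k)
    srrf_reconstruct(subs[[k]], srrf_params(ring_radius = 3), k))
  sp <- sentinel_split(ph$model, maps, ph$points)
  mean_speeds <- tapply(ph$points$speed, ph$model$labels, mean)
  expect_equal(sp$sentinel_index, unname(which.max(mean_speeds)))

  # sentinel map concentrates on the fast (8 mm/s) streamline at 0.6 h
  g <- sp$sentinel$grid
  g[g < 0.3 * max(g)] <- 0            # centroid of the dominant ridge
  ridge_z <- sum(row(g) * g) / sum(g) * sp$sentinel$pixel_size
  fast_z <- 0.6 * ph$acq$n_z * ph$acq$pixel_size
  expect_lt(abs(ridge_z - fast_z), 2 * ph$acq$pixel_size)

  # mean speeds {2, 8}: pattern 2 is sentinel; K = 1 leaves non-sentinel empty
  toy <- fake_model(rbind(c(0, 1, 0), c(1, 1, 0)), c(5, 5))
  pts <- data.frame(speed = c(rep(2, 5), rep(8, 5)), direction = 0)
  mp <- list(maps[[1]], maps[[2]])
  sp2 <- sentinel_split(toy, mp, pts)
  expect_equal(sp2$sentinel_index, 2)

  one <- fake_model(matrix(c(0.5, 1, 0), 1), 10)
  sp1 <- sentinel_split(one, maps[1], data.frame(speed = rep(2, 10)))
  expect_true(all(sp1$non_sentinel$grid == 0))
})

test_that("study arithmetic matches the printed formulas", {
  # caliper volume: 6 mm diameter gives ~100 mm^3
  expect_equal(tumor_volume(6, 6), 108)
  expect_error(tumor_volume(3, 5))

  # volume change, printed convention and baseline convention
  expect_equal(delta_v(100, 150), (100 - 150) / 150)
  expect_equal(delta_v(100, 150, convention = "baseline"), 0.5)
  expect_error(delta_v(100, 0))

  # printed longitudinal cross-checks: PD 1.55 -> 2.46 is a ~59% increase,
  # PV 0.55 -> 0.91 a ~65% rise
  expect_equal(relative_change(2.46, 1.55), 0.587, tolerance = 0.005)
  expect_equal(relative_change(0.91, 0.55), 0.655, tolerance = 0.005)
  expect_error(relative_change(1, 0), "baseline")
})

test_that("Spearman correlation matches a brute-force rank oracle", {
  expect_equal(spearman_cor(1:6, c(2, 4, 9, 16, 25, 36)), 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3), -1)
  xs <- c(1, 2, 3, 4, 5); ys <- c(2, 1, 4, 3, 5)
  # oracle: Pearson correlation of average ranks
  rk <- function(v) { r <- rank(v, ties.method = "average"); r }
  oracle <- stats::cor(rk(xs), rk(ys))
  expect_equal(spearman_cor(xs, ys), oracle)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2))
})
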