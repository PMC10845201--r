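#' Build the normalized hemodynamic feature space
#'
#' Each feature point contributes `(speed, cos(direction), sin(direction))`.
#' Speed is min-max normalized to `[0, 1]` so it is commensurate with the
#' circular direction encoding (which avoids the wrap at +/- pi); a constant
#' speed column degenerates to 0.5 with a warning. Optional weights rescale
#' the three columns.
#'
#' @param points a `parm_points` data frame from [extract_feature_points()].
#' @param weights length-3 positive scalars for (speed, cos, sin).
#' @return numeric matrix `n x 3` with attribute `normalization` storing the
#'   min-max transform and weights for inverse mapping.
#' @export
build_feature_space <- function(points, weights = c(1, 1, 1)) {
  stopifnot(nrow(points) >= 1, length(weights) == 3, all(weights > 0))
  smin <- min(points$speed); smax <- max(points$speed)
  if (smax > smin) {
    s <- (points$speed - smin) / (smax - smin)
  } else {
    warning("constant speed column: normalized to 0.5")
    s <- rep(0.5, nrow(points))
  }
  f <- cbind(speed = s, cos_dir = cos(points$direction),
             sin_dir = sin(points$direction))
  f <- sweep(f, 2, weights, "*")
  attr(f, "normalization") <- list(speed_min = smin, speed_max = smax,
                                   weights = weights)
  f
}

# mean silhouette width of a labelled subsample (seeded, at most n_sil points)
silhouette_score <- function(features, labels, n_sil, seed) {
  n <- nrow(features)
  idx <- if (n > n_sil)
    withr::with_seed(seed, sample.int(n, n_sil)) else seq_len(n)
  lab <- labels[idx]
  if (length(unique(lab)) < 2) return(-1)
  sil <- cluster::silhouette(lab, stats::dist(features[idx, , drop = FALSE]))
  mean(sil[, 3])
}

# assign rows to the nearest center (squared Euclidean)
nearest_center <- function(features, centers) {
  d2 <- matrix(0, nrow(features), nrow(centers))
  for (k in seq_len(nrow(centers)))
    d2[, k] <- colSums((t(features) - centers[k, ])^2)
  max.col(-d2, ties.method = "first")
}

#' Adaptive K-means pattern recognition
#'
#' Runs seeded multi-start K-means for each candidate pattern count
#' `K = 2..k_max` and selects the K with the largest mean silhouette width;
#' when even the best silhouette falls below `silhouette_floor` the feature
#' cloud is declared a single pattern (`K = 1`). For large point sets the
#' centers are fit on a seeded subsample and every point is then assigned to
#' its nearest center, so labels cover the full set. Deterministic given
#' `seed`.
#'
#' @param features matrix from [build_feature_space()].
#' @param k_max largest candidate pattern count (>= 2).
#' @param seed integer seed.
#' @param n_fit maximum number of points used to fit the centers.
#' @param n_sil maximum number of points entering the silhouette.
#' @param silhouette_floor mean-silhouette threshold below which `K = 1`.
#' @param nstart number of K-means restarts per candidate K.
#' @return object of class `pattern_model`: `K`, `centers` (K x 3), `labels`
#'   (per point, in `1..K`), `occupancy` counts, `selection_scores` (per
#'   candidate K), `normalization`, `seed`.
#' @export
adaptive_kmeans <- function(features, k_max = 10, seed = 1L, n_fit = 20000,
                            n_sil = 2000, silhouette_floor = 0.35,
                            nstart = 10) {
  if (k_max < 2) stop("k_max must be >= 2")
  n <- nrow(features)
  if (n < k_max + 1) stop("need at least k_max + 1 feature points")
  n_distinct <- nrow(unique(features))
  k_hi <- min(k_max, n_distinct)
  fit_idx <- if (n > n_fit)
    withr::with_seed(seed, sample.int(n, n_fit)) else seq_len(n)
  fit_x <- features[fit_idx, , drop = FALSE]

  scores <- rep(NA_real_, k_hi)
  fits <- vector("list", k_hi)
  if (k_hi >= 2) {
    for (K in 2:k_hi) {
      # some restarts of a multi-start Lloyd run land on empty clusters;
      # kmeans() recovers, so silence that specific warning
      km <- withCallingHandlers(
        withr::with_seed(seed + 1000L * K,
          stats::kmeans(fit_x, centers = K, nstart = nstart, iter.max = 200,
                        algorithm = "Lloyd")),
        warning = function(w) {
          if (grepl("empty cluster", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      fits[[K]] <- km
      scores[K] <- silhouette_score(fit_x, km$cluster, n_sil, seed + 17L * K)
    }
  }
  best <- if (all(is.na(scores))) 1L else which.max(scores)
  if (is.na(scores[best]) || scores[best] < silhouette_floor) best <- 1L

  if (best == 1L) {
    centers <- matrix(colMeans(features), nrow = 1,
                      dimnames = list(NULL, colnames(features)))
    labels <- rep(1L, n)
  } else {
    centers <- fits[[best]]$centers
    labels <- nearest_center(features, centers)
  }
  occupancy <- tabulate(labels, nbins = nrow(centers))
  structure(list(K = nrow(centers), centers = centers, labels = labels,
                 occupancy = occupancy,
                 selection_scores = scores,
                 normalization = attr(features, "normalization"),
                 seed = as.integer(seed)),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("<pattern_model> K = %d patterns over %d feature points\n",
              x$K, sum(x$occupancy)))
  cat("  occupancy:", paste(x$occupancy, collapse = ", "), "\n")
  invisible(x)
}

#' Split a spatio-temporal stack into per-pattern subsequences
#'
#' Pattern `n`'s sequence keeps the original intensities at the feature-point
#' voxels labelled `n` and is zero elsewhere, so the outputs are
#' voxel-disjoint and sum exactly to the input restricted to the labelled
#' support. Empty patterns yield all-zero sequences (kept, so indices stay
#' aligned with the model).
#'
#' @param stack the [build_stack()] result the points came from.
#' @param points the `parm_points` used for clustering (provides voxel
#'   indices).
#' @param model a [adaptive_kmeans()] `pattern_model` (or an integer label
#'   vector aligned with `points`).
#' @return list of `K` [ceus_sequence()] objects covering the stack segment.
#' @export
split_sequence <- function(stack, points, model) {
  labels <- if (inherits(model, "pattern_model")) model$labels else as.integer(model)
  stopifnot(length(labels) == nrow(points))
  K <- max(labels)
  d <- dim(stack$voxels)
  lapply(seq_len(K), function(k) {
    arr <- array(0, dim = d)
    idx <- points$voxel[labels == k]
    arr[idx] <- stack$voxels[idx]
    ceus_sequence(arr, stack$pixel_size, 1 / stack$frame_interval)
  })
}

#' Serialize a pattern model to JSON
#' @param model a `pattern_model`.
#' @param path output path.
#' @export
write_pattern_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, centers = model$centers,
         occupancy = model$occupancy,
         selection_scores = model$selection_scores,
         normalization = model$normalization, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
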