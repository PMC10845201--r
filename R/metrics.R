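#' Heterogeneity parameters of a pattern model
#'
#' Pattern count (PC) is the number of identified patterns K. Pattern
#' distance (PD) is the maximum Euclidean distance between any two cluster
#' centers in the normalized feature space (0 when K = 1 by convention).
#' Each occupancy ratio is `R_n = M_n / sum(M)`; pattern variance (PV) is the
#' variance of the `R_n` (sample variance, divisor K - 1, by default; 0 when
#' K = 1).
#'
#' @param model a [adaptive_kmeans()] `pattern_model`.
#' @param ddof variance divisor offset: 1 = sample variance (default),
#'   0 = population variance.
#' @return object of class `heterogeneity_metrics`: `PC`, `PD`, `PV`,
#'   `ratios`.
#' @export
heterogeneity <- function(model, ddof = 1) {
  stopifnot(inherits(model, "pattern_model"), ddof %in% c(0, 1))
  K <- model$K
  PD <- if (K > 1) max(stats::dist(model$centers)) else 0
  ratios <- model$occupancy / sum(model$occupancy)
  PV <- if (K > 1) {
    v <- stats::var(ratios)                 # divisor K - 1
    if (ddof == 0) v * (K - 1) / K else v
  } else 0
  structure(list(PC = K, PD = PD, PV = PV, ratios = ratios),
            class = "heterogeneity_metrics")
}

#' @export
print.heterogeneity_metrics <- function(x, ...) {
  cat(sprintf("PC = %d, PD = %.4g, PV = %.4g\n", x$PC, x$PD, x$PV))
  invisible(x)
}

# ---- skeleton morphology ----------------------------------------------------

# 8-connected component labels of a logical matrix (skeleton chains are
# 8-connected, so 4-connected labeling would shatter diagonal branches)
label8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nz <- nrow(mask)
  coords <- arrayInd(idx, dim(mask))
  key <- coords[, 1] + nz * (coords[, 2] - 1L)
  lookup <- match(seq_len(nz * ncol(mask)), key)  # position -> point id
  edges <- integer(0)
  for (o in list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    nb_z <- coords[, 1] + o[1]; nb_x <- coords[, 2] + o[2]
    ok <- nb_z >= 1 & nb_z <= nz & nb_x >= 1 & nb_x <= ncol(mask)
    nb_id <- rep(NA_integer_, length(idx))
    nb_id[ok] <- lookup[nb_z[ok] + nz * (nb_x[ok] - 1L)]
    has <- !is.na(nb_id)
    if (any(has)) edges <- c(edges, rbind(which(has), nb_id[has]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# 8-neighbour shifts; rows are z (downward), cols are x
shift_mat <- function(m, dz, dx) {
  nz <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, nz, nx)
  zs <- max(1, 1 - dz):min(nz, nz - dz)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  out[zs, xs] <- m[zs + dz, xs + dx]
  out
}

#' Morphological skeleton of a binary mask (Zhang-Suen thinning)
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize_mask <- function(mask) {
  img <- matrix(as.integer(as.matrix(mask) != 0), nrow(mask), ncol(mask))
  # neighbours in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) shift_mat(img, o[1], o[2]))
      B <- Reduce(`+`, P)
      ring <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(i)
        (ring[[i]] == 0L) * (ring[[i + 1]] == 1L)))
      if (step == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0L
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0L
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- img == 1L & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# ordered path through a degree-<=2 pixel component; coords: matrix (z, x)
trace_path <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(coords)
  key <- function(z, x) paste(z, x)
  lookup <- stats::setNames(seq_len(n), key(coords[, 1], coords[, 2]))
  nbrs <- lapply(seq_len(n), function(i) {
    # 4-adjacent neighbours first so staircase corner pixels stay on the path
    dz <- c(-1, 1, 0, 0, -1, -1, 1, 1); dx <- c(0, 0, -1, 1, -1, 1, -1, 1)
    cand <- key(coords[i, 1] + dz, coords[i, 2] + dx)
    j <- lookup[cand]
    j <- j[!is.na(j) & j != i]
    unname(j)
  })
  deg <- lengths(nbrs)
  start <- if (any(deg <= 1)) which(deg <= 1)[1] else 1L
  path <- integer(n); seen <- logical(n)
  path[1] <- start; seen[start] <- TRUE
  for (i in 2:n) {
    nxt <- nbrs[[path[i - 1]]]
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) { path <- path[1:(i - 1)]; break }
    path[i] <- nxt[1]; seen[nxt[1]] <- TRUE
  }
  coords[path, , drop = FALSE]
}

# arc length of a pixel path: polyline length after moving-average smoothing
# (endpoints pinned), which removes the digitization bias of raw chain codes
# while keeping straight axis-aligned paths exact
path_arc_length <- function(coords, window = 5) {
  n <- nrow(coords)
  if (n < 2) return(0)
  if (n > 2 && window > 1) {
    half <- floor(window / 2)
    sm <- coords
    for (i in 2:(n - 1)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      sm[i, ] <- colMeans(coords[lo:hi, , drop = FALSE])
    }
    coords <- sm
  }
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' Vessel graph from a skeleton (or binary vessel mask)
#'
#' Junction (node) pixels are skeleton pixels with at least three skeleton
#' neighbours; adjacent node pixels are merged into single junctions.
#' Removing node pixels leaves the branches: connected chains traced into
#' ordered paths with arc length (smoothed polyline) and chord length
#' (endpoint distance).
#'
#' @param skeleton logical matrix; set `is_skeleton = FALSE` to thin a filled
#'   vessel mask first.
#' @param pixel_size grid pitch in mm.
#' @param roi_mask optional logical matrix (same shape) defining the ROI;
#'   defaults to the full grid.
#' @param binary_mask optional filled vessel mask used for the area-based
#'   density metric; defaults to the skeleton input.
#' @param is_skeleton whether `skeleton` is already one pixel wide.
#' @param smooth_window moving-average window for arc-length measurement.
#' @return object of class `vessel_graph`: `skeleton`, `binary`, `n_nodes`,
#'   `branches` (data frame with `n_px`, `arc_mm`, `chord_mm`), `paths`,
#'   `roi_area_mm2`, `roi_px`, `pixel_size`.
#' @export
vessel_graph_from_skeleton <- function(skeleton, pixel_size = 1,
                                       roi_mask = NULL, binary_mask = NULL,
                                       is_skeleton = TRUE, smooth_window = 5) {
  skel0 <- as.matrix(skeleton) != 0
  if (is.null(binary_mask)) binary_mask <- skel0
  skel <- if (is_skeleton) skel0 else skeletonize_mask(skel0)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(skel), ncol(skel))
  roi_mask <- as.matrix(roi_mask) != 0

  # junctions via the ring crossing number: >= 3 distinct neighbour runs
  # around the 8-ring (a raw neighbour count misfires on staircase corners)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  P <- lapply(offs, function(o) shift_mat(skel + 0L, o[1], o[2]))
  ring <- c(P, P[1])
  crossings <- Reduce(`+`, lapply(1:8, function(i)
    (ring[[i]] == 0L) * (ring[[i + 1]] == 1L)))
  node_px <- skel & crossings >= 3
  n_nodes <- if (any(node_px)) max(label8(node_px)) else 0L

  branch_px <- skel & !node_px
  branches <- data.frame(n_px = integer(), arc_mm = numeric(),
                         chord_mm = numeric())
  paths <- list()
  if (any(branch_px)) {
    lab <- label8(branch_px)
    nb_lab <- max(lab)
    all_idx <- which(lab > 0)
    comp <- split(all_idx, as.vector(lab)[all_idx])
    for (ci in seq_along(comp)) {
      coords <- arrayInd(comp[[ci]], dim(skel))
      path <- trace_path(coords)
      arc <- path_arc_length(path, smooth_window) * pixel_size
      chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2)) * pixel_size
      branches <- rbind(branches,
                        data.frame(n_px = nrow(coords), arc_mm = arc,
                                   chord_mm = chord))
      paths[[length(paths) + 1]] <- path
    }
  }
  structure(list(skeleton = skel, binary = binary_mask,
                 n_nodes = as.integer(n_nodes), branches = branches,
                 paths = paths,
                 roi_area_mm2 = sum(roi_mask) * pixel_size^2,
                 roi_px = sum(roi_mask), roi_mask = roi_mask,
                 pixel_size = pixel_size),
            class = "vessel_graph")
}

#' Vessel graph from a super-resolved map
#'
#' Binarizes the map (Otsu threshold over the nonzero intensities by
#' default), removes connected components below `min_size` pixels,
#' skeletonizes, and runs the branch/node analysis.
#'
#' @param map an `sr_map` (or plain matrix in `[0, 1]`).
#' @param threshold `"otsu"` or a numeric threshold.
#' @param min_size smallest retained component, pixels.
#' @param roi_mask optional logical ROI on the magnified grid.
#' @param pixel_size grid pitch in mm (taken from the map when available).
#' @export
build_vessel_graph <- function(map, threshold = "otsu", min_size = 10,
                               roi_mask = NULL, pixel_size = NULL) {
  grid <- if (inherits(map, "sr_map")) map$grid else as.matrix(map)
  if (is.null(pixel_size))
    pixel_size <- if (inherits(map, "sr_map")) map$pixel_size else 1
  nzv <- grid[grid > 0]
  if (!length(nzv)) {
    return(vessel_graph_from_skeleton(matrix(FALSE, nrow(grid), ncol(grid)),
                                      pixel_size, roi_mask))
  }
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(nzv)
    if (rng[1] == rng[2]) rng[1] / 2 else
      EBImage::otsu(matrix(nzv, ncol = 1), range = rng)
  } else as.numeric(threshold)
  binary <- grid > thr
  if (any(binary)) {
    lab <- label8(binary)
    sizes <- tabulate(as.vector(lab)[as.vector(lab) > 0])
    small <- which(sizes < min_size)
    if (length(small)) binary[matrix(as.vector(lab) %in% small, nrow(grid))] <- FALSE
  }
  vessel_graph_from_skeleton(binary, pixel_size, roi_mask,
                             binary_mask = binary, is_skeleton = FALSE)
}

#' Structural vascular metrics
#'
#' Vessel density VD = vessel (binary) area / ROI area; vessel number VN =
#' branch count; node number NN = junction count; vessel number per pixel
#' VNP = VN / ROI pixel count; vessel tortuosity VT = mean branch arc/chord
#' ratio (branches with chord shorter than 2 pixels are excluded; VT = 1
#' when no branch qualifies).
#'
#' @param graph a [vessel_graph_from_skeleton()] / [build_vessel_graph()]
#'   result.
#' @return named list with `VD`, `VN`, `NN`, `VNP`, `VT`.
#' @export
structural_metrics <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"), graph$roi_px > 0)
  VD <- sum(graph$binary & graph$roi_mask) / graph$roi_px
  VN <- nrow(graph$branches)
  NN <- graph$n_nodes
  VNP <- VN / graph$roi_px
  ok <- graph$branches$chord_mm >= 2 * graph$pixel_size
  VT <- if (any(ok))
    mean(graph$branches$arc_mm[ok] / graph$branches$chord_mm[ok]) else 1
  list(VD = VD, VN = VN, NN = NN, VNP = VNP, VT = VT)
}

#' Functional flow metrics
#'
#' Mean speed MS (mm/s); speed entropy SE: Shannon entropy in bits of the
#' speed histogram over `speed_bins` equal-width bins spanning `[0, v_max]`;
#' orientation variance OV: circular variance
#' `1 - |mean unit direction vector|` in `[0, 1]`.
#'
#' @param points a `parm_points` data frame (needs `speed`, `direction`).
#' @param speed_bins number of histogram bins.
#' @param v_max upper edge of the speed histogram; defaults to the point
#'   set's speed ceiling.
#' @return named list with `MS`, `SE`, `OV`.
#' @export
functional_metrics <- function(points, speed_bins = 32, v_max = NULL) {
  stopifnot(nrow(points) >= 1)
  if (is.null(v_max)) v_max <- attr(points, "v_max")
  if (is.null(v_max)) v_max <- max(points$speed)
  MS <- mean(points$speed)
  breaks <- seq(0, v_max, length.out = speed_bins + 1)
  s <- pmin(pmax(points$speed, 0), v_max)
  counts <- graphics::hist(s, breaks = breaks, plot = FALSE)$counts
  p <- counts[counts > 0] / sum(counts)
  SE <- -sum(p * log2(p))
  OV <- 1 - sqrt(mean(cos(points$direction))^2 + mean(sin(points$direction))^2)
  list(MS = MS, SE = SE, OV = max(0, min(1, OV)))
}

#' Extract the sentinel microvasculature
#'
#' The sentinel pattern is the one whose feature points have the highest
#' mean speed; its super-resolved map is the sentinel microvasculature. The
#' non-sentinel map is the pixel-wise maximum composite of all remaining
#' per-pattern maps (a zero map when K = 1).
#'
#' @param model a `pattern_model`.
#' @param maps list of `K` per-pattern `sr_map` objects (aligned with
#'   pattern indices).
#' @param points the `parm_points` the model was fit on.
#' @return list with `sentinel_index`, `mean_speeds`, `sentinel` map,
#'   `non_sentinel` map.
#' @export
sentinel_split <- function(model, maps, points) {
  stopifnot(inherits(model, "pattern_model"), length(maps) == model$K,
            length(model$labels) == nrow(points))
  ms <- vapply(seq_len(model$K), function(k) {
    s <- points$speed[model$labels == k]
    if (length(s)) mean(s) else -Inf
  }, numeric(1))
  top <- which(ms == max(ms))
  if (length(top) > 1) {
    warning("tie in pattern mean speeds: lowest pattern index chosen")
    top <- top[1]
  }
  non <- if (model$K > 1) composite_map(maps[-top]) else {
    z <- maps[[1]]
    z$grid <- z$grid * 0
    z$pattern_index <- "non-sentinel (empty)"
    z
  }
  sent <- maps[[top]]
  sent$pattern_index <- paste0("sentinel(", top, ")")
  list(sentinel_index = top, mean_speeds = ms,
       sentinel = sent, non_sentinel = non)
}

# ---- study arithmetic -------------------------------------------------------

#' Ellipsoidal tumor volume from caliper axes
#'
#' `V = a * b^2 / 2` with `a` the long and `b` the short axis (mm), the
#' standard caliper formula for subcutaneous xenografts.
#' @param a long axis, mm.
#' @param b short axis, mm (`a >= b > 0`).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(a, b) {
  stopifnot(all(b > 0), all(a >= b))
  a * b^2 / 2
}

#' Relative tumor volume change
#'
#' As printed, `dV = (V_b - V_a) / V_a` with `V_b` the baseline volume and
#' `V_a` the post-treatment volume. That convention divides by the later
#' volume and is the negative-growth direction of the usual relative-change
#' formula; `convention = "baseline"` gives the conventional
#' `(V_a - V_b) / V_b` (change relative to baseline) instead.
#'
#' @param v_baseline baseline volume (mm^3).
#' @param v_followup post-treatment volume (mm^3).
#' @param convention `"printed"` (default) or `"baseline"`.
#' @export
delta_v <- function(v_baseline, v_followup,
                    convention = c("printed", "baseline")) {
  convention <- match.arg(convention)
  if (convention == "printed") {
    if (any(v_followup == 0)) stop("denominator volume is zero")
    (v_baseline - v_followup) / v_followup
  } else {
    if (any(v_baseline == 0)) stop("baseline volume is zero")
    (v_followup - v_baseline) / v_baseline
  }
}

#' Relative change of a longitudinal indicator
#'
#' `(value at day N - value at baseline) / value at baseline`.
#' @param value indicator value at the later time point.
#' @param baseline indicator value at baseline.
#' @export
relative_change <- function(value, baseline) {
  if (any(baseline == 0)) stop("baseline value is zero: relative change undefined")
  (value - baseline) / baseline
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; errors on constant input,
#' where the coefficient is undefined.
#' @param xs,ys equal-length numeric vectors (length >= 3).
#' @export
spearman_cor <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("constant input: rank correlation undefined")
  stats::cor(xs, ys, method = "spearman")
}
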