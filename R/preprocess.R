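#' Casorati SVD of a CEUS sequence
#'
#' Reshapes the sequence into the pixels-by-frames Casorati matrix and
#' computes its full singular value decomposition. The decomposition is
#' exact (LAPACK); the clutter filter itself ([svd_filter()]) uses a faster
#' Gram-matrix route internally because it only needs the leading temporal
#' subspace.
#'
#' @param seq a [ceus_sequence()] with at least 2 frames.
#' @return object of class `casorati_svd`: `singular_values` (non-increasing),
#'   `temporal` (frames x k), `spatial` (pixels x k), and the frame shape.
#' @export
casorati_svd <- function(seq) {
  stopifnot(inherits(seq, "ceus_sequence"), n_frames(seq) >= 2)
  C <- casorati(seq)
  s <- svd(C, nu = ncol(C), nv = ncol(C))
  structure(list(singular_values = s$d, temporal = s$v, spatial = s$u,
                 nz = dim(seq$frames)[2], nx = dim(seq$frames)[3],
                 pixel_size = seq$pixel_size, frame_rate = seq$frame_rate),
            class = "casorati_svd")
}

#' Rebuild a sequence from a band of singular components
#'
#' @param dec a [casorati_svd()].
#' @param components integer indices of components to retain (1-based).
#' @export
svd_reconstruct <- function(dec, components) {
  stopifnot(all(components >= 1), all(components <= length(dec$singular_values)))
  C <- dec$spatial[, components, drop = FALSE] %*%
    (dec$singular_values[components] * t(dec$temporal[, components, drop = FALSE]))
  ceus_sequence(uncasorati(C, dec$nz, dec$nx), dec$pixel_size, dec$frame_rate)
}

# adaptive low cutoff: elbow of the log singular-value curve, located as the
# largest discrete second difference over the first half of the spectrum;
# returns the number of leading (clutter) components to remove
adaptive_cutoff <- function(d) {
  keep <- d > max(d) * 1e-12
  ls <- log(d[keep])
  n <- length(ls)
  if (n < 4) return(1L)
  hi <- max(3L, floor(n / 2))
  idx <- 2:(hi - 1)
  curv <- ls[idx + 1] - 2 * ls[idx] + ls[idx - 1]
  as.integer(idx[which.max(curv)] - 1L)
}

#' SVD clutter filter
#'
#' Removes the leading (tissue-clutter) singular components of the Casorati
#' matrix and, optionally, trailing noise components. The filter is a linear
#' projection: the output is the input minus its projection onto the removed
#' temporal subspace.
#'
#' @param seq a [ceus_sequence()].
#' @param cutoff number of leading components to remove (0 = none), or
#'   `"adaptive"` to place the cutoff at the largest-curvature turning point
#'   of the log singular-value curve (first half of the spectrum).
#' @param cutoff_high optional index of the last retained component;
#'   components beyond it are removed too. Default keeps all.
#' @return filtered [ceus_sequence()]; attributes `cutoff`, `cutoff_high` and
#'   `singular_values` record the decision.
#' @export
svd_filter <- function(seq, cutoff = "adaptive", cutoff_high = NULL) {
  stopifnot(inherits(seq, "ceus_sequence"), n_frames(seq) >= 2)
  C <- casorati(seq)
  e <- eigen(crossprod(C), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  nc <- length(d)
  n_low <- if (identical(cutoff, "adaptive")) adaptive_cutoff(d) else as.integer(cutoff)
  if (n_low >= nc) stop("cutoff must be smaller than the number of components")
  if (n_low < 0) stop("cutoff must be >= 0")
  hi <- if (is.null(cutoff_high)) nc else as.integer(cutoff_high)
  stopifnot(hi >= n_low + 1, hi <= nc)
  rm_idx <- c(seq_len(n_low), if (hi < nc) (hi + 1):nc)
  if (length(rm_idx)) {
    Vrm <- e$vectors[, rm_idx, drop = FALSE]
    C <- C - (C %*% Vrm) %*% t(Vrm)
  }
  out <- ceus_sequence(uncasorati(C, dim(seq$frames)[2], dim(seq$frames)[3]),
                       seq$pixel_size, seq$frame_rate, roi_mask = seq$roi_mask)
  attr(out, "cutoff") <- n_low
  attr(out, "cutoff_high") <- hi
  attr(out, "singular_values") <- d
  out
}

#' Screen a sequence for motion-corrupted frames
#'
#' Computes the Pearson correlation of every adjacent frame pair (on B-mode
#' frames when available). Both frames of any pair whose correlation falls
#' below `threshold` are excluded; the retained frames are partitioned into
#' contiguous segments and segments shorter than `min_segment` are discarded
#' (their frames join the exclusion list) so that velocimetry windows remain
#' valid. Zero-variance (constant) frame pairs are assigned correlation 1.
#'
#' @param seq a [ceus_sequence()] (typically B-mode).
#' @param threshold correlation threshold; pairs below it mark motion.
#' @param min_segment minimum retained-segment length in frames.
#' @return object of class `motion_report`: `frame_correlations` (length
#'   `n - 1`), `excluded_frames` (sorted indices), `segments` (matrix with
#'   1-based inclusive `start`, `end` columns).
#' @export
screen_motion <- function(seq, threshold = 0.8, min_segment = 50) {
  stopifnot(inherits(seq, "ceus_sequence"), n_frames(seq) >= 2)
  nt <- n_frames(seq)
  C <- casorati(seq)
  sds <- apply(C, 2, stats::sd)
  cors <- vapply(seq_len(nt - 1), function(i) {
    if (sds[i] == 0 || sds[i + 1] == 0) return(1)
    stats::cor(C[, i], C[, i + 1])
  }, numeric(1))
  bad_pair <- cors < threshold
  excluded <- sort(unique(c(which(bad_pair), which(bad_pair) + 1L)))
  keep <- setdiff(seq_len(nt), excluded)
  segs <- contiguous_segments(keep)
  if (nrow(segs)) {
    short <- (segs[, 2] - segs[, 1] + 1) < min_segment
    for (i in which(short)) excluded <- c(excluded, segs[i, 1]:segs[i, 2])
    segs <- segs[!short, , drop = FALSE]
    excluded <- sort(unique(excluded))
  }
  structure(list(frame_correlations = cors,
                 excluded_frames = excluded, segments = segs),
            class = "motion_report")
}

contiguous_segments <- function(idx) {
  if (!length(idx)) return(matrix(integer(), 0, 2,
                                  dimnames = list(NULL, c("start", "end"))))
  brk <- which(diff(idx) > 1)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  matrix(c(starts, ends), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf("<motion_report> %d excluded frames, %d segment(s)\n",
              length(x$excluded_frames), nrow(x$segments)))
  invisible(x)
}
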