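#' Pipeline configuration
#'
#' Resolved, serializable configuration for a full run:
#' simulate (or load) -> motion screen -> SVD filter -> trail features ->
#' pattern clustering -> per-pattern reconstruction -> metrics. Every source
#' of randomness derives from `seed`.
#'
#' @param seed master integer seed.
#' @param input path to a TIFF sequence (with YAML sidecar) or `NULL` to
#'   simulate the bundled phantom.
#' @param phantom `"demo3"` (three streamlines with distinct speed and
#'   direction) or a list of [streamline_spec()].
#' @param acquisition an [acquisition_spec()].
#' @param motion list: `enabled`, `threshold`, `min_segment`.
#' @param filter list: `cutoff` (`"adaptive"` or integer), `cutoff_high`.
#' @param features list: `detect_quantile`, `gradient_sigma`, `window_sigma`,
#'   `time_scale`, `min_coherence`, `v_max`.
#' @param clustering list: `k_max`, `n_fit`, `n_sil`, `silhouette_floor`,
#'   `nstart`, `weights`.
#' @param srrf an [srrf_params()].
#' @param metrics list: `speed_bins`, `graph_min_size`, `graph_threshold`.
#' @param acquisition_id label written with the metric rows.
#' @export
parm_config <- function(seed = 7L, input = NULL, phantom = "demo3",
                        acquisition = acquisition_spec(rng_seed = seed),
                        motion = list(enabled = FALSE, threshold = 0.8,
                                      min_segment = 50),
                        filter = list(cutoff = "adaptive", cutoff_high = NULL),
                        features = list(detect_quantile = 0.95,
                                        gradient_sigma = 1, window_sigma = 2,
                                        time_scale = 1, min_coherence = 0.5,
                                        v_max = NULL),
                        clustering = list(k_max = 10, n_fit = 20000,
                                          n_sil = 2000,
                                          silhouette_floor = 0.35,
                                          nstart = 10, weights = c(1, 1, 1)),
                        srrf = srrf_params(),
                        metrics = list(speed_bins = 32, graph_min_size = 10,
                                       graph_threshold = "otsu"),
                        acquisition_id = "run1") {
  structure(list(seed = as.integer(seed), input = input, phantom = phantom,
                 acquisition = acquisition, motion = motion, filter = filter,
                 features = features, clustering = clustering, srrf = srrf,
                 metrics = metrics, acquisition_id = acquisition_id),
            class = "parm_config")
}

demo_streamlines <- function(acq) {
  w <- acq$n_x * acq$pixel_size
  h <- acq$n_z * acq$pixel_size
  list(
    streamline_spec(rbind(c(0.02 * w, 0.30 * h), c(0.98 * w, 0.30 * h)),
                    speed = 2, direction_sign = 1, mb_rate = 20),
    streamline_spec(rbind(c(0.02 * w, 0.60 * h), c(0.98 * w, 0.60 * h)),
                    speed = 8, direction_sign = -1, mb_rate = 20),
    streamline_spec(rbind(c(0.50 * w, 0.02 * h), c(0.50 * w, 0.98 * h)),
                    speed = 5, direction_sign = 1, mb_rate = 20))
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes the run directory:
#' `config.yaml` (resolved configuration), `model.json`, `points.csv`
#' (feature points with pattern labels), `metrics.csv` (one row per
#' compartment: whole, each pattern, sentinel, non-sentinel),
#' `maps/*.tif` super-resolved maps, and `log.txt` (versions, seed, config
#' checksum, stage timings). Deterministic given the configuration.
#'
#' @param config a [parm_config()].
#' @param out_dir run directory (created if missing).
#' @return (invisibly) a list with all intermediate objects.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "parm_config"))
  if (!is.null(config$input) && !file.exists(config$input))
    stop("input path does not exist: ", config$input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  log <- character()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  stage <- function(msg, t) {
    log <<- c(log, sprintf("%-28s %7.1f s", msg, tic() - t))
  }

  acq <- config$acquisition
  truth <- NULL
  t1 <- tic()
  if (is.null(config$input)) {
    sl <- if (identical(config$phantom, "demo3")) demo_streamlines(acq)
          else config$phantom
    sim <- simulate_ceus(sl, acq, seed = config$seed)
    seq <- sim$seq; truth <- sim$truth
  } else {
    seq <- read_ceus_tiff(config$input)
  }
  stage("acquire/simulate", t1)

  segment <- NULL
  if (isTRUE(config$motion$enabled)) {
    rep <- screen_motion(seq, config$motion$threshold,
                         config$motion$min_segment)
    if (nrow(rep$segments) == 0) stop("motion screening left no usable segment")
    len <- rep$segments[, 2] - rep$segments[, 1]
    segment <- rep$segments[which.max(len), ]
    jsonlite::write_json(list(excluded_frames = rep$excluded_frames,
                              segments = rep$segments),
                         file.path(out_dir, "motion.json"), digits = NA)
  }

  t1 <- tic()
  filtered <- svd_filter(seq, cutoff = config$filter$cutoff,
                         cutoff_high = config$filter$cutoff_high)
  stage(sprintf("svd filter (cutoff %d)", attr(filtered, "cutoff")), t1)

  t1 <- tic()
  fz <- config$features
  stack <- build_stack(filtered, segment = segment,
                       detect_quantile = fz$detect_quantile)
  orient <- tensor_orientation(stack, gradient_sigma = fz$gradient_sigma,
                               window_sigma = fz$window_sigma,
                               time_scale = fz$time_scale)
  points <- extract_feature_points(stack, orient, v_max = fz$v_max,
                                   min_coherence = fz$min_coherence)
  stage(sprintf("trail features (%d pts)", nrow(points)), t1)

  t1 <- tic()
  cz <- config$clustering
  feats <- build_feature_space(points, weights = cz$weights)
  model <- adaptive_kmeans(feats, k_max = cz$k_max, seed = config$seed,
                           n_fit = cz$n_fit, n_sil = cz$n_sil,
                           silhouette_floor = cz$silhouette_floor,
                           nstart = cz$nstart)
  stage(sprintf("clustering (K = %d)", model$K), t1)

  t1 <- tic()
  subseqs <- split_sequence(stack, points, model)
  maps <- lapply(seq_len(model$K), function(k)
    srrf_reconstruct(subseqs[[k]], config$srrf, pattern_index = k))
  comp <- composite_map(maps)
  sent <- sentinel_split(model, maps, points)
  stage("per-pattern reconstruction", t1)

  t1 <- tic()
  het <- heterogeneity(model)
  mz <- config$metrics
  compartments <- c(list(whole = list(map = comp, pts = points)),
                    stats::setNames(lapply(seq_len(model$K), function(k)
                      list(map = maps[[k]],
                           pts = points[model$labels == k, , drop = FALSE])),
                      paste0("pattern", seq_len(model$K))),
                    list(sentinel = list(
                           map = sent$sentinel,
                           pts = points[model$labels == sent$sentinel_index, ,
                                        drop = FALSE]),
                         non_sentinel = list(
                           map = sent$non_sentinel,
                           pts = points[model$labels != sent$sentinel_index, ,
                                        drop = FALSE])))
  rows <- lapply(names(compartments), function(nm) {
    cc <- compartments[[nm]]
    g <- build_vessel_graph(cc$map, threshold = mz$graph_threshold,
                            min_size = mz$graph_min_size)
    st <- structural_metrics(g)
    fn <- if (nrow(cc$pts)) functional_metrics(cc$pts, mz$speed_bins,
                                               v_max = attr(points, "v_max"))
          else list(MS = NA_real_, SE = NA_real_, OV = NA_real_)
    data.frame(acquisition_id = config$acquisition_id, compartment = nm,
               n_points = nrow(cc$pts),
               PC = if (nm == "whole") het$PC else NA_integer_,
               PD = if (nm == "whole") het$PD else NA_real_,
               PV = if (nm == "whole") het$PV else NA_real_,
               VD = st$VD, VN = st$VN, NN = st$NN, VNP = st$VNP, VT = st$VT,
               MS = fn$MS, SE = fn$SE, OV = fn$OV)
  })
  metrics <- do.call(rbind, rows)
  stage("metrics", t1)

  # outputs
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), cfg_path)
  write_pattern_model(model, file.path(out_dir, "model.json"))
  pts_out <- points
  pts_out$pattern <- model$labels
  utils::write.csv(pts_out[, c("t_index", "z", "x", "speed", "direction",
                               "coherence", "intensity", "pattern")],
                   file.path(out_dir, "points.csv"), row.names = FALSE)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  for (k in seq_len(model$K))
    write_sr_map(maps[[k]], file.path(out_dir, "maps",
                                      sprintf("pattern%02d.tif", k)))
  write_sr_map(comp, file.path(out_dir, "maps", "composite.tif"))
  write_sr_map(sent$sentinel, file.path(out_dir, "maps", "sentinel.tif"))
  write_sr_map(sent$non_sentinel, file.path(out_dir, "maps", "non_sentinel.tif"))
  log <- c(sprintf("parm %s | R %s", as.character(utils::packageVersion("parm")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed %d | config md5 %s", config$seed,
                   unname(tools::md5sum(cfg_path))),
           log, sprintf("%-28s %7.1f s", "total", tic() - t0))
  writeLines(log, file.path(out_dir, "log.txt"))

  invisible(list(seq = seq, filtered = filtered, stack = stack,
                 points = points, model = model, maps = maps,
                 composite = comp, sentinel = sent, heterogeneity = het,
                 metrics = metrics, truth = truth, out_dir = out_dir))
}

config_to_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

#' Render a human-readable report for a completed run
#'
#' Writes `report.md` plus PNG panels into the run directory: one panel per
#' pattern map, the composite and sentinel maps, and the feature-space
#' scatter colored by pattern.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @export
parm_report <- function(run_dir) {
  metrics <- utils::read.csv(file.path(run_dir, "metrics.csv"))
  points <- utils::read.csv(file.path(run_dir, "points.csv"))
  maps <- list.files(file.path(run_dir, "maps"), pattern = "\\.tif$",
                     full.names = TRUE)
  pngs <- character()
  for (m in maps) {
    grid <- tiff::readTIFF(m)
    out <- sub("\\.tif$", ".png", m)
    grDevices::png(out, width = 600, height = 600)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    graphics::image(t(grid)[, nrow(grid):1], col = grDevices::hcl.colors(64, "inferno"),
                    axes = FALSE, main = basename(m), asp = nrow(grid) / ncol(grid))
    graphics::par(op)
    grDevices::dev.off()
    pngs <- c(pngs, basename(out))
  }
  sc <- file.path(run_dir, "feature_space.png")
  grDevices::png(sc, width = 700, height = 600)
  graphics::plot(points$speed, points$direction, col = points$pattern + 1,
                 pch = 16, cex = 0.4, xlab = "speed (mm/s)",
                 ylab = "direction (rad)",
                 main = "hemodynamic feature space by pattern")
  grDevices::dev.off()

  md <- c("# PARM run report", "",
          sprintf("Run directory: `%s`", normalizePath(run_dir)), "",
          "## Metrics", "",
          paste(names(metrics), collapse = " | "),
          paste(rep("---", ncol(metrics)), collapse = " | "),
          apply(metrics, 1, function(r)
            paste(vapply(r, function(v) format(v, digits = 4), ""),
                  collapse = " | ")),
          "", "## Panels", "",
          sprintf("![%s](maps/%s)", pngs, pngs),
          "", "![feature space](feature_space.png)")
  writeLines(md, file.path(run_dir, "report.md"))
  invisible(file.path(run_dir, "report.md"))
}
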