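#' Assemble a pipeline configuration
#'
#' Plain-list configuration with the reference operating points as
#' defaults; the full configuration (and its hash) is echoed into every
#' output the pipeline writes.
#'
#' @param sim_params a [SimParams-class] (used when `input_dir` is NULL).
#' @param input_dir optional directory of existing panoramas
#'   (`frame_%04d.tif` + `frames.csv`), consumed instead of simulating.
#' @param pixel_scale µm/px (default 3.516).
#' @param hypha_width px (default 7).
#' @param n_px node-proximity radius, px (default 20).
#' @param fit_window hours, `c(5, NA)`: NA upper bound = end of series.
#' @param min_particle_px,opening_radius cleaning parameters.
#' @param analysis_frames indices of frames to vectorize (default: all).
#' @param out_dir output directory (NULL = nothing written).
#' @return a list of class `mycelia_config`.
#' @export
pipelineConfig <- function(sim_params = simParams(), input_dir = NULL,
                           pixel_scale = 3.516, hypha_width = 7,
                           n_px = 20, fit_window = c(5, NA),
                           min_particle_px = 50, opening_radius = 1,
                           analysis_frames = NULL, out_dir = NULL) {
  cfg <- list(sim_params = sim_params, input_dir = input_dir,
              pixel_scale = pixel_scale, hypha_width = hypha_width,
              n_px = n_px, fit_window = fit_window,
              min_particle_px = min_particle_px,
              opening_radius = opening_radius,
              analysis_frames = analysis_frames, out_dir = out_dir)
  class(cfg) <- "mycelia_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load panoramas) -> grayscale/binarize/clean ->
#' vectorize each frame -> tally series -> node correction -> growth-rate
#' fits and branching/anastomosis decomposition -> intra-thallus faces of
#' the final frame. Deterministic given the configuration; a manifest
#' records the configuration hash, seeds and per-stage record counts.
#'
#' @param config a list from [pipelineConfig()].
#' @return list with `series` ([GrowthSeries-class]), `graphs`, `rates`
#'   ([RateEstimates-class]), `faces` ([FaceSet-class] of the final
#'   analyzed frame), `sim` (when simulated) and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "mycelia_config"))
  manifest <- list(config = config,
                   config_hash = .config_hash(config),
                   stages = list())
  stage <- function(key, ...) {
    manifest$stages[[key]] <<- list(...)
  }

  # --- stage 1: frames --------------------------------------------------
  sim <- NULL
  if (is.null(config$input_dir)) {
    sim <- simulateNetwork(config$sim_params)
    nf <- nrow(sim@truth)
    frames <- config$analysis_frames
    if (is.null(frames)) frames <- seq_len(nf)
    pans <- lapply(frames, function(f)
      renderPanorama(sim, f, pixel_scale = config$pixel_scale,
                     hypha_width = config$hypha_width))
    times <- sim@truth$time_h[frames]
    stage("simulate", frames = nf, seed = config$sim_params@seed,
          events = nrow(sim@events))
  } else {
    meta <- read.csv(file.path(config$input_dir, "frames.csv"))
    frames <- config$analysis_frames
    if (is.null(frames)) frames <- meta$frame
    meta <- meta[match(frames, meta$frame), ]
    pans <- lapply(seq_len(nrow(meta)), function(i)
      readPanorama(file.path(config$input_dir,
                             sprintf("frame_%04d.tif", meta$frame[i])),
                   time_h = meta$time_h[i],
                   pixel_scale = meta$pixel_scale_um[i],
                   frame_index = meta$frame[i]))
    times <- meta$time_h
    stage("load", frames = length(pans), dir = config$input_dir)
  }

  # --- stage 2: binarize ------------------------------------------------
  masks <- lapply(pans, function(p) {
    px <- p@pixels
    if (all(px %in% c(0, 1))) px   # already a clean binary mask
    else binarizeAndClean(px, min_particle_px = config$min_particle_px,
                          opening_radius = config$opening_radius)
  })
  stage("binarize", frames = length(masks),
        min_particle_px = config$min_particle_px)

  # --- stage 3: vectorize -----------------------------------------------
  graphs <- lapply(masks, extractGraph, pixel_scale = config$pixel_scale,
                   hypha_width = config$hypha_width)
  tl <- do.call(rbind, lapply(seq_along(graphs), function(i)
    classifyAndTally(graphs[[i]], time = times[i], frame = frames[i])))
  series <- new("GrowthSeries", tallies = tl, label = "pipeline",
                T1 = NA_real_)
  stage("vectorize", frames = length(graphs),
        vertices = sum(vapply(graphs, function(g)
          nrow(graphVertices(g)), 1)),
        pruned_spurs = sum(vapply(graphs, function(g) g@pruned_spurs, 1)))

  # --- stage 4: node correction ------------------------------------------
  series <- correctNodes(series, graphs, n_px = config$n_px)
  stage("correct", n_px = config$n_px,
        r_pooled = attr(tallies(series), "r_pooled"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tl_out <- tallies(series)
    tl_out$config_hash <- manifest$config_hash
    write.csv(tl_out, file.path(config$out_dir, "series.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, n_px = config$n_px,
           r_pooled = attr(tallies(series), "r_pooled"),
           sigma_r = attr(tallies(series), "sigma_r")),
      file.path(config$out_dir, "node_correction.json"),
      auto_unbox = TRUE, digits = NA)
  }

  # --- stage 5: rates -----------------------------------------------------
  win <- config$fit_window
  if (is.na(win[2])) win[2] <- max(times)
  if (sum(times >= win[1] & times <= win[2]) < 4)
    stop("rates stage: fit window [", win[1], ", ", win[2],
         "] h contains fewer than 4 analyzed frames")
  rates <- estimateRates(series, window = win)
  stage("rates", alpha_b = rates@alpha_b, alpha_a = rates@alpha_a)

  # --- stage 6: faces ------------------------------------------------------
  fset <- tryCatch(extractFaces(masks[[length(masks)]],
                                pixel_scale = config$pixel_scale,
                                time_h = times[length(times)]),
                   error = function(e) NULL)
  stage("faces", n = if (is.null(fset)) 0L else nrow(faces(fset)))

  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(config_hash = manifest$config_hash,
           rates = rates@rates,
           alpha_b = rates@alpha_b, alpha_a = rates@alpha_a,
           scaling_exponent = rates@scaling_exponent),
      file.path(config$out_dir, "rates.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(series = series, graphs = graphs, rates = rates, faces = fset,
       sim = sim, manifest = manifest)
}

.config_hash <- function(config) {
  # hash the analysis-relevant settings only (not the output location)
  cfg <- config[setdiff(names(config), "out_dir")]
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small deterministic polynomial hash, no extra dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
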