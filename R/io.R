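#' Read a multi-frame TIFF stack
#'
#' Loads all frames of a (possibly multi-page) TIFF file as integer
#' matrices and attaches frame times, synthesised from
#' \code{frame_interval} when the file carries no timestamps.
#'
#' @param path TIFF file path.
#' @param frame_interval minutes between frames used to synthesise
#'   timestamps (default 3).
#' @return list with \code{frames} (list of matrices) and \code{t}
#'   (minutes).
#' @export
read_stack <- function(path, frame_interval = 3) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("failed to parse TIFF '", path, "': ",
                             conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  shp <- dim(frames[[1]])
  for (f in frames) if (!all(dim(f) == shp))
    stop("mixed frame shapes in ", path)
  list(frames = frames, t = (seq_along(frames) - 1) * frame_interval)
}

#' Write a multi-frame 16-bit TIFF stack
#'
#' @param frames list of matrices with values in [0, 65535] (label masks or
#'   16-bit images).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(m) {
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read trajectory tables as CSV
#'
#' UTF-8, comma-separated, header row, times in minutes, areas in px^2.
#'
#' @param traj trajectory data.frame (e.g. from a \code{colony_sim} or
#'   [build_lineage()]).
#' @param path CSV path.
#' @return \code{path} invisibly (write) or the data.frame (read).
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' Serialise a lineage to JSON
#'
#' Writes roots and a parent-to-children adjacency map.
#'
#' @param tree a [build_lineage()] result, or any data.frame with
#'   \code{cell_id} and \code{parent_id} columns.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
write_lineage_json <- function(tree, path = NULL) {
  tracks <- if (inherits(tree, "lineage_tree")) tree$tracks else tree
  stopifnot(all(c("cell_id", "parent_id") %in% names(tracks)))
  roots <- tracks$cell_id[is.na(tracks$parent_id)]
  kids <- tracks[!is.na(tracks$parent_id), ]
  adj <- lapply(split(kids$cell_id, kids$parent_id), as.integer)
  js <- jsonlite::toJSON(list(roots = as.integer(roots), children = adj),
                         auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Validate a pipeline configuration
#'
#' Checks the nested configuration used by [run_pipeline()]; errors name
#' the offending field.
#'
#' @param config named list: \code{rng_seed} (integer), \code{ahl_list}
#'   (non-negative numeric), \code{sim} (a [sim_config()] or argument
#'   list), \code{seg} (a [seg_config()] or argument list), optional
#'   \code{noise_ahl}, \code{sender_ratios}, \code{out_dir}.
#' @return validated config (classed \code{pipeline_config}).
#' @export
pipeline_config <- function(config) {
  fail <- function(field, msg)
    stop("invalid config field '", field, "': ", msg, call. = FALSE)
  if (!is.list(config)) fail("(root)", "must be a list")
  if (is.null(config$rng_seed) || !is.numeric(config$rng_seed))
    fail("rng_seed", "integer seed required")
  if (is.null(config$ahl_list) || !is.numeric(config$ahl_list) ||
      any(config$ahl_list < 0))
    fail("ahl_list", "non-negative concentrations required")
  if (length(config$ahl_list) < 4)
    fail("ahl_list", "need at least 4 concentrations for a Hill fit")
  config$sim <- if (inherits(config$sim, "sim_config")) config$sim else
    tryCatch(do.call(sim_config, as.list(config$sim)),
             error = function(e) fail("sim", conditionMessage(e)))
  config$seg <- if (inherits(config$seg, "seg_config")) config$seg else
    tryCatch(do.call(seg_config, as.list(config$seg)),
             error = function(e) fail("seg", conditionMessage(e)))
  if (!is.null(config$noise_ahl) &&
      (!is.numeric(config$noise_ahl) || config$noise_ahl < 0))
    fail("noise_ahl", "must be a non-negative concentration")
  if (!is.null(config$sender_ratios) &&
      (any(config$sender_ratios <= 0) || length(config$sender_ratios) < 3))
    fail("sender_ratios", "need at least 3 positive ratios")
  structure(config, class = "pipeline_config")
}

#' Run the simulate-segment-track-analyse pipeline
#'
#' Chains the full analysis on synthetic data: renders and segments one
#' image stack per AHL concentration, computes colony-level expression
#' rates and the Hill response fit, the stationary noise plateau, and
#' (when \code{sender_ratios} is given) the sender-strength calibration.
#' Every run is reproducible from \code{rng_seed}; the report carries the
#' seed and a hash of the configuration.
#'
#' @param config a [pipeline_config()] (or plain list passed through it).
#' @return report list; written to \code{out_dir/report.json} when
#'   \code{out_dir} is set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  seed <- as.integer(config$rng_seed)

  res <- tryCatch(
    colony_response_experiment(config$ahl_list, config$sim, config$seg,
                               seed = seed),
    error = function(e) stop("stage 'colony_response' failed: ",
                             conditionMessage(e), call. = FALSE))
  noise <- tryCatch({
    noise_ahl <- if (is.null(config$noise_ahl)) 50 else config$noise_ahl
    pop <- simulate_snapshot_population(200, config$sim, noise_ahl,
                                        seed = seed + 1L)
    noise_curve(pop$snapshots, pop$t, dominant_only = TRUE,
                seed = seed + 2L)
  }, error = function(e) stop("stage 'noise' failed: ",
                              conditionMessage(e), call. = FALSE))
  sender <- NULL
  if (!is.null(config$sender_ratios)) {
    sender <- tryCatch(
      calibrate_sender_strength(config$sender_ratios, seed = seed + 3L),
      error = function(e) stop("stage 'sender' failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  cfg_json <- jsonlite::toJSON(config[c("rng_seed", "ahl_list", "noise_ahl",
                                        "sender_ratios")],
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)

  report <- list(
    seed = seed,
    config_hash = hash,
    hill = as.list(round(res$fit$coefficients, 8)),
    hill_se = as.list(round(res$fit$se, 8)),
    response = res$response,
    noise_plateau_cv = round(noise$plateau_cv, 8),
    sender_slope = if (!is.null(sender)) round(sender$calibration$slope, 10)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
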