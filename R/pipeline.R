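#' Colony-level response curve from rendered synthetic stacks
#'
#' Full image-pipeline round trip: one microcolony is simulated and
#' rendered per AHL concentration, segmented frame by frame, and the
#' colony-level expression rate alpha(t) = dF/dt / A is computed from the
#' background-corrected total fluorescence and total segmented area.  The
#' maximum rate over the exponential-growth window per concentration is
#' then fitted with a Hill curve.
#'
#' @param ahl_list AHL concentrations (nM), at least 4.
#' @param config a [sim_config()]; its trap/pixel scale sets the rendered
#'   image size.
#' @param seg a [seg_config()] (pixel_size is aligned with \code{config}).
#' @param seed base RNG seed; concentration i uses seed + i.
#' @param keep_stacks keep rendered stacks in the result (memory heavy).
#' @return list with \code{response} (ahl, alpha_max, mu), \code{fit}
#'   (a [fit_hill()]), and per-concentration diagnostics.
#' @export
colony_response_experiment <- function(ahl_list,
                                       config = chemostat_sim_config(),
                                       seg = NULL, seed = 1,
                                       keep_stacks = FALSE) {
  if (length(ahl_list) < 4) stop("need at least 4 concentrations")
  if (is.null(seg))
    seg <- seg_config(pixel_size = config$pixel_size,
                      # geometry priors from the simulated cell type
                      max_length = 1.1 * config$division_length,
                      max_width = 1.6 * config$cell_width)
  seg$pixel_size <- config$pixel_size
  rows <- vector("list", length(ahl_list))
  stacks <- if (keep_stacks) vector("list", length(ahl_list)) else NULL
  for (i in seq_along(ahl_list)) {
    ahl <- ahl_list[i]
    sim <- simulate_colony(config, ahl = ahl, seed = seed + i)
    stack <- render_frames(sim, seed = seed + 1000L + i)
    segres <- segment_stack(stack, config = seg)
    tot <- data.frame(
      t = stack$t,
      A = vapply(segres$regions, function(r) sum(r$area), numeric(1)),
      F = vapply(segres$regions, function(r) sum(r$F_corr), numeric(1)))
    ok <- tot$A > 0
    tot <- tot[ok, ]
    alpha <- compute_alpha(tot$t, tot$F, tot$A)
    # light second smoothing pass so the max statistic is not dominated by
    # single-frame segmentation/shot noise
    if (length(alpha) >= 13)
      alpha <- signal::sgolayfilt(alpha, p = 2, n = 13)
    gw <- tryCatch(estimate_growth_rate(tot$t, tot$A, r2_min = 0.9),
                   error = function(e) NULL)
    interior <- 7:(length(alpha) - 6)  # smoothing edges excluded
    win <- if (is.null(gw)) interior else intersect(gw$window, interior)
    # rate estimates from a near-empty trap are unreliable: require the
    # colony to have reached 10% of its final area
    win <- intersect(win, which(tot$A >= 0.1 * max(tot$A)))
    if (length(win) == 0) win <- interior
    rows[[i]] <- data.frame(ahl = ahl, alpha_max = alpha_max(alpha, win),
                            mu = if (is.null(gw)) NA_real_ else gw$mu)
    if (keep_stacks) stacks[[i]] <- stack
  }
  response <- do.call(rbind, rows)
  fit <- fit_hill(response$ahl, response$alpha_max)
  list(response = response, fit = fit, stacks = stacks)
}

#' Chemostat-scale simulation configuration for pipeline runs
#'
#' The rendered-pipeline experiments use a 32 x 24 um trap view at
#' 0.125 um/px (256 x 192 px), 127 frames at 3-minute intervals, growing
#' a colony from two founders to under ~200 cells; induction parameters
#' default to the chemostat preset.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
chemostat_sim_config <- function(...) {
  args <- list(trap_size = c(32, 24), pixel_size = 0.125,
               duration = 378, frame_interval = 3, init_cells = 2,
               induction = induction_preset("chemostat"))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Single-cell-scale simulation configuration
#'
#' Trajectory-level experiments use the same 32 x 24 um trap view as the
#' chemostat runs, grown from two founders, with the single-cell induction
#' preset matching the chosen observable (mean-rate or max-rate).
#'
#' @param observable "mean" or "max"; selects the induction preset.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
single_cell_sim_config <- function(observable = c("mean", "max"), ...) {
  observable <- match.arg(observable)
  preset <- if (observable == "mean") "single_mean" else "single_max"
  args <- list(trap_size = c(32, 24), pixel_size = 0.125,
               duration = 378, frame_interval = 3, init_cells = 2,
               induction = induction_preset(preset))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Single-cell response curve from simulated trajectories
#'
#' Trajectory-level round trip: per concentration, ground-truth single-cell
#' trajectories are generated, restricted to the dominant subpopulation
#' ([dominant_filter()]), and each trajectory's expression rate series
#' alpha(t) = dF/dt / A is summarised by its maximum or time average.  The
#' per-concentration means (with SDs) are fitted with a Hill curve.
#'
#' @param ahl_list AHL concentrations (nM).
#' @param config a [sim_config()]; use the \code{single_max} induction
#'   preset with \code{observable = "max"} and \code{single_mean} with
#'   \code{"mean"}.
#' @param observable "max" (max_t alpha) or "mean" (time-averaged alpha).
#' @param filter apply dominant-subpopulation filtering (default TRUE).
#' @param min_len minimum trajectory length in frames (Savitzky-Golay
#'   window).
#' @param seed base RNG seed.
#' @return list with \code{response} (ahl, value, sd, n), \code{fit}.
#' @export
trajectory_response_experiment <- function(ahl_list, config,
                                           observable = c("max", "mean"),
                                           filter = TRUE, min_len = 9,
                                           seed = 1) {
  observable <- match.arg(observable)
  rows <- vector("list", length(ahl_list))
  for (i in seq_along(ahl_list)) {
    sim <- simulate_colony(config, ahl = ahl_list[i], seed = seed + i)
    traj <- sim$trajectories
    if (filter)
      traj <- dominant_filter(traj, seed = seed + 100L + i)$trajectories
    vals <- trajectory_alpha_stats(traj, observable, min_len)
    rows[[i]] <- data.frame(ahl = ahl_list[i], value = mean(vals),
                            sd = stats::sd(vals), n = length(vals))
  }
  response <- do.call(rbind, rows)
  fit <- fit_hill(response$ahl, response$value, sd = response$sd)
  list(response = response, fit = fit)
}

# per-trajectory alpha summaries (max or mean) over cell lifetimes
trajectory_alpha_stats <- function(traj, observable, min_len) {
  out <- numeric(0)
  for (cell in unique(traj$cell_id)) {
    seg <- traj[traj$cell_id == cell, ]
    if (nrow(seg) < min_len) next
    seg <- seg[order(seg$frame), ]
    alpha <- compute_alpha(seg$t_min, seg$F, seg$area)
    out <- c(out, if (observable == "max") max(alpha) else mean(alpha))
  }
  if (length(out) == 0) stop("no trajectories of sufficient length")
  out
}
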