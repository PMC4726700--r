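#' Induction parameter presets
#'
#' Default Hill induction parameters of the AHL/P_lux receiver module for
#' the three measurement modalities the analysis targets: bulk plate-reader
#' response, chemostat colony-level response, and single-cell trajectory
#' response (mean-rate and max-rate observables).
#'
#' @param mode one of "bulk", "chemostat", "single_mean", "single_max".
#' @param alpha_g maximal expression rate (a.u./min), default 1.
#' @param basal basal rate, default 0.
#' @return list(alpha_g, K, n, basal) with K in nM.
#' @export
induction_preset <- function(mode = c("bulk", "chemostat", "single_mean",
                                      "single_max"),
                             alpha_g = 1, basal = 0) {
  mode <- match.arg(mode)
  kn <- switch(mode,
    bulk        = c(K = 13.9, n = 0.97),
    chemostat   = c(K = 5.3,  n = 0.95),
    single_mean = c(K = 3.8,  n = 1.5),
    single_max  = c(K = 2.7,  n = 1.2))
  list(alpha_g = alpha_g, K = unname(kn["K"]), n = unname(kn["n"]),
       basal = basal, mode = mode)
}

#' Simulation configuration
#'
#' Parameters of the agent-based rod-cell colony simulator and of the
#' synthetic microscopy renderer.  Defaults emulate receiver E. coli growing
#' in a single-layer 100 x 60 um microfluidic trap imaged every 3 minutes.
#'
#' @param trap_size trap (width, height) in um.
#' @param pixel_size um per pixel (default 0.1, 100x objective scale).
#' @param frame_interval minutes between frames (default 3).
#' @param duration total simulated time in minutes.
#' @param growth_rate exponential growth rate mu in 1/h (chemostat range is
#'   roughly 0.36-1/h).
#' @param division_length length at which a rod divides (um).
#' @param division_asymmetry_cv CV of the daughter length fraction about 1/2.
#' @param cell_width rod width (um).
#' @param init_cells number of founder cells.
#' @param induction Hill induction parameters, see [induction_preset()].
#' @param extrinsic_cv target stationary coefficient of variation of the
#'   per-cell steady-state expression level p; realised half as a
#'   birth-sampled lognormal kinetic-rate factor and half as a slow
#'   Ornstein-Uhlenbeck factor (see the methods vignette).
#' @param extrinsic_tau correlation time of the OU factor (min).
#' @param late_inducer_fraction fraction of cells in the late-inducing,
#'   slow-growing phenotype.
#' @param late_inducer_delay minutes before late inducers start expressing.
#' @param late_inducer_growth_factor growth-rate multiplier for late
#'   inducers (in [0, 1]).
#' @param late_inducer_alpha_factor expression-rate multiplier for late
#'   inducers after their delay.
#' @param sender_fraction fraction of founder cells that are senders.
#' @param rate_mixing weight with which a daughter retains the parent's
#'   kinetic-rate deviations (remainder re-randomised at birth).
#' @param relax_iters pairwise overlap-relaxation iterations per step.
#' @param psf_sigma_px Gaussian PSF sigma for rendering, in pixels.
#' @param fluor_gain photon counts per unit p per pixel.
#' @param fluor_bg fluorescence background level (counts).
#' @param bf_bg,bf_depth,bf_noise brightfield background level, cell
#'   darkness depth and additive noise SD (counts).
#' @param rng_seed integer seed; all simulator randomness derives from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(trap_size = c(100, 60), pixel_size = 0.1,
                       frame_interval = 3, duration = 450,
                       growth_rate = 0.7, division_length = 4,
                       division_asymmetry_cv = 0.05, cell_width = 1,
                       init_cells = 1,
                       induction = induction_preset("chemostat"),
                       extrinsic_cv = 0.17, extrinsic_tau = 60,
                       late_inducer_fraction = 0.05,
                       late_inducer_delay = 300,
                       late_inducer_growth_factor = 0.3,
                       late_inducer_alpha_factor = 0.3,
                       sender_fraction = 0, rate_mixing = 0.5,
                       relax_iters = 10, psf_sigma_px = 2,
                       fluor_gain = 30, fluor_bg = 200,
                       bf_bg = 30000, bf_depth = 15000, bf_noise = 300,
                       rng_seed = NULL) {
  cfg <- list(trap_size = trap_size, pixel_size = pixel_size,
              frame_interval = frame_interval, duration = duration,
              growth_rate = growth_rate, division_length = division_length,
              division_asymmetry_cv = division_asymmetry_cv,
              cell_width = cell_width, init_cells = init_cells,
              induction = induction, extrinsic_cv = extrinsic_cv,
              extrinsic_tau = extrinsic_tau,
              late_inducer_fraction = late_inducer_fraction,
              late_inducer_delay = late_inducer_delay,
              late_inducer_growth_factor = late_inducer_growth_factor,
              late_inducer_alpha_factor = late_inducer_alpha_factor,
              sender_fraction = sender_fraction, rate_mixing = rate_mixing,
              relax_iters = relax_iters, psf_sigma_px = psf_sigma_px,
              fluor_gain = fluor_gain, fluor_bg = fluor_bg,
              bf_bg = bf_bg, bf_depth = bf_depth, bf_noise = bf_noise,
              rng_seed = rng_seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, field, msg)
    if (!cond) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  chk(length(cfg$trap_size) == 2 && all(cfg$trap_size > 0),
      "trap_size", "two positive dimensions required")
  chk(cfg$pixel_size > 0, "pixel_size", "must be positive")
  chk(cfg$frame_interval > 0, "frame_interval", "must be positive")
  chk(cfg$duration > 0, "duration", "must be positive")
  chk(cfg$growth_rate > 0, "growth_rate", "must be positive")
  chk(cfg$division_length > cfg$cell_width, "division_length",
      "must exceed cell_width")
  chk(cfg$cell_width > 0, "cell_width", "must be positive")
  chk(cfg$division_asymmetry_cv >= 0, "division_asymmetry_cv",
      "must be non-negative")
  for (f in c("late_inducer_fraction", "late_inducer_growth_factor",
              "late_inducer_alpha_factor", "sender_fraction", "rate_mixing")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  chk(cfg$extrinsic_cv >= 0, "extrinsic_cv", "must be non-negative")
  chk(cfg$extrinsic_tau > 0, "extrinsic_tau", "must be positive")
  ind <- cfg$induction
  chk(is.list(ind) && all(c("alpha_g", "K", "n", "basal") %in% names(ind)),
      "induction", "needs alpha_g, K, n, basal")
  chk(ind$K > 0 && ind$n > 0 && ind$alpha_g >= 0 && ind$basal >= 0,
      "induction", "K, n must be positive; rates non-negative")
  invisible(TRUE)
}

# Variance budget for the extrinsic noise model.  Total target log-variance
# v = log(1 + cv^2) is split 50/50 between the birth-sampled kinetic-rate
# factor and the OU factor; the OU injection variance is inflated by the
# low-pass attenuation mu*tau/(1 + mu*tau) that dilution (p_dot = a - mu p)
# applies to a slowly varying rate factor, so that the *realised* stationary
# CV of p matches extrinsic_cv.
noise_budget <- function(cfg) {
  v <- log(1 + cfg$extrinsic_cv^2)
  mu_min <- cfg$growth_rate / 60
  rho <- mu_min * cfg$extrinsic_tau / (1 + mu_min * cfg$extrinsic_tau)
  v_kin <- v / 2
  v_ou <- min(v / 2 / max(rho, 0.1), 2 * v)   # clamp the inflation
  list(v_kin = v_kin, v_ou = v_ou)
}
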