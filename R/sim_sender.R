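#' Simulate a sender-receiver experiment
#'
#' Integrates the LuxI/AHL production model for a microchamber containing
#' sender and receiver cells, and derives the quantities the downstream
#' calibration consumes: the AHL time course, the receiver expression rate
#' alpha(t) (Hill response to the instantaneous AHL level), a sender
#' reporter rate series peaking at the sender induction maximum, and the
#' (optionally fluctuating) sender/receiver ratio r(t).
#'
#' @param params a [sender_params()] object.
#' @param t_grid output times (min), increasing from 0.
#' @param receiver Hill parameters of the receiver response (default
#'   chemostat preset).
#' @param t_peak time of maximal sender induction for the synthetic sender
#'   reporter series (min, default 450).
#' @param r_fluct_cv CV of slow division-driven fluctuations applied to
#'   r(t) (default 0; the returned ratio series is what a per-frame
#'   sender/receiver count would measure).
#' @param r_fluct_tau correlation time of the ratio fluctuations (min).
#' @param seed RNG seed for the ratio fluctuations.
#' @return list of class \code{sender_sim}: data.frame \code{series}
#'   (t, luxi, ahl, receiver_alpha, sender_rate, r), \code{params},
#'   \code{receiver}.
#' @export
simulate_sender_receiver <- function(params, t_grid,
                                     receiver = induction_preset("chemostat"),
                                     t_peak = 450, r_fluct_cv = 0,
                                     r_fluct_tau = 90, seed = NULL) {
  stopifnot(inherits(params, "sender_params"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  r0 <- if (is.function(params$r)) params$r else function(t) params$r

  r_meas <- vapply(t_grid, r0, numeric(1))
  if (r_fluct_cv > 0) {
    v <- log(1 + r_fluct_cv^2)
    n <- length(t_grid)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sqrt(v))
    for (k in 2:n) {
      a <- exp(-(t_grid[k] - t_grid[k - 1]) / r_fluct_tau)
      x[k] <- x[k - 1] * a + stats::rnorm(1, 0, sqrt(v * (1 - a^2)))
    }
    r_meas <- r_meas * exp(x - v / 2)
    p2 <- params
    p2$r <- stats::approxfun(t_grid, r_meas, rule = 2)
    sol <- solve_sender_ode(p2, t_grid)
  } else {
    sol <- solve_sender_ode(params, t_grid)
  }
  recv_alpha <- hill(sol$ahl, receiver$alpha_g, receiver$K, receiver$n,
                     receiver$basal)
  # synthetic sender reporter rate: smooth unimodal curve with its maximum
  # at t_peak (senders induce from the start and saturate)
  sender_rate <- (sol$t / t_peak) * exp(1 - sol$t / t_peak)
  series <- data.frame(t = sol$t, luxi = sol$luxi, ahl = sol$ahl,
                       receiver_alpha = recv_alpha,
                       sender_rate = sender_rate,
                       r = stats::approx(t_grid, r_meas, xout = sol$t,
                                         rule = 2)$y)
  structure(list(series = series, params = params, receiver = receiver),
            class = "sender_sim")
}

#' End-to-end sender-strength calibration on simulated experiments
#'
#' Runs one simulated sender-receiver experiment per sender/receiver ratio,
#' measures the receiver rate at the sender induction maximum, inverts the
#' receiver calibration curve to an effective AHL concentration, computes
#' the s-statistic from the measured ratio series, and fits the
#' AHL_eff-versus-s line through the origin whose slope identifies
#' 1/2 * alpha_a * alpha_l * N0.
#'
#' @param ratios sender/receiver ratios, one experiment each (the nominal
#'   experimental ratios are 0.067, 0.142, 0.33 and 1).
#' @param params base [sender_params()] (the \code{r} field is replaced per
#'   experiment).
#' @param calibration a [fit_hill()] receiver calibration; by default the
#'   exact chemostat-preset curve is used via a noiseless fit.
#' @param t_grid time grid (min).
#' @param t_peak sender induction maximum (min).
#' @param alpha_noise_cv multiplicative noise on the measured receiver rate.
#' @param r_fluct_cv ratio fluctuation CV passed to the simulator.
#' @param seed RNG seed.
#' @return list with \code{experiments} (data.frame r, t_max, s, alpha,
#'   ahl_eff, ahl_sd), \code{calibration} (the sender-strength fit),
#'   \code{truth} (generating slope 1/2 alpha_a alpha_l N0).
#' @export
calibrate_sender_strength <- function(ratios, params = sender_params(),
                                      calibration = NULL,
                                      t_grid = seq(0, 600, by = 3),
                                      t_peak = 450, alpha_noise_cv = 0.05,
                                      r_fluct_cv = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  receiver <- induction_preset("chemostat")
  if (is.null(calibration)) {
    cc <- c(0, 1, 2, 4, 8, 12, 20, 50)
    calibration <- fit_hill(cc, hill(cc, receiver$alpha_g, receiver$K,
                                     receiver$n, receiver$basal))
  }
  rows <- lapply(ratios, function(rr) {
    p <- params; p$r <- rr
    sim <- simulate_sender_receiver(p, t_grid, receiver = receiver,
                                    t_peak = t_peak,
                                    r_fluct_cv = r_fluct_cv)
    t_max <- detect_t_max(sim$series$t, sim$series$sender_rate)
    s <- compute_s(sim$series[, c("t", "r")], t_max)
    a_true <- sim$series$receiver_alpha[which.min(abs(sim$series$t - t_max))]
    a_meas <- a_true * (1 + stats::rnorm(1, 0, alpha_noise_cv))
    a_meas <- min(max(a_meas, 1e-9),
                  0.995 * (calibration$coefficients[["alpha_g"]] +
                           calibration$coefficients[["basal"]]))
    inv <- invert_hill(a_meas, calibration,
                       alpha_sd = a_true * alpha_noise_cv)
    data.frame(r = rr, t_max = t_max, s = s$s, r_mean = s$r_mean,
               alpha = a_meas, ahl_eff = inv$ahl, ahl_sd = inv$sd)
  })
  experiments <- do.call(rbind, rows)
  sd_use <- experiments$ahl_sd
  if (any(!is.finite(sd_use) | sd_use <= 0)) sd_use <- NULL
  cal <- fit_sender_strength(experiments$s, experiments$ahl_eff, sd = sd_use)
  truth <- 0.5 * params$alpha_a * params$alpha_l * params$N0
  list(experiments = experiments, calibration = cal, truth = truth)
}
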