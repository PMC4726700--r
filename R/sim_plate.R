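#' Simulate plate-reader absorbance/fluorescence time series
#'
#' Emulates a bulk induction experiment: cultures start at OD 0.1 and grow
#' logistically; the reporter accumulates as dF/dt = alpha(ahl) * M with
#' alpha the Hill response to the inducer concentration.  Measurements
#' every \code{sample_interval} minutes carry multiplicative noise.
#'
#' @param ahl_list inducer concentrations (nM), non-negative; the bulk
#'   experiments span 0-100 nM.
#' @param induction Hill parameters (default bulk preset:
#'   K = 13.9 nM, n = 0.97).
#' @param duration total time in minutes (default 900, i.e. 15 h).
#' @param sample_interval minutes between reads (default 5).
#' @param od0 initial absorbance (default 0.1).
#' @param od_max logistic carrying capacity (default 1.2).
#' @param mu_bulk bulk growth rate (1/h, default 1).
#' @param noise_cv multiplicative measurement noise CV on both channels
#'   (default 0.05; set 0 for noiseless series).
#' @param seed RNG seed.
#' @return data.frame with columns \code{ahl}, \code{t} (min), \code{M}
#'   (OD-like), \code{F} (a.u.).
#' @export
simulate_plate_reader <- function(ahl_list,
                                  induction = induction_preset("bulk"),
                                  duration = 900, sample_interval = 5,
                                  od0 = 0.1, od_max = 1.2, mu_bulk = 1,
                                  noise_cv = 0.05, seed = NULL) {
  if (length(ahl_list) == 0) stop("ahl_list must not be empty")
  if (any(ahl_list < 0)) stop("concentrations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = sample_interval)
  mu <- mu_bulk / 60                                   # 1/min
  M <- od_max / (1 + (od_max / od0 - 1) * exp(-mu * t))
  # closed-form integral of the logistic curve
  intM <- (od_max / mu) * log((od_max - od0 + od0 * exp(mu * t)) / od_max)
  out <- lapply(ahl_list, function(ahl) {
    a <- hill(ahl, induction$alpha_g, induction$K, induction$n,
              induction$basal)
    F <- a * intM
    Mn <- M; Fn <- F
    if (noise_cv > 0) {
      Mn <- M * (1 + stats::rnorm(length(t), 0, noise_cv))
      Fn <- F * (1 + stats::rnorm(length(t), 0, noise_cv))
    }
    data.frame(ahl = ahl, t = t, M = pmax(Mn, 1e-6), F = Fn)
  })
  do.call(rbind, out)
}

#' Bulk response curve from plate-reader tables
#'
#' For each inducer concentration, estimates alpha(t) = dF/dt / M over the
#' exponential-growth window and takes its maximum, reproducing the bulk
#' response-curve construction; then fits a Hill curve to alpha_max versus
#' concentration.
#'
#' @param plate data.frame from [simulate_plate_reader()] (columns ahl, t,
#'   M, F).
#' @param window,order Savitzky-Golay settings for [compute_alpha()].
#' @return list with \code{response} (data.frame ahl, alpha_max) and
#'   \code{fit} (a [fit_hill()] object).
#' @export
plate_response_curve <- function(plate, window = 7, order = 2) {
  stopifnot(all(c("ahl", "t", "M", "F") %in% names(plate)))
  concs <- sort(unique(plate$ahl))
  h <- (window - 1) %/% 2
  amax <- vapply(concs, function(cc) {
    d <- plate[plate$ahl == cc, ]
    d <- d[order(d$t), ]
    n <- nrow(d)
    alpha <- compute_alpha(d$t, d$F, d$M, window = window, order = order)
    interior <- (h + 1):(n - h)      # smoothed-derivative edges excluded
    win <- tryCatch(estimate_growth_rate(d$t, d$M, r2_min = 0.9)$window,
                    error = function(e) interior)
    win <- intersect(win, interior)
    if (length(win) == 0) win <- interior
    alpha_max(alpha, win)
  }, numeric(1))
  response <- data.frame(ahl = concs, alpha_max = amax)
  fit <- fit_hill(response$ahl, response$alpha_max)
  list(response = response, fit = fit)
}
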