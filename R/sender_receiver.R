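#' Default sender-receiver model parameters
#'
#' Parameters of the LuxI/AHL production model: sender cells express the AHL
#' synthase LuxI, which in turn produces the diffusible signal AHL; both
#' species are well mixed in the microchamber.  The model is
#' \deqn{d[LuxI]/dt = \alpha_l\, r\, N(t) - \lambda [LuxI]}
#' \deqn{d[AHL]/dt  = \alpha_a [LuxI] - C [AHL]}
#' with receiver population \eqn{N(t) = N_0 e^{\gamma t}} and sender/receiver
#' ratio \code{r} (possibly time dependent).
#'
#' @param alpha_l LuxI production rate per sender-equivalent per minute.
#' @param alpha_a AHL production rate per LuxI unit (nM/min per LuxI unit).
#' @param lambda LuxI degradation/dilution rate (1/min).
#' @param C_out AHL outflow rate from the chamber (1/min).
#' @param gamma receiver population growth rate (1/min).
#' @param N0 initial receiver count.
#' @param r sender/receiver ratio: a scalar or a function of time (min).
#' @return list of class \code{sender_params}.
#' @export
sender_params <- function(alpha_l = 1e-4, alpha_a = 0.04, lambda = 8e-4,
                          C_out = 8e-4, gamma = 1e-3, N0 = 50, r = 0.33) {
  num <- c(alpha_l = alpha_l, alpha_a = alpha_a, lambda = lambda,
           C_out = C_out, gamma = gamma, N0 = N0)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all sender parameters must be finite and non-negative")
  if (N0 < 1) stop("N0 must be at least 1")
  if (!is.function(r) && (!is.numeric(r) || length(r) != 1 || r < 0))
    stop("r must be a non-negative scalar or a function of time")
  structure(list(alpha_l = alpha_l, alpha_a = alpha_a, lambda = lambda,
                 C_out = C_out, gamma = gamma, N0 = N0, r = r),
            class = "sender_params")
}

#' Integrate the LuxI/AHL sender model
#'
#' Adaptive-step integration (lsoda, relative tolerance 1e-8) of the
#' two-variable LuxI/AHL system starting from [LuxI] = [AHL] = 0.
#'
#' @param params a [sender_params()] object.
#' @param t_grid output times in minutes, strictly increasing from 0.
#' @return data.frame with columns \code{t}, \code{luxi}, \code{ahl}.
#' @export
solve_sender_ode <- function(params, t_grid) {
  stopifnot(inherits(params, "sender_params"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (t_grid[1] != 0) t_grid <- c(0, t_grid)
  rfun <- if (is.function(params$r)) params$r else {
    r0 <- params$r; function(t) r0
  }
  deriv <- function(t, y, p) {
    N <- p$N0 * exp(p$gamma * t)
    dluxi <- p$alpha_l * rfun(t) * N - p$lambda * y[1]
    dahl <- p$alpha_a * y[1] - p$C_out * y[2]
    list(c(dluxi, dahl))
  }
  sol <- deSolve::ode(y = c(luxi = 0, ahl = 0), times = t_grid,
                      func = deriv, parms = params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  out$luxi <- pmax(out$luxi, 0)
  out$ahl <- pmax(out$ahl, 0)
  out
}

#' Quadratic closed-form AHL approximation
#'
#' In the limit of small growth, degradation and outflow rates the AHL
#' concentration produced by exponentially growing senders rises
#' quadratically, \eqn{[AHL](t) \simeq \tfrac12 \alpha_a \alpha_l r N_0 t^2}.
#'
#' @param params a [sender_params()] object (scalar \code{r}).
#' @param t time(s) in minutes, non-negative.
#' @return AHL concentration(s) in nM.
#' @export
ahl_closed_form <- function(params, t) {
  stopifnot(inherits(params, "sender_params"))
  if (any(t < 0)) stop("t must be non-negative")
  r <- if (is.function(params$r)) params$r(0) else params$r
  0.5 * params$alpha_a * params$alpha_l * r * params$N0 * t^2
}

#' Sender-strength parameter s
#'
#' Bundles the experiment-specific sender/receiver ratio history and
#' measurement time into \eqn{s = \langle r \rangle t_{max}^2}, where the
#' average ratio is the time-weighted (trapezoidal) mean of r(t) over
#' [0, t_max].
#'
#' @param r_series data.frame with columns \code{t} (min) and \code{r},
#'   covering [0, t_max].
#' @param t_max measurement time (min), positive.
#' @return list with \code{s} (min^2), \code{r_mean}, \code{t_max}.
#' @export
compute_s <- function(r_series, t_max) {
  stopifnot(is.data.frame(r_series), all(c("t", "r") %in% names(r_series)))
  if (nrow(r_series) == 0) stop("empty ratio series")
  if (t_max <= 0) stop("t_max must be positive")
  o <- order(r_series$t)
  t <- r_series$t[o]; r <- r_series$r[o]
  if (min(t) > 0 || max(t) < t_max)
    stop("r_series must cover the interval [0, t_max]")
  keep <- t <= t_max
  t2 <- t[keep]; r2 <- r[keep]
  if (max(t2) < t_max) {          # interpolate the endpoint
    r_end <- stats::approx(t, r, xout = t_max)$y
    t2 <- c(t2, t_max); r2 <- c(r2, r_end)
  }
  if (length(t2) < 2) stop("need at least two samples in [0, t_max]")
  integral <- sum(diff(t2) * (utils::head(r2, -1) + utils::tail(r2, -1)) / 2)
  r_mean <- integral / t_max
  list(s = r_mean * t_max^2, r_mean = r_mean, t_max = t_max)
}

#' Time of maximal sender induction
#'
#' Returns the time at which a (smoothed) sender reporter expression-rate
#' series attains its maximum; ties are broken towards the earlier time.
#'
#' @param t time points (min).
#' @param rate sender expression-rate series.
#' @param window,order Savitzky-Golay smoothing settings (window 7 default;
#'   set \code{window = 1} to disable smoothing).
#' @return t_max in minutes.
#' @export
detect_t_max <- function(t, rate, window = 7, order = 2) {
  stopifnot(length(t) == length(rate))
  sm <- rate
  if (window > 1 && length(rate) >= window)
    sm <- signal::sgolayfilt(rate, p = order, n = window, m = 0)
  if (max(sm) - min(sm) <= 1e-12 * max(abs(sm), 1))
    stop("rate series is flat: no induction maximum")
  t[which.max(sm)]
}

#' Calibrate sender strength from (s, effective AHL) pairs
#'
#' Weighted linear fit through the origin of \eqn{AHL_{eff} = slope \cdot s};
#' under the quadratic production law the slope identifies
#' \eqn{\tfrac12 \alpha_a \alpha_l N_0}.  A free-intercept diagnostic fit is
#' reported alongside.
#'
#' @param s sender-strength values (min^2), at least 3 distinct.
#' @param ahl_eff effective AHL concentrations (nM).
#' @param sd optional per-experiment standard deviations of \code{ahl_eff}.
#' @return list of class \code{sender_calibration}: \code{slope} (nM/min^2),
#'   \code{slope_se}, \code{residuals}, \code{intercept_diag} (free-intercept
#'   fit coefficients), \code{data}.
#' @export
fit_sender_strength <- function(s, ahl_eff, sd = NULL) {
  stopifnot(length(s) == length(ahl_eff))
  if (length(unique(s)) < 2 || length(s) < 3)
    stop("need at least 3 experiments with distinct s")
  w <- if (is.null(sd)) rep(1, length(s)) else {
    stopifnot(all(sd > 0)); 1 / sd^2
  }
  fit <- stats::lm(ahl_eff ~ 0 + s, weights = w)
  diag_fit <- stats::lm(ahl_eff ~ s, weights = w)
  structure(list(
    slope = unname(stats::coef(fit)[1]),
    slope_se = unname(sqrt(diag(stats::vcov(fit)))[1]),
    residuals = unname(stats::residuals(fit)),
    intercept_diag = stats::coef(diag_fit),
    data = data.frame(s = s, ahl_eff = ahl_eff, weight = w)),
    class = "sender_calibration")
}

#' @export
print.sender_calibration <- function(x, ...) {
  cat(sprintf("Sender-strength calibration: AHL_eff = %.4g * s (SE %.2g)\n",
              x$slope, x$slope_se))
  cat(sprintf("  free-intercept diagnostic: intercept %.3g, slope %.4g\n",
              x$intercept_diag[1], x$intercept_diag[2]))
  invisible(x)
}
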