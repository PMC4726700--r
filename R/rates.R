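#' Expression rate from a fluorescence time series
#'
#' Estimates the gene expression rate \eqn{\alpha(t) = \dot F / M} from a
#' fluorescence signal and a cell-mass proxy (OD-like absorbance in bulk,
#' total segmented cell area in microfluidic experiments).  The derivative
#' \eqn{\dot F} is computed by Savitzky-Golay smoothed differentiation.
#'
#' @param t time points (minutes), strictly increasing, uniformly spaced.
#' @param F fluorescence signal (arbitrary units), same length as \code{t}.
#' @param mass cell-mass proxy, positive, length 1 or \code{length(t)}.
#' @param window Savitzky-Golay window length (odd, default 7).
#' @param order Savitzky-Golay polynomial order (default 2).
#' @return numeric vector alpha(t), units a.u. per minute per mass unit.
#' @export
compute_alpha <- function(t, F, mass, window = 7, order = 2) {
  n <- length(t)
  stopifnot(length(F) == n, window %% 2 == 1, order < window)
  if (n < max(5, window)) stop("need at least as many samples as the window")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(mass <= 0)) stop("mass must be positive")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-8 * max(dt))
    stop("t must be uniformly spaced for Savitzky-Golay differentiation")
  Fdot <- sg_deriv(F, dt[1], window, order)
  Fdot / mass
}

# Savitzky-Golay first derivative with exact least-squares edge handling
sg_deriv <- function(x, dt, window, order) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  # interior: central convolution with the derivative filter row
  Fm <- signal::sgolay(p = order, n = window, m = 1, ts = dt)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    if (hi - lo + 1 < window) {
      # edge: local polynomial fit on the truncated window
      idx <- lo:hi
      tt <- (idx - i) * dt
      deg <- min(order, length(idx) - 1)
      fit <- stats::lm.fit(outer(tt, 0:deg, `^`), x[idx])
      out[i] <- if (deg >= 1) fit$coefficients[2] else 0
    } else {
      out[i] <- sum(Fm[h + 1, ] * x[(i - h):(i + h)])
    }
  }
  out
}

#' Self-consistency check of the rate identity
#'
#' For a stable reporter expressed during exponential growth the two rate
#' expressions \eqn{\dot F / M} and \eqn{d/dt(F/M) + \mu F/M} are identical;
#' this diagnostic returns their maximum absolute discrepancy over a window,
#' quantifying differentiation/noise error in the rate estimate.
#'
#' @param t time (minutes), uniform grid.
#' @param F fluorescence signal.
#' @param M mass proxy, positive, same length.
#' @param mu growth rate in 1/min (note: per minute, matching \code{t}).
#' @param window,order Savitzky-Golay settings, as in [compute_alpha()].
#' @param relative if \code{TRUE}, normalise by the maximum |dF/dt / M|.
#' @return maximum (relative) deviation over the series.
#' @export
verify_rate_identity <- function(t, F, M, mu, window = 7, order = 2,
                                 relative = TRUE) {
  stopifnot(length(F) == length(t), length(M) == length(t), all(M > 0))
  dt <- diff(t)
  lhs <- sg_deriv(F, dt[1], window, order) / M
  rhs <- sg_deriv(F / M, dt[1], window, order) + mu * F / M
  dev <- max(abs(lhs - rhs))
  if (relative) {
    scale <- max(abs(lhs))
    if (scale > 0) dev <- dev / scale
  }
  dev
}

#' Summary rate statistics over the exponential window
#'
#' \code{alpha_max} returns the maximum and \code{alpha_mean} the time
#' average of a rate series over a window (by default the whole series);
#' used as per-colony or per-trajectory induction measures.
#'
#' @param alpha rate series.
#' @param window optional logical or integer index vector selecting the
#'   exponential-phase samples.
#' @return scalar statistic.
#' @export
alpha_max <- function(alpha, window = NULL) {
  a <- if (is.null(window)) alpha else alpha[window]
  a <- a[is.finite(a)]
  if (length(a) == 0) stop("empty window")
  max(a)
}

#' @rdname alpha_max
#' @export
alpha_mean <- function(alpha, window = NULL) {
  a <- if (is.null(window)) alpha else alpha[window]
  a <- a[is.finite(a)]
  if (length(a) == 0) stop("empty window")
  mean(a)
}

#' Estimate the exponential growth rate from a mass time series
#'
#' Computes a smoothed local slope of log(mass) (Savitzky-Golay first
#' derivative over roughly a quarter of the series), takes its maximum as
#' the specific growth rate mu, and reports as the exponential-phase
#' window the contiguous stretch around the maximum where the local slope
#' stays within 80% of it.  An error is raised when no growing log-linear
#' stretch exists (e.g. saturated-only data: the selected window fails the
#' \code{r2_min} log-linearity check).
#'
#' @param t time (minutes), uniformly spaced.
#' @param mass positive mass proxy (area, OD).
#' @param r2_min minimum R^2 of log(mass) vs t over the selected window.
#' @param min_points minimum series and window length.
#' @return list with \code{mu} (1/h), \code{window} (index range),
#'   \code{r2} (over the window).
#' @export
estimate_growth_rate <- function(t, mass, r2_min = 0.98, min_points = 10) {
  stopifnot(length(t) == length(mass))
  if (any(mass <= 0)) stop("mass must be positive")
  n <- length(t)
  if (n < min_points) stop("series shorter than min_points")
  y <- log(mass)
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-8 * max(dt))
    stop("t must be uniformly spaced")
  w <- max(min_points + (min_points + 1) %% 2, min(round(n / 4), 41))
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, n - (n + 1) %% 2)
  slope <- sg_deriv(y, dt[1], w, 2)
  smax <- max(slope)
  if (smax <= 0)
    stop("no growing log-linear window found (mass never increases)")
  i_max <- which.max(slope)
  lo <- i_max
  while (lo > 1 && slope[lo - 1] >= 0.8 * smax) lo <- lo - 1
  hi <- i_max
  while (hi < n && slope[hi + 1] >= 0.8 * smax) hi <- hi + 1
  if (hi - lo + 1 < min_points) {
    lo <- max(1, i_max - min_points %/% 2)
    hi <- min(n, lo + min_points - 1)
  }
  window <- lo:hi
  fit <- stats::lm.fit(cbind(1, t[window]), y[window])
  r2 <- 1 - sum(fit$residuals^2) /
    max(sum((y[window] - mean(y[window]))^2), 1e-300)
  if (r2 < r2_min)
    stop("no log-linear growth window found (R^2 >= ", r2_min, ")")
  list(mu = smax * 60, window = window, r2 = r2)
}
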