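#' Hill dose-response function
#'
#' Evaluates the activating Hill function used throughout the AHL/P_lux
#' response analysis,
#' \deqn{\alpha(c) = basal + \alpha_g \frac{c^n}{c^n + K^n},}
#' where \code{K} is the half-induction threshold (nM) and \code{n} the
#' cooperativity exponent.
#'
#' @param conc inducer concentrations (nM), non-negative.
#' @param alpha_g maximal rate above basal (response units).
#' @param K half-induction threshold (nM), positive.
#' @param n Hill exponent, positive.
#' @param basal basal rate at zero inducer (default 0).
#' @return numeric vector of responses, same length as \code{conc}.
#' @examples
#' hill(c(0, 10, 1e6), alpha_g = 1, K = 10, n = 1)
#' @export
hill <- function(conc, alpha_g, K, n, basal = 0) {
  stopifnot(K > 0, n > 0, alpha_g >= 0, basal >= 0)
  if (any(conc < 0)) stop("concentrations must be non-negative")
  frac <- ifelse(conc == 0, 0, 1 / (1 + (K / conc)^n))
  basal + alpha_g * frac
}

#' Fit a Hill response curve
#'
#' Weighted least-squares fit of \code{basal + alpha_g * c^n / (c^n + K^n)}
#' to measured responses versus inducer concentration.  The optimiser
#' (Levenberg-Marquardt, \code{minpack.lm}) is multi-started over a grid of
#' (K, n) values to avoid local minima; the basal term is bounded below by 0.
#'
#' @param conc inducer concentrations (nM); at least 4 distinct values.
#' @param response measured responses (e.g. alpha_max per concentration).
#' @param sd optional per-point standard deviations used as weights
#'   (1/sd^2).  Non-positive or missing entries are replaced by the smallest
#'   positive sd (uniform weights if none).
#' @param fixed_basal if \code{TRUE}, fixes the basal term at 0.
#' @return object of class \code{hill_fit}: list with \code{coefficients}
#'   (alpha_g, K, n, basal), \code{se}, \code{vcov}, \code{fitted},
#'   \code{residuals}, \code{converged}.
#' @seealso [invert_hill()] for mapping a measured rate back to an effective
#'   concentration.
#' @export
fit_hill <- function(conc, response, sd = NULL, fixed_basal = FALSE) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  ok <- is.finite(conc) & is.finite(response)
  conc <- conc[ok]; response <- response[ok]
  w <- rep(1, length(conc))
  if (!is.null(sd)) {
    sd <- sd[ok]
    pos <- is.finite(sd) & sd > 0
    if (any(pos)) sd[!pos] <- min(sd[pos])
    if (any(pos)) w <- 1 / sd^2
  }

  rng <- max(response) - min(response)
  if (rng <= 0) rng <- max(abs(response), 1)
  cpos <- sort(unique(conc[conc > 0]))
  k_starts <- unique(pmax(stats::quantile(cpos, c(0.25, 0.5, 0.75),
                                          names = FALSE), 1e-6))
  n_starts <- c(0.5, 1, 2)
  b0 <- max(min(response), 0)

  df <- data.frame(conc = conc, response = response)
  best <- NULL
  for (k0 in k_starts) for (n0 in n_starts) {
    fit <- tryCatch({
      if (fixed_basal) {
        minpack.lm::nlsLM(
          response ~ ag * ifelse(conc == 0, 0, 1 / (1 + (K / conc)^n)),
          data = df, weights = w,
          start = list(ag = rng, K = k0, n = n0),
          lower = c(0, 1e-9, 0.05), upper = c(Inf, Inf, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          response ~ b + ag * ifelse(conc == 0, 0, 1 / (1 + (K / conc)^n)),
          data = df, weights = w,
          start = list(b = b0, ag = rng, K = k0, n = n0),
          lower = c(0, 0, 1e-9, 0.05), upper = c(Inf, Inf, Inf, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed from all starts")
  fit <- best$fit

  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(cf), length(cf), dimnames = list(names(cf), names(cf)))
  })
  se <- sqrt(pmax(diag(V), 0))
  if (fixed_basal) {
    coefs <- c(alpha_g = unname(cf["ag"]), K = unname(cf["K"]),
               n = unname(cf["n"]), basal = 0)
    ses <- c(alpha_g = unname(se["ag"]), K = unname(se["K"]),
             n = unname(se["n"]), basal = 0)
  } else {
    coefs <- c(alpha_g = unname(cf["ag"]), K = unname(cf["K"]),
               n = unname(cf["n"]), basal = unname(cf["b"]))
    ses <- c(alpha_g = unname(se["ag"]), K = unname(se["K"]),
             n = unname(se["n"]), basal = unname(se["b"]))
  }
  fv <- hill(conc, coefs["alpha_g"], coefs["K"], coefs["n"], coefs["basal"])
  res <- response - fv
  # convergence warning for responses that are non-monotone beyond noise
  conv <- TRUE
  mono <- stats::cor(conc, response, method = "spearman")
  if (is.finite(mono) && mono < 0.2) {
    warning("response is not monotone in concentration; fit may be unreliable")
    conv <- FALSE
  }
  structure(list(coefficients = coefs, se = ses, vcov = V,
                 data = df, weights = w, fitted = fv, residuals = res,
                 converged = conv, fixed_basal = fixed_basal),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit: alpha(c) = basal + alpha_g * c^n / (c^n + K^n)\n")
  m <- rbind(estimate = x$coefficients, se = x$se)
  print(round(m, 4))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, conc, ...) {
  cf <- object$coefficients
  hill(conc, cf["alpha_g"], cf["K"], cf["n"], cf["basal"])
}

#' Invert a Hill calibration curve to an effective inducer concentration
#'
#' Maps a measured expression rate back through a fitted receiver response
#' curve, yielding the effective AHL concentration a bioreporter cell was
#' exposed to:
#' \deqn{AHL_{eff} = K \left(\frac{\alpha - b}{(\alpha_g + b) - \alpha}\right)^{1/n}.}
#' Uncertainty is propagated to first order (delta method) from the fit
#' covariance and, optionally, the standard deviation of the measured rate.
#'
#' @param alpha measured rate, in the same units as the calibration responses.
#' @param fit a [fit_hill()] result.
#' @param alpha_sd optional standard deviation of \code{alpha}.
#' @return list with \code{ahl} (nM), \code{sd} (nM, \code{NA} if the fit
#'   covariance is unavailable), and \code{below_basal} flag.
#' @export
invert_hill <- function(alpha, fit, alpha_sd = 0) {
  stopifnot(inherits(fit, "hill_fit"), length(alpha) == 1)
  cf <- fit$coefficients
  ag <- cf[["alpha_g"]]; K <- cf[["K"]]; n <- cf[["n"]]; b <- cf[["basal"]]
  sat <- ag + b
  if (alpha >= sat) stop("rate at or above saturation: Hill curve not invertible")
  if (alpha <= b) return(list(ahl = 0, sd = 0, below_basal = TRUE))
  ratio <- (alpha - b) / (sat - alpha)
  ahl <- K * ratio^(1 / n)

  # delta method: gradient of ahl wrt (alpha_g, K, n, basal, alpha)
  dK <- ratio^(1 / n)
  dn <- -K * ratio^(1 / n) * log(ratio) / n^2
  d_dalpha <- K / n * ratio^(1 / n - 1) * sat_grad(alpha, b, sat)
  d_dag <- K / n * ratio^(1 / n - 1) * (-(alpha - b) / (sat - alpha)^2)
  d_db <- K / n * ratio^(1 / n - 1) *
    (-(sat - alpha) - (alpha - b)) / (sat - alpha)^2
  g <- c(d_dag, dK, dn, d_db)
  V <- fit$vcov
  sd_out <- NA_real_
  if (!anyNA(V)) {
    if (fit$fixed_basal) { g4 <- g[1:3]; V4 <- V } else {
      # vcov order is (b, ag, K, n)
      g4 <- c(g[4], g[1], g[2], g[3]); V4 <- V
    }
    var_fit <- drop(t(g4) %*% V4 %*% g4)
    sd_out <- sqrt(max(var_fit, 0) + (d_dalpha * alpha_sd)^2)
  }
  list(ahl = unname(ahl), sd = unname(sd_out), below_basal = FALSE)
}

# d(ratio)/d(alpha) where ratio = (alpha-b)/(sat-alpha)
sat_grad <- function(alpha, b, sat) {
  ((sat - alpha) + (alpha - b)) / (sat - alpha)^2
}
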