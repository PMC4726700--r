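#' Lognormal maximum-likelihood fit
#'
#' MLE of a lognormal distribution (mean and SD of the log values) with a
#' Kolmogorov-Smirnov goodness-of-fit statistic against the fitted
#' distribution.
#'
#' @param values positive observations, at least 20.
#' @return list with \code{meanlog}, \code{sdlog}, \code{ks_stat}, \code{n},
#'   and the implied \code{cv} = sqrt(exp(sdlog^2) - 1).
#' @export
fit_lognormal_mle <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 20) stop("need at least 20 values")
  if (any(values <= 0)) stop("lognormal fit requires positive values")
  lx <- log(values)
  m <- mean(lx)
  s <- sqrt(mean((lx - m)^2))   # MLE (biased) variant
  ks <- suppressWarnings(
    stats::ks.test(values, stats::plnorm, meanlog = m, sdlog = s)$statistic)
  list(meanlog = m, sdlog = s, ks_stat = unname(ks),
       n = length(values), cv = sqrt(exp(s^2) - 1))
}

#' Two-component Gaussian mixture on log expression values
#'
#' Separates a minority "late-inducer" subpopulation from the dominant
#' induced population by EM fitting of a two-component Gaussian mixture to
#' the logarithm of per-cell expression values, as in time-slice histograms
#' of F/A.  EM is restarted from several random initialisations; a BIC
#' comparison against a single Gaussian guards degenerate cases.  The
#' dominant component is the higher-mean one when the weights are comparable
#' (both in [0.25, 0.75]), otherwise the higher-weight one.
#'
#' @param values positive expression values (e.g. p = F/A), n >= 50.
#' @param restarts number of random EM restarts (default 10).
#' @param seed optional RNG seed for the restarts.
#' @param max_iter,tol EM iteration controls.
#' @return list of class \code{log_gmm} with \code{weights}, \code{means},
#'   \code{sds} (log scale), \code{assignment} ("dominant"/"late" per cell),
#'   \code{responsibility} (n x 2), \code{dominant} (component index),
#'   \code{loglik}, \code{loglik_trace}, \code{k} (1 or 2 after BIC guard).
#' @export
gmm_separate_log <- function(values, restarts = 10, seed = NULL,
                             max_iter = 500, tol = 1e-8) {
  values <- values[is.finite(values)]
  if (any(values <= 0)) stop("mixture fitting requires positive values")
  n <- length(values)
  if (n < 50) stop("need at least 50 values")
  if (!is.null(seed)) set.seed(seed)
  x <- log(values)

  best <- NULL
  for (rep in seq_len(restarts)) {
    init <- em_init(x, rep)
    fit <- tryCatch(em_1d(x, init, max_iter, tol), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  single <- list(weights = 1, means = mean(x),
                 sds = max(stats::sd(x), 1e-12),
                 loglik = sum(stats::dnorm(x, mean(x),
                                           max(stats::sd(x), 1e-12),
                                           log = TRUE)))
  if (is.null(best)) {
    warning("EM did not converge from any restart; single-component fallback")
    return(gmm_single(x, single, n))
  }
  bic2 <- -2 * best$loglik + 5 * log(n)
  bic1 <- -2 * single$loglik + 2 * log(n)
  if (bic1 <= bic2) return(gmm_single(x, single, n))
  # overlap guard: two heavily overlapping components (or a vanishing
  # one) describe a single population, not a subpopulation split
  sep <- abs(diff(best$means)) / max(min(best$sds), 1e-12)
  if (sep < 3 || min(best$weights) < 0.02)
    return(gmm_single(x, single, n))

  w <- best$weights; mu <- best$means; sd <- best$sds
  dominant <- if (min(w) >= 0.25 && max(w) <= 0.75) which.max(mu) else
    which.max(w)
  resp <- best$resp
  assign <- ifelse(max.col(resp) == dominant, "dominant", "late")
  structure(list(weights = w, means = mu, sds = sd,
                 assignment = assign, responsibility = resp,
                 dominant = dominant, loglik = best$loglik,
                 loglik_trace = best$trace, k = 2L, logdata = x),
            class = "log_gmm")
}

gmm_single <- function(x, single, n) {
  structure(list(weights = 1, means = single$means, sds = single$sds,
                 assignment = rep("dominant", n),
                 responsibility = matrix(1, n, 1),
                 dominant = 1L, loglik = single$loglik,
                 loglik_trace = single$loglik, k = 1L, logdata = x),
            class = "log_gmm")
}

em_init <- function(x, rep) {
  if (rep == 1) {            # quantile split init (deterministic)
    q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  } else {
    q <- sort(sample(x, 2))
  }
  s0 <- max(stats::sd(x) / 2, 1e-6)
  list(w = c(0.5, 0.5), mu = q, sd = c(s0, s0))
}

# plain 1-D two-component EM; returns loglik trace for monotonicity checks
em_1d <- function(x, init, max_iter, tol) {
  n <- length(x)
  w <- init$w; mu <- init$mu; sd <- init$sd
  min_sd <- max(diff(range(x)) * 1e-4, 1e-10)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) stop("degenerate component")
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    r1 <- d1 / tot
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("component collapsed")
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sd <- c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
            sqrt(sum((1 - r1) * (x - mu[2])^2) / n2))
    sd <- pmax(sd, min_sd)
    w <- c(n1, n2) / n
  }
  resp <- cbind(r1, 1 - r1)
  list(weights = w, means = mu, sds = sd, resp = resp,
       loglik = trace[length(trace)], trace = trace)
}

#' Restrict trajectories to the dominant subpopulation
#'
#' Classifies cells by their expression level at the end of the experiment
#' (Gaussian mixture on log terminal p = F/A) and keeps only trajectories
#' whose terminal cell belongs to the dominant component; ancestors of kept
#' cells are retained so rate computation along lineages stays consistent.
#'
#' @param traj trajectory table: data.frame with columns \code{cell_id},
#'   \code{frame}, \code{t_min}, \code{area}, \code{F}, \code{parent_id}
#'   (NA for roots).  Terminal cells are those present in the last frame.
#' @param seed RNG seed forwarded to the mixture fit.
#' @param min_cells below this many terminal cells the filter keeps all
#'   trajectories (with a warning).
#' @return list with \code{trajectories} (filtered table), \code{kept_ids},
#'   \code{mixture} (the [gmm_separate_log()] fit, or NULL).
#' @export
dominant_filter <- function(traj, seed = NULL, min_cells = 50) {
  need <- c("cell_id", "frame", "area", "F")
  stopifnot(is.data.frame(traj), all(need %in% names(traj)))
  last <- max(traj$frame)
  term <- traj[traj$frame == last & traj$area > 0, ]
  p <- term$F / term$area
  ids <- term$cell_id
  usable <- is.finite(p) & p > 0
  if (sum(usable) < min_cells) {
    warning("too few positive terminal cells for mixture filtering; keeping all")
    return(list(trajectories = traj, kept_ids = unique(traj$cell_id),
                mixture = NULL))
  }
  mix <- gmm_separate_log(p[usable], seed = seed)
  kept <- ids[usable][mix$assignment == "dominant"]
  if (length(kept) == 0) stop("no dominant component found")
  # lineage closure: keep all ancestors of kept terminal cells
  if ("parent_id" %in% names(traj)) {
    parent_of <- traj$parent_id[match(unique(traj$cell_id), traj$cell_id)]
    names(parent_of) <- unique(traj$cell_id)
    keep_set <- as.character(kept)
    frontier <- keep_set
    while (length(frontier) > 0) {
      pars <- parent_of[frontier]
      pars <- as.character(pars[!is.na(pars) & pars > 0])
      frontier <- setdiff(pars, keep_set)
      keep_set <- union(keep_set, frontier)
    }
    kept_all <- as.numeric(keep_set)
  } else kept_all <- kept
  list(trajectories = traj[traj$cell_id %in% kept_all, ],
       kept_ids = sort(kept_all), mixture = mix)
}

#' Time-resolved expression noise curve
#'
#' Computes per-snapshot mean and variance of per-cell expression p = F/A
#' and the fractional noise CV^2(t) = var/mean^2, optionally restricted to
#' the dominant subpopulation (mixture per snapshot).  The plateau estimate
#' is the median CV^2 over snapshots whose mean has reached at least
#' \code{plateau_frac} of the maximal mean expression.
#'
#' @param snapshots list of numeric vectors (per-cell p values, one vector
#'   per time point) or a data.frame with columns \code{t}, \code{p}.
#' @param t optional time vector when \code{snapshots} is a list.
#' @param dominant_only if \code{TRUE}, fit a log-Gaussian mixture per
#'   snapshot and use only cells assigned to the dominant component.
#' @param min_cells snapshots with fewer cells are skipped with a warning.
#' @param plateau_frac fraction of the maximal mean defining the plateau
#'   region (default 1/3).
#' @param seed RNG seed for the per-snapshot mixture fits.
#' @return list of class \code{noise_curve}: data.frame \code{curve}
#'   (t, mean, var, cv2, n), \code{plateau_cv2}, \code{plateau_cv}.
#' @export
noise_curve <- function(snapshots, t = NULL, dominant_only = FALSE,
                        min_cells = 20, plateau_frac = 1 / 3, seed = NULL) {
  if (is.data.frame(snapshots)) {
    stopifnot(all(c("t", "p") %in% names(snapshots)))
    t <- sort(unique(snapshots$t))
    snapshots <- lapply(t, function(tt) snapshots$p[snapshots$t == tt])
  }
  if (is.null(t)) t <- seq_along(snapshots)
  stopifnot(length(t) == length(snapshots))
  rows <- lapply(seq_along(snapshots), function(i) {
    p <- snapshots[[i]]
    p <- p[is.finite(p)]
    if (length(p) < min_cells) {
      warning("snapshot ", i, " has fewer than ", min_cells,
              " cells; skipped")
      return(NULL)
    }
    if (dominant_only && all(p > 0) && length(p) >= 50) {
      mix <- gmm_separate_log(p, seed = seed)
      p <- p[mix$assignment == "dominant"]
    }
    m <- mean(p); v <- stats::var(p)
    data.frame(t = t[i], mean = m, var = v,
               cv2 = if (m > 0) v / m^2 else NA_real_, n = length(p))
  })
  curve <- do.call(rbind, rows)
  if (is.null(curve) || nrow(curve) == 0) stop("no usable snapshots")
  sel <- curve$mean >= plateau_frac * max(curve$mean)
  plateau_cv2 <- stats::median(curve$cv2[sel], na.rm = TRUE)
  structure(list(curve = curve, plateau_cv2 = plateau_cv2,
                 plateau_cv = sqrt(plateau_cv2)),
            class = "noise_curve")
}

#' @export
print.noise_curve <- function(x, ...) {
  cat(sprintf("Noise curve over %d snapshots; plateau CV^2 = %.4f (CV = %.3f)\n",
              nrow(x$curve), x$plateau_cv2, x$plateau_cv))
  invisible(x)
}
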