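#' @keywords internal
# Rod (spherocylinder) area in um^2 for length L (tip to tip) and width w.
rod_area <- function(length, width) {
  pmax(length - width, 0) * width + pi * width^2 / 4
}

new_cell_rates <- function(n, v_kin) {
  s <- sqrt(v_kin / 4)
  matrix(stats::rnorm(4 * n, 0, s), ncol = 4,
         dimnames = list(NULL, c("d_ar", "d_lr", "d_ap", "d_lp")))
}

#' Initialise a colony of rod cells
#'
#' Places founder cells near the trap centre with random orientations and
#' assigns phenotypes (late inducer with probability
#' \code{late_inducer_fraction}) and roles (sender with probability
#' \code{sender_fraction}).  Per-cell kinetic-rate deviations are drawn
#' lognormally (four independent rates whose product sets the cell's
#' steady-state expression factor).
#'
#' @param config a [sim_config()].
#' @param n number of founder cells (default \code{config$init_cells}).
#' @return colony data.frame (one row per cell).
#' @export
colony_init <- function(config, n = config$init_cells) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  nb <- noise_budget(config)
  W <- config$trap_size[1]; H <- config$trap_size[2]
  spread <- min(W, H) / 4
  rates <- new_cell_rates(n, nb$v_kin)
  df <- data.frame(
    cell_id = seq_len(n),
    parent_id = NA_real_,
    x = W / 2 + stats::runif(n, -spread, spread),
    y = H / 2 + stats::runif(n, -spread, spread),
    theta = stats::runif(n, 0, pi),
    length = config$division_length *
      stats::runif(n, 0.55, 0.95),
    width = config$cell_width,
    role = ifelse(stats::runif(n) < config$sender_fraction,
                  "sender", "receiver"),
    phenotype = ifelse(stats::runif(n) < config$late_inducer_fraction,
                       "late_inducer", "normal"),
    p = 0,
    ou = stats::rnorm(n, 0, sqrt(nb$v_ou)),
    birth_t = 0
  )
  cbind(df, rates)
}

#' Advance colony mechanics by one time step
#'
#' Cells elongate exponentially at the configured growth rate (late
#' inducers at a reduced rate), divide once they reach the division length
#' (length split with the configured asymmetry CV, kinetic rates partially
#' re-randomised in the daughters), and overlapping rods are relaxed by
#' iterative pairwise repulsion.  Cells pushed beyond the trap bounds leave
#' through the open trap edges and are removed.
#'
#' @param colony colony data.frame from [colony_init()] or a previous step.
#' @param config a [sim_config()].
#' @param dt time step in minutes.
#' @param next_id first cell_id to assign to newborn cells (default: one
#'   beyond the current maximum).
#' @return list with \code{colony} (updated data.frame), \code{next_id},
#'   \code{divisions} (data.frame parent/child ids this step).
#' @export
step_colony <- function(colony, config, dt, next_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (dt <= 0) stop("dt must be positive")
  if (nrow(colony) == 0) stop("empty colony")
  if (is.null(next_id)) next_id <- max(colony$cell_id) + 1
  nb <- noise_budget(config)
  mu_min <- config$growth_rate / 60
  fac <- ifelse(colony$phenotype == "late_inducer",
                config$late_inducer_growth_factor, 1)
  colony$length <- colony$length * exp(mu_min * fac * dt)

  # divisions
  div_rows <- which(colony$length >= config$division_length)
  divisions <- data.frame(parent = numeric(0), child1 = numeric(0),
                          child2 = numeric(0))
  if (length(div_rows) > 0) {
    kids <- vector("list", length(div_rows))
    for (k in seq_along(div_rows)) {
      i <- div_rows[k]
      L <- colony$length[i]; w <- colony$width[i]
      f <- 0.5 * (1 + stats::rnorm(1, 0, 2 * config$division_asymmetry_cv))
      f <- min(max(f, 0.3), 0.7)
      L1 <- f * L; L2 <- (1 - f) * L
      u <- c(cos(colony$theta[i]), sin(colony$theta[i]))
      c0 <- c(colony$x[i], colony$y[i])
      # daughters centred on their halves of the mother axis
      c1 <- c0 + u * (L / 2 - L1 / 2)
      c2 <- c0 - u * (L / 2 - L2 / 2)
      w_mix <- config$rate_mixing
      par_rates <- as.numeric(colony[i, c("d_ar", "d_lr", "d_ap", "d_lp")])
      kid_rates <- t(vapply(1:2, function(j) {
        w_mix * par_rates +
          sqrt(1 - w_mix^2) * stats::rnorm(4, 0, sqrt(nb$v_kin / 4))
      }, numeric(4)))
      colnames(kid_rates) <- c("d_ar", "d_lr", "d_ap", "d_lp")
      th <- colony$theta[i] + stats::rnorm(2, 0, 0.05)
      kid <- data.frame(
        cell_id = c(next_id, next_id + 1),
        parent_id = colony$cell_id[i],
        x = c(c1[1], c2[1]), y = c(c1[2], c2[2]),
        theta = th,
        length = c(L1, L2), width = w,
        role = colony$role[i], phenotype = colony$phenotype[i],
        p = colony$p[i],                  # concentration conserved
        ou = colony$ou[i],
        birth_t = NA_real_)
      kid <- cbind(kid, kid_rates)
      kids[[k]] <- kid
      divisions <- rbind(divisions,
                         data.frame(parent = colony$cell_id[i],
                                    child1 = next_id, child2 = next_id + 1))
      next_id <- next_id + 2
    }
    colony <- rbind(colony[-div_rows, ], do.call(rbind, kids))
  }

  colony <- relax_overlaps(colony, config)

  # open trap edges: cells whose centre leaves the trap are washed away
  W <- config$trap_size[1]; H <- config$trap_size[2]
  inside <- colony$x >= 0 & colony$x <= W & colony$y >= 0 & colony$y <= H
  colony <- colony[inside, ]
  rownames(colony) <- NULL
  list(colony = colony, next_id = next_id, divisions = divisions)
}

# Iterative pairwise repulsion of overlapping rods.  Each rod is
# approximated by a chain of discs along its axis; overlapping discs of
# different cells push the two cells apart symmetrically.
relax_overlaps <- function(colony, config) {
  n <- nrow(colony)
  if (n < 2) return(colony)
  w <- config$cell_width * 1.05           # small target separation
  for (iter in seq_len(config$relax_iters)) {
    nd <- pmax(2L, pmin(6L, ceiling(colony$length / w)))
    cell_idx <- rep.int(seq_len(n), nd)
    frac <- unlist(lapply(nd, function(k) seq(-0.5, 0.5, length.out = k)))
    half <- (colony$length[cell_idx] - w) / 2
    ux <- cos(colony$theta[cell_idx]); uy <- sin(colony$theta[cell_idx])
    px <- colony$x[cell_idx] + 2 * frac * half * ux
    py <- colony$y[cell_idx] + 2 * frac * half * uy

    # candidate cell pairs by centre distance
    dx <- outer(colony$x, colony$x, `-`)
    dy <- outer(colony$y, colony$y, `-`)
    cut <- outer(colony$length, colony$length, `+`) / 2 + w
    cand <- which(upper.tri(dx) & dx^2 + dy^2 < cut^2, arr.ind = TRUE)
    if (nrow(cand) == 0) break

    disp_x <- numeric(n); disp_y <- numeric(n); cnt <- numeric(n)
    disc_of <- split(seq_along(cell_idx), cell_idx)
    moved <- FALSE
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      di <- disc_of[[i]]; dj <- disc_of[[j]]
      ddx <- outer(px[di], px[dj], `-`)
      ddy <- outer(py[di], py[dj], `-`)
      d2 <- ddx^2 + ddy^2
      m <- which.min(d2)
      dmin <- sqrt(d2[m])
      overlap <- w - dmin
      if (overlap > 1e-6) {
        if (dmin < 1e-9) { dirx <- 1; diry <- 0 } else {
          dirx <- ddx[m] / dmin; diry <- ddy[m] / dmin
        }
        push <- overlap / 2 * 0.9
        disp_x[i] <- disp_x[i] + push * dirx
        disp_y[i] <- disp_y[i] + push * diry
        disp_x[j] <- disp_x[j] - push * dirx
        disp_y[j] <- disp_y[j] - push * diry
        cnt[i] <- cnt[i] + 1; cnt[j] <- cnt[j] + 1
        moved <- TRUE
      }
    }
    if (!moved) break
    adj <- cnt > 0
    colony$x[adj] <- colony$x[adj] + disp_x[adj] / cnt[adj]
    colony$y[adj] <- colony$y[adj] + disp_y[adj] / cnt[adj]
  }
  colony
}

#' Advance per-cell reporter expression by one time step
#'
#' Each cell's instantaneous expression rate is the Hill response to the
#' ambient AHL concentration, multiplied by the cell's lognormal kinetic
#' factor (product of its four birth-sampled rates) and a slowly varying
#' extrinsic Ornstein-Uhlenbeck factor.  The reporter amount per unit area
#' p follows the dilution dynamics p_dot = alpha - mu p (Euler step).  Late
#' inducers express nothing before \code{late_inducer_delay} and at a
#' reduced rate afterwards.
#'
#' @param colony colony data.frame.
#' @param config a [sim_config()].
#' @param ahl ambient AHL concentration (nM), non-negative.
#' @param dt time step (min), positive.
#' @param t current absolute time (min), used for the late-inducer delay.
#' @return updated colony data.frame (new \code{p} and \code{ou} columns).
#' @export
step_expression <- function(colony, config, ahl, dt, t = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (dt <= 0) stop("dt must be positive")
  if (ahl < 0) stop("ahl must be non-negative")
  n <- nrow(colony)
  if (n == 0) return(colony)
  nb <- noise_budget(config)

  # OU update (exact discretisation of the stationary process)
  a <- exp(-dt / config$extrinsic_tau)
  colony$ou <- colony$ou * a +
    stats::rnorm(n, 0, sqrt(nb$v_ou * (1 - a^2)))

  ind <- config$induction
  base <- hill(ahl, ind$alpha_g, ind$K, ind$n, ind$basal)
  kin <- with(colony, d_ar - d_lr + d_ap - d_lp)
  r_fac <- exp(kin - nb$v_kin / 2)
  x_fac <- exp(colony$ou - nb$v_ou / 2)
  alpha <- base * r_fac * x_fac
  late <- colony$phenotype == "late_inducer"
  alpha[late] <- ifelse(t + dt < config$late_inducer_delay, 0,
                        alpha[late] * config$late_inducer_alpha_factor)
  mu_min <- config$growth_rate / 60 *
    ifelse(late, config$late_inducer_growth_factor, 1)
  colony$p <- pmax(colony$p + dt * (alpha - mu_min * colony$p), 0)
  attr(colony, "alpha") <- alpha
  colony
}

#' Simulate a microcolony time course
#'
#' Runs the colony simulator for \code{config$duration} minutes at the
#' given AHL concentration, recording the full state at every frame
#' together with the lineage and ground-truth trajectories.
#'
#' @param config a [sim_config()].
#' @param ahl ambient AHL concentration (nM).
#' @param seed RNG seed (overrides \code{config$rng_seed}).
#' @return list of class \code{colony_sim}: \code{frames} (list of colony
#'   data.frames), \code{t} (minutes per frame), \code{trajectories}
#'   (long data.frame: cell_id, frame, t_min, area, F, p, alpha, phenotype,
#'   role, parent_id), \code{lineage} (cell_id, parent_id), \code{config}.
#' @export
simulate_colony <- function(config, ahl = 0, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  dt <- config$frame_interval
  times <- seq(0, config$duration, by = dt)
  colony <- colony_init(config)
  next_id <- max(colony$cell_id) + 1
  frames <- vector("list", length(times))
  frames[[1]] <- colony
  alphas <- vector("list", length(times))
  alphas[[1]] <- rep(0, nrow(colony))
  for (k in seq_along(times)[-1]) {
    st <- step_colony(colony, config, dt, next_id)
    colony <- st$colony; next_id <- st$next_id
    if (nrow(colony) == 0) {
      frames <- frames[seq_len(k - 1)]
      times <- times[seq_len(k - 1)]
      warning("colony went extinct (all cells left the trap)")
      break
    }
    colony <- step_expression(colony, config, ahl, dt, t = times[k - 1])
    frames[[k]] <- colony
    alphas[[k]] <- attr(colony, "alpha")
  }

  traj <- do.call(rbind, lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    data.frame(cell_id = fr$cell_id, frame = k, t_min = times[k],
               area = rod_area(fr$length, fr$width),
               p = fr$p,
               F = fr$p * rod_area(fr$length, fr$width),
               alpha = alphas[[k]],
               phenotype = fr$phenotype, role = fr$role,
               parent_id = fr$parent_id)
  }))
  lin <- unique(traj[, c("cell_id", "parent_id")])
  rownames(lin) <- NULL
  structure(list(frames = frames, t = times, trajectories = traj,
                 lineage = lin, ahl = ahl, config = config),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated microcolony: %d frames (%.0f min), %d -> %d cells, AHL = %g nM\n",
    length(x$frames), max(x$t), nrow(x$frames[[1]]),
    nrow(x$frames[[length(x$frames)]]), x$ahl))
  invisible(x)
}

#' Simulate a fixed population of cells to expression steady state
#'
#' Expression-only variant of the simulator: a fixed set of cells (no
#' growth, division or mechanics; dilution at the configured growth rate
#' still acts on p) is advanced to steady state, recording per-cell p at
#' every frame.  Used for stationary noise characterisation.
#'
#' @param n number of cells.
#' @param config a [sim_config()].
#' @param ahl AHL concentration (nM).
#' @param duration minutes to simulate (default \code{config$duration}).
#' @param seed RNG seed.
#' @return list with \code{t}, \code{snapshots} (list of per-cell p
#'   vectors), \code{phenotype}, \code{final} (colony data.frame).
#' @export
simulate_snapshot_population <- function(n, config, ahl,
                                         duration = config$duration,
                                         seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  colony <- colony_init(config, n = n)
  dt <- config$frame_interval
  times <- seq(0, duration, by = dt)
  snaps <- vector("list", length(times))
  snaps[[1]] <- colony$p
  for (k in seq_along(times)[-1]) {
    colony <- step_expression(colony, config, ahl, dt, t = times[k - 1])
    snaps[[k]] <- colony$p
  }
  list(t = times, snapshots = snaps, phenotype = colony$phenotype,
       final = colony)
}
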