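test_that("lognormal MLE recovers parameters and closed-form CV", {
  # degenerate: all values equal
  f0 <- fit_lognormal_mle(rep(3, 30))
  expect_equal(f0$meanlog, log(3))
  expect_equal(f0$sdlog, 0)
  # Monte-Carlo recovery within 3 SE
  set.seed(17)
  x <- rlnorm(1e4, meanlog = 1, sdlog = 0.5)
  f <- fit_lognormal_mle(x)
  expect_lt(abs(f$meanlog - 1), 3 * 0.5 / sqrt(1e4))
  expect_lt(abs(f$sdlog - 0.5), 3 * 0.5 / sqrt(2 * 1e4))
  expect_equal(f$cv, sqrt(exp(f$sdlog^2) - 1))
  expect_error(fit_lognormal_mle(c(-1, rep(1, 30))), "positive")
  expect_error(fit_lognormal_mle(rep(1, 5)), "at least 20")
})

test_that("lognormal MLE agrees with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(4)
  x <- rlnorm(500, 0.7, 0.3)
  f <- fit_lognormal_mle(x)
  ref <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(f$meanlog, unname(ref$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(f$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-3)
})

test_that("planted two-component mixture is recovered accurately", {
  set.seed(1)
  truth <- rep(c(1, 2), c(1800, 200))        # component index per cell
  x <- exp(c(rnorm(1800, 0, 0.3), rnorm(200, 2, 0.3)))
  g <- gmm_separate_log(x, seed = 5)
  expect_equal(g$k, 2L)
  mu <- sort(g$means)
  expect_lt(abs(mu[1] - 0), 0.1)
  expect_lt(abs(mu[2] - 2), 0.1)
  # assignment agreement against the planted labels (dominant = majority
  # component, which here is the low-mean, weight-0.9 one)
  dominant_truth <- truth == 1
  expect_lt(mean((g$assignment == "dominant") != dominant_truth), 0.02)
  # responsibilities are proper probabilities
  expect_equal(rowSums(g$responsibility), rep(1, 2000), tolerance = 1e-12)
})

test_that("mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  set.seed(2)
  x <- exp(c(rnorm(900, 0, 0.25), rnorm(300, 1.5, 0.25)))
  g <- gmm_separate_log(x, seed = 6)
  ref <- mclust::Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(g$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  set.seed(9)
  x <- exp(c(rnorm(500, 0, 0.4), rnorm(100, 1.8, 0.3)))
  g <- gmm_separate_log(x, seed = 10)
  expect_true(all(diff(g$loglik_trace) > -1e-8))
})

test_that("a single tight cluster collapses to one dominant component", {
  set.seed(12)
  x <- exp(rnorm(400, 1, 0.2))
  g <- gmm_separate_log(x, seed = 13)
  expect_true(g$k == 1L || max(g$weights) >= 0.95)
  expect_true(all(g$assignment == "dominant"))
})

test_that("component label swap does not change assignments", {
  set.seed(14)
  x <- exp(c(rnorm(700, 0, 0.3), rnorm(300, 1.6, 0.3)))
  g1 <- gmm_separate_log(x, seed = 15)
  g2 <- gmm_separate_log(x, seed = 16)      # different restarts
  expect_equal(g1$assignment, g2$assignment)
})

test_that("dominant filter keeps everything without a late subpopulation", {
  cfg <- tiny_chemostat_config(late_inducer_fraction = 0, duration = 300)
  sim <- simulate_colony(cfg, ahl = 20, seed = 31)
  filt <- dominant_filter(sim$trajectories, seed = 32)
  # classifiable trajectories = cells present at the end plus their
  # ancestors (cells whose lineage left the trap cannot be classified)
  traj <- sim$trajectories
  parent_of <- traj$parent_id[match(unique(traj$cell_id), traj$cell_id)]
  names(parent_of) <- unique(traj$cell_id)
  expected <- unique(traj$cell_id[traj$frame == max(traj$frame)])
  frontier <- expected
  while (length(frontier) > 0) {
    frontier <- setdiff(stats::na.omit(parent_of[as.character(frontier)]),
                        expected)
    expected <- c(expected, frontier)
  }
  expect_setequal(filt$kept_ids, expected)
})

test_that("dominant filter removes late inducers with high purity", {
  # snapshot-style population (no division), as in time-slice histograms
  cfg <- sim_config(late_inducer_fraction = 0.1, duration = 600)
  pop <- simulate_snapshot_population(600, cfg, ahl = 20, seed = 33)
  nfr <- length(pop$t)
  traj <- do.call(rbind, lapply(seq(1, nfr, by = 20), function(k)
    data.frame(cell_id = seq_along(pop$snapshots[[k]]), frame = k,
               t_min = pop$t[k], area = 2,
               F = 2 * pop$snapshots[[k]],
               parent_id = NA_real_)))
  filt <- dominant_filter(traj, seed = 34)
  term <- data.frame(cell_id = seq_len(600), phenotype = pop$phenotype)
  kept_term <- term[term$cell_id %in% filt$kept_ids, ]
  frac_kept <- nrow(kept_term) / nrow(term)
  expect_gte(frac_kept, 0.85)
  expect_lte(frac_kept, 0.95)
  purity <- mean(kept_term$phenotype == "normal")
  expect_gte(purity, 0.9)
  # idempotence
  filt2 <- dominant_filter(filt$trajectories, seed = 34)
  expect_setequal(filt2$kept_ids, filt$kept_ids)
})

test_that("noise curve is zero for identical cells and matches lognormal CV", {
  snaps <- replicate(10, rep(2, 50), simplify = FALSE)
  nc <- noise_curve(snaps)
  expect_equal(nc$curve$cv2, rep(0, 10))
  expect_equal(nc$plateau_cv2, 0)
  # stationary lognormal population: plateau CV^2 = exp(sigma^2) - 1
  set.seed(41)
  sig <- 0.25
  snaps2 <- replicate(30, rlnorm(800, 0, sig), simplify = FALSE)
  nc2 <- noise_curve(snaps2)
  expect_equal(nc2$plateau_cv2, exp(sig^2) - 1, tolerance = 0.15)
})

test_that("plateau estimator is invariant under rescaling of p", {
  set.seed(42)
  snaps <- lapply(seq(0.1, 1, length.out = 15), function(m)
    rlnorm(300, log(m), 0.2))
  nc1 <- noise_curve(snaps)
  nc2 <- noise_curve(lapply(snaps, `*`, 37.5))
  expect_equal(nc1$plateau_cv2, nc2$plateau_cv2, tolerance = 1e-12)
})

test_that("generator round trip reproduces the configured extrinsic CV", {
  cfg <- sim_config(duration = 750, extrinsic_cv = 0.17,
                    late_inducer_fraction = 0.05)
  pop <- simulate_snapshot_population(500, cfg, ahl = 50, seed = 55)
  nc <- noise_curve(pop$snapshots, pop$t, dominant_only = TRUE, seed = 56)
  expect_gte(nc$plateau_cv, 0.14)
  expect_lte(nc$plateau_cv, 0.20)
})
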