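test_that("linear-in-time source integrates to AHL = t^2 / 2 exactly", {
  p <- sender_params(alpha_l = 1, alpha_a = 1, lambda = 0, C_out = 0,
                     gamma = 0, N0 = 1, r = 1)
  sol <- solve_sender_ode(p, seq(0, 2, by = 0.05))
  expect_equal(sol$luxi, sol$t, tolerance = 1e-7)
  expect_equal(sol$ahl, sol$t^2 / 2, tolerance = 1e-6)
  expect_equal(ahl_closed_form(p, 2), 2.0)
  expect_equal(ahl_closed_form(p, 0), 0)
})

test_that("no senders or no LuxI production means no AHL", {
  p <- sender_params(r = 0)
  sol <- solve_sender_ode(p, seq(0, 300, by = 3))
  expect_true(all(sol$ahl == 0))
  p2 <- sender_params(alpha_l = 0)
  sol2 <- solve_sender_ode(p2, seq(0, 300, by = 3))
  expect_true(all(sol2$luxi == 0) && all(sol2$ahl == 0))
})

test_that("adaptive solution matches a fine-step fixed integrator", {
  p <- sender_params(alpha_l = 1e-4, alpha_a = 0.04, lambda = 2e-3,
                     C_out = 3e-3, gamma = 1.5e-3, N0 = 50, r = 0.33)
  tg <- seq(0, 450, by = 3)
  sol <- solve_sender_ode(p, tg)
  # independent fixed-step RK4 oracle at 100x smaller step
  h <- 0.03
  tt <- seq(0, 450, by = h)
  y <- c(0, 0)
  deriv <- function(t, y) c(p$alpha_l * p$r * p$N0 * exp(p$gamma * t) -
                              p$lambda * y[1],
                            p$alpha_a * y[1] - p$C_out * y[2])
  keep <- numeric(length(tg)); ki <- 1
  for (i in seq_along(tt)) {
    if (ki <= length(tg) && abs(tt[i] - tg[ki]) < h / 2) {
      keep[ki] <- y[2]; ki <- ki + 1
    }
    k1 <- deriv(tt[i], y)
    k2 <- deriv(tt[i] + h / 2, y + h / 2 * k1)
    k3 <- deriv(tt[i] + h / 2, y + h / 2 * k2)
    k4 <- deriv(tt[i] + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  rel <- abs(sol$ahl[-1] - keep[-1]) / keep[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("AHL is monotone non-decreasing without outflow and monotone in rates", {
  base <- list(alpha_l = 1e-4, alpha_a = 0.04, lambda = 1e-3, C_out = 0,
               gamma = 1e-3, N0 = 50, r = 0.33)
  tg <- seq(0, 450, by = 9)
  sol <- solve_sender_ode(do.call(sender_params, base), tg)
  expect_true(all(diff(sol$ahl) >= -1e-12))
  for (fld in c("alpha_a", "alpha_l", "r", "N0")) {
    up <- base; up[[fld]] <- up[[fld]] * 2
    sol_up <- solve_sender_ode(do.call(sender_params, up), tg)
    expect_true(all(sol_up$ahl >= sol$ahl - 1e-12), label = fld)
  }
})

test_that("closed form converges to the ODE as rates vanish", {
  tg <- seq(0, 450, by = 9)
  for (eps in c(4e-4, 1e-4, 1e-5)) {
    p <- sender_params(alpha_l = 1e-4, alpha_a = 0.04, lambda = eps,
                       C_out = eps, gamma = eps, N0 = 50, r = 0.33)
    sol <- solve_sender_ode(p, tg)
    ratio <- sol$ahl[-1] / ahl_closed_form(p, tg[-1])
    if ((3 * eps) * max(tg) <= 0.2)
      expect_lt(max(abs(ratio - 1)), 0.05)
  }
  # tighter limit: ratio approaches 1
  p0 <- sender_params(alpha_l = 1e-4, alpha_a = 0.04, lambda = 1e-6,
                      C_out = 1e-6, gamma = 1e-6, N0 = 50, r = 0.33)
  sol0 <- solve_sender_ode(p0, tg)
  expect_lt(max(abs(sol0$ahl[-1] / ahl_closed_form(p0, tg[-1]) - 1)), 1e-3)
})

test_that("compute_s matches constant- and linear-ratio arithmetic", {
  tg <- seq(0, 400, by = 2)
  s1 <- compute_s(data.frame(t = tg, r = rep(0.33, length(tg))), 300)
  expect_equal(s1$s, 0.33 * 300^2)
  # r(t) = t / t_max: <r> = 1/2
  tg2 <- seq(0, 100, by = 0.5)
  s2 <- compute_s(data.frame(t = tg2, r = tg2 / 100), 100)
  expect_equal(s2$r_mean, 0.5, tolerance = 1e-6)
  expect_equal(s2$s, 5000, tolerance = 1e-3)
  s3 <- compute_s(data.frame(t = tg, r = rep(0, length(tg))), 300)
  expect_equal(s3$s, 0)
  expect_error(compute_s(data.frame(t = tg, r = tg), 500), "cover")
  expect_error(compute_s(data.frame(t = numeric(0), r = numeric(0)), 10),
               "empty")
})

test_that("detect_t_max finds the induction maximum, earliest on ties", {
  t <- seq(0, 600, by = 3)
  rate <- (t / 400) * exp(1 - t / 400)
  expect_lt(abs(detect_t_max(t, rate) - 400), 6)
  # two equal peaks: earlier wins
  tw <- c(rep(0, 5), 1, rep(0, 5), 1, rep(0, 5))
  expect_equal(detect_t_max(seq_along(tw), tw, window = 1), 6)
  expect_error(detect_t_max(t, rep(1, length(t))), "flat")
})

test_that("sender-strength fit recovers an exact linear relation", {
  s <- c(1e4, 3e4, 1e5, 2e5)
  cal <- fit_sender_strength(s, 0.001 * s)
  expect_equal(cal$slope, 0.001, tolerance = 1e-10)
  # scale invariance of weighted least squares
  c1 <- fit_sender_strength(s, 0.001 * s * c(1.1, 0.9, 1.05, 0.97),
                            sd = c(1, 2, 3, 4))
  c2 <- fit_sender_strength(s, 0.001 * s * c(1.1, 0.9, 1.05, 0.97),
                            sd = 2 * c(1, 2, 3, 4))
  expect_equal(c1$slope, c2$slope, tolerance = 1e-12)
  expect_error(fit_sender_strength(c(1, 1), c(1, 1)), "3 experiments")
})

test_that("end-to-end sender calibration recovers the generating slope", {
  res <- calibrate_sender_strength(c(1 / 15, 0.142, 0.33, 1), seed = 21)
  expect_equal(res$calibration$slope, res$truth, tolerance = 0.2)
  expect_true(all(res$experiments$ahl_eff >= 0))
})
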