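geom <- cell_geometry()

make_unconfined_trajs <- function(D = 0.5, seed = 7, n_frames = 2200,
                                  act = 20, life = 30, loc_sigma = 0) {
  cfg <- sim_config(states = data.frame(fraction = 1, D = D),
                    loc_sigma = loc_sigma, n_frames = n_frames,
                    mean_activations_per_pulse = act,
                    bleach_mean_frames = life, seed = seed)
  tr <- simulate_trajectories(cfg, geom, confine = FALSE)
  p <- tr$positions
  structure(data.frame(traj_id = p$emitter, frame = p$frame,
                       x_um = p$x_um, y_um = p$y_um),
            frame_interval = cfg$frame_interval,
            class = c("trajectory_set", "data.frame"))
}

test_that("ensemble MSD matches 4 D dt on unconfined motion and is zero when static", {
  trajs <- filter_trajectories(make_unconfined_trajs(), 5)
  msd <- compute_msd_ensemble(trajs, max_lag = 4)
  expect_true(all(msd$n_pairs > 1e4))
  expect_equal(msd$msd_um2, 4 * 0.5 * msd$dt_s, tolerance = 0.03)

  static <- structure(data.frame(traj_id = rep(1:3, each = 10),
                                 frame = rep(1:10, 3), x_um = 1, y_um = 2),
                      class = c("trajectory_set", "data.frame"))
  expect_true(all(compute_msd_ensemble(static, 3)$msd_um2 == 0))
})

test_that("localization noise shifts the MSD by a 4 sigma^2 intercept", {
  trajs <- make_unconfined_trajs()
  set.seed(31)
  sig <- 0.04
  trajs$x_um <- trajs$x_um + rnorm(nrow(trajs), 0, sig)
  trajs$y_um <- trajs$y_um + rnorm(nrow(trajs), 0, sig)
  msd <- compute_msd_ensemble(filter_trajectories(trajs, 5), max_lag = 4)
  offset <- msd$msd_um2 - 4 * 0.5 * msd$dt_s
  expect_equal(mean(offset), 4 * sig^2, tolerance = 0.15)
})

test_that("zero-intercept MSD fit reproduces exact slopes and the 4x conversion", {
  curve <- structure(data.frame(lag = 1:6, dt_s = (1:6) * 0.00576,
                                msd_um2 = 2.0 * (1:6) * 0.00576,
                                n_pairs = 1000L),
                     class = c("msd_curve", "data.frame"))
  fit <- fit_msd_linear(curve, n_lags = 4)
  expect_equal(fit$D_slope, 2.0)
  expect_equal(fit$D_conv, 0.5)
  expect_identical(fit$D_slope, 4 * fit$D_conv)   # exact identity

  zero <- curve; zero$msd_um2 <- 0
  expect_equal(fit_msd_linear(zero)$D_slope, 0)

  # simulated recovery: D_conv = 0.5 -> slope 2.0 within 5%
  trajs <- filter_trajectories(make_unconfined_trajs(seed = 13), 5)
  fit2 <- fit_msd_linear(compute_msd_ensemble(trajs, 4), 4)
  expect_equal(fit2$D_slope, 2.0, tolerance = 0.05)
})

test_that("osd speed is displacement over the uniform frame interval", {
  steps <- structure(data.frame(traj_id = 1, frame = 1:2,
                                osd_um = c(0.1, 0), osd2_um2 = c(0.01, 0),
                                x_mid = 0, y_mid = 0, dt_s = 0.00576),
                     class = c("step_table", "data.frame"))
  sp <- compute_osd_speed(steps)
  expect_equal(sp$speed_um_s, c(0.1 / 0.00576, 0))
  steps$dt_s <- c(0.00576, 0.01)
  expect_error(compute_osd_speed(steps), "uniform")
})

test_that("fast-state steps are faster than slow-state steps in a two-state simulation", {
  o2_fast <- simulate_osd2(2000, 1, 2.0, seed = 1)
  o2_slow <- simulate_osd2(2000, 1, 0.05, seed = 2)
  expect_gt(mean(sqrt(o2_fast)) / 0.00576, mean(sqrt(o2_slow)) / 0.00576)
})

test_that("one-state CDF fit agrees with the closed-form mean estimator", {
  t <- 0.00576
  o2 <- simulate_osd2(2e4, 1, 1.0, t = t, seed = 5)
  fit <- fit_cdf_mixture(o2, n = 1, t = t)
  expect_equal(fit$D_prime, 1.0, tolerance = 0.03)
  # osd^2 ~ Exp(mean 4 D' t): sample-mean estimator is the analytic cross-check
  expect_equal(fit$D_prime, mean(o2) / (4 * t), tolerance = 0.03)
  expect_identical(fit$D, 4 * fit$D_prime)
  # model normalization: CDF(0) = 0, CDF(Inf) = 1
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, Inf), 1)
})

test_that("two-state mixture parameters are recovered across seeds", {
  t <- 0.00576
  for (s in c(11, 12, 13)) {
    o2 <- simulate_osd2(2e4, c(0.6, 0.4), c(0.05, 2.0), t = t, seed = s)
    fit <- fit_cdf_mixture(o2, n = 2, t = t)
    expect_equal(fit$P[2], 0.6, tolerance = 0.035)      # slow fraction, +/- 0.02 abs
    expect_lt(abs(fit$P[2] - 0.6), 0.02)
    expect_lt(abs(fit$D_prime[1] - 2.0) / 2.0, 0.10)
    expect_lt(abs(fit$D_prime[2] - 0.05) / 0.05, 0.10)
    expect_true(all(diff(fit$D_prime) < 0))             # state 1 is fast
    expect_equal(sum(fit$P), 1, tolerance = 1e-9)
  }
  expect_error(fit_cdf_mixture(runif(100), n = 2), "at least 500")
})

test_that("state-number selection finds one state in pure data and two in mixed data", {
  t <- 0.00576
  one <- simulate_osd2(2e4, 1, 0.5, t = t, seed = 21)
  sel1 <- select_state_number(one, t = t)
  expect_equal(sel1$chosen, 1)

  two <- simulate_osd2(2e4, c(0.6, 0.4), c(0.05, 2.0), t = t, seed = 22)
  sel2 <- select_state_number(two, t = t)
  expect_equal(sel2$chosen, 2)
  # the two-state fit improves hugely on one state; a third adds little
  expect_gt(sel2$rss["n1"] / sel2$rss["n2"], 100)
  expect_lt(sel2$rss["n2"] / sel2$rss["n3"], 3)
})

test_that("reference replicates define the mean +/- 2 sd constraint on the fast state", {
  mk_fit <- function(D1) structure(list(n = 2, P = c(0.5, 0.5),
                                        D_prime = c(D1 / 4, 0.0125),
                                        D = c(D1, 0.05), t = 0.00576),
                                   class = "cdf_mixture_fit")
  # hand computation: mean 2.1, sample sd 0.1414214
  iv <- constrain_from_reference(list(mk_fit(2.0), mk_fit(2.2)))
  expect_equal(iv$D1_interval, c(2.1 - 2 * sd(c(2.0, 2.2)), 2.1 + 2 * sd(c(2.0, 2.2))))
  expect_equal(iv$D1_interval, c(1.8171573, 2.3828427), tolerance = 1e-6)
  expect_equal(iv$D_prime_interval, iv$D1_interval / 4)

  expect_warning(iv1 <- constrain_from_reference(list(mk_fit(2.0))), "single replicate")
  expect_equal(iv1$D1_interval, c(2, 2))

  # constrained fit honours the box, and agrees with the unconstrained fit
  # when the optimum already lies inside
  t <- 0.00576
  o2 <- simulate_osd2(2e4, c(0.6, 0.4), c(0.05, 2.0), t = t, seed = 30)
  free <- fit_cdf_mixture(o2, n = 2, t = t)
  con <- fit_cdf_mixture(o2, n = 2, t = t,
                         D1_constraint = c(free$D_prime[1] * 0.8,
                                           free$D_prime[1] * 1.2))
  expect_gte(con$D_prime[1], free$D_prime[1] * 0.8 - 1e-9)
  expect_lte(con$D_prime[1], free$D_prime[1] * 1.2 + 1e-9)
  expect_equal(con$D_prime, free$D_prime, tolerance = 0.02)
  # a tight box away from the optimum pins the fast state inside it
  tight <- fit_cdf_mixture(o2, n = 2, t = t, D1_constraint = c(2.5, 3.0))
  expect_gte(tight$D_prime[1], 2.5 - 1e-9)
  expect_lte(tight$D_prime[1], 3.0 + 1e-9)
})
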