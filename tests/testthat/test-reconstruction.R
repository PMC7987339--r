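# forward-render a pixel-integrated Gaussian spot (matches the imaging model)
render_spot <- function(ny, nx, x0, y0, photons, sigma_px, bg = 0) {
  fx <- pnorm((seq_len(nx) + 0.5 - x0) / sigma_px) -
        pnorm((seq_len(nx) - 0.5 - x0) / sigma_px)
  fy <- pnorm((seq_len(ny) + 0.5 - y0) / sigma_px) -
        pnorm((seq_len(ny) - 0.5 - y0) / sigma_px)
  photons * outer(fy, fx) + bg
}

test_that("candidate detection matches the exhaustive brute-force scan", {
  # all-zero and constant frames yield no candidates, not an error
  expect_equal(nrow(detect_candidates(matrix(0, 12, 12))), 0)
  expect_equal(nrow(detect_candidates(matrix(7, 12, 12))), 0)

  # one bright spot at (20, 30): found exactly, and scan agrees
  set.seed(5)
  fr <- matrix(rnorm(40 * 50, 100, 2), 40, 50)
  fr <- fr + render_spot(40, 50, 30, 20, 200, 0.8)  # peak SNR ~ 10
  got <- detect_candidates(fr)
  expect_equal(got, data.frame(row = 20L, col = 30L))
  expect_equal(got, oracle_candidates(fr))

  # random noisy frames: implementation = oracle, as sets
  for (s in 1:3) {
    set.seed(s)
    f <- matrix(rpois(30 * 30, 5), 30, 30)
    f[10, 10] <- f[10, 10] + 40
    f[22, 17] <- f[22, 17] + 40
    expect_equal(detect_candidates(f), oracle_candidates(f))
  }
})

test_that("two tied peaks inside one 5x5 neighbourhood leave one candidate", {
  set.seed(7)
  fr <- matrix(rnorm(400, 10, 0.5), 20, 20)
  fr[10, 9] <- 60; fr[10, 11] <- 60   # exact tie within the 5x5 window
  got <- detect_candidates(fr)
  expect_equal(nrow(got), 1)
  expect_equal(got, data.frame(row = 10L, col = 9L))  # lexicographic winner
  expect_equal(got, oracle_candidates(fr))
})

test_that("2D Gaussian fit recovers centres to sub-pixel accuracy", {
  # centred on a pixel: essentially exact
  fr <- render_spot(15, 15, 8, 8, 500, 0.8, bg = 2)
  f1 <- fit_gaussian2d(fr, 8, 8)
  expect_true(f1$fit_ok)
  expect_lt(abs(f1$x_px - 8), 1e-6)
  expect_lt(abs(f1$y_px - 8), 1e-6)

  # sub-pixel offset (0.30, -0.20) px
  fr2 <- render_spot(15, 15, 8.30, 7.80, 500, 0.8, bg = 2)
  f2 <- fit_gaussian2d(fr2, 8, 8)
  expect_true(f2$fit_ok)
  expect_lt(abs(f2$x_px - 8.30), 1e-3)
  expect_lt(abs(f2$y_px - 7.80), 1e-3)
  expect_equal(f2$photons, 500, tolerance = 1e-3)

  # flat window: failed fit, encoded in fit_ok
  expect_false(fit_gaussian2d(matrix(5, 15, 15), 8, 8)$fit_ok)
})

test_that("localization precision improves with photon count and meets the CRB-scale bound", {
  set.seed(21)
  sigma_px <- 0.75
  rmse <- vapply(c(100, 500, 2000), function(N) {
    err <- replicate(60, {
      x0 <- 8 + runif(1, -0.5, 0.5); y0 <- 8 + runif(1, -0.5, 0.5)
      lam <- render_spot(15, 15, x0, y0, N, sigma_px, bg = 5)
      fr <- matrix(rpois(length(lam), lam), 15, 15)
      ft <- fit_gaussian2d(fr, round(y0), round(x0))
      if (ft$fit_ok) sqrt((ft$x_px - x0)^2 + (ft$y_px - y0)^2) else NA
    })
    sqrt(mean(err^2, na.rm = TRUE))
  }, 1.0)
  expect_true(all(diff(rmse) < 0))          # monotone in photons
  # 500-photon case within 2x the shot-noise-limited scale sigma/sqrt(N)
  expect_lt(rmse[2], 2 * sqrt(2) * sigma_px / sqrt(500))
})

test_that("drift estimation recovers constructed shifts and is idempotent", {
  set.seed(2)
  n <- 400
  x <- runif(n, 5, 45); y <- runif(n, 5, 25)
  locs <- data.frame(frame = c(rep(1:50, length.out = n), rep(51:100, length.out = n)),
                     x_px = c(x, x + 2), y_px = c(y, y + 1))
  dr <- estimate_drift_fft(locs, block_size = 50, img_size_px = c(32, 52))
  expect_equal(dr$blocks$dx_px, c(0, 2), tolerance = 0.05)
  expect_equal(dr$blocks$dy_px, c(0, 1), tolerance = 0.1)

  # identical blocks: zero shift
  locs0 <- data.frame(frame = c(rep(1:50, length.out = n), rep(51:100, length.out = n)),
                      x_px = c(x, x), y_px = c(y, y))
  dr0 <- estimate_drift_fft(locs0, block_size = 50, img_size_px = c(32, 52))
  expect_equal(max(abs(c(dr0$blocks$dx_px, dr0$blocks$dy_px))), 0, tolerance = 1e-9)

  # idempotence under a smooth (linear) drift: correcting the corrected
  # table finds ~no residual shift
  xb <- runif(150, 5, 40); yb <- runif(150, 5, 25)
  lin <- data.frame(frame = rep(1:120, each = 150),
                    x_px = rep(xb, 120) + 0.02 * rep(1:120, each = 150),
                    y_px = rep(yb, 120))
  drl <- estimate_drift_fft(lin, block_size = 30, img_size_px = c(32, 52),
                            upsample = 4)
  corrected <- apply_drift(lin, drl, pixel_size = 0.173)
  dr2 <- estimate_drift_fft(corrected, block_size = 30,
                            img_size_px = c(32, 52), upsample = 4)
  expect_lt(max(abs(c(dr2$blocks$dx_px, dr2$blocks$dy_px))), 0.1)
})

test_that("localize_stack finds sparse static emitters and flags frame mismatches", {
  mv <- make_static_movie(seed = 3, n_frames = 330)
  locs <- localize_stack(mv$stack, drift_block_size = NULL)
  tp <- mv$truth$positions
  tp <- tp[!(tp$frame %in% mv$stack$descriptor$activation_frames), ]
  m <- merge(tp, as.data.frame(locs), by = "frame", suffixes = c(".t", ".l"))
  d <- sqrt((m$x_um.t - m$x_um.l)^2 + (m$y_um.t - m$y_um.l)^2)
  hit <- tapply(d, paste(m$frame, m$emitter), min)
  expect_gte(mean(hit < mv$cfg$pixel_size), 0.95)

  bad_desc <- mv$stack$descriptor
  bad_desc$n_frames <- 999
  expect_error(localize_stack(mv$stack$data, bad_desc), "999")

  # background-only stack: empty table
  cfg0 <- sim_config(states = data.frame(fraction = 1, D = 0), n_frames = 22,
                     photons_per_frame = 0, mean_activations_per_pulse = 0,
                     seed = 1)
  tr0 <- simulate_trajectories(cfg0, cell_geometry())
  st0 <- render_movie(tr0, cfg0)
  expect_equal(nrow(localize_stack(st0, drift_block_size = NULL)), 0)
})

test_that("image stacks round-trip through TIFF with their descriptor", {
  cfg <- sim_config(states = data.frame(fraction = 1, D = 0), n_frames = 11,
                    mean_activations_per_pulse = 1, seed = 6)
  tr <- simulate_trajectories(cfg, cell_geometry())
  st <- render_movie(tr, cfg)
  path <- file.path(tempdir(), "mini.tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(back$data, st$data)
  expect_equal(back$descriptor$pixel_size, st$descriptor$pixel_size)
  expect_equal(back$descriptor$activation_frames, st$descriptor$activation_frames)
})
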