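test_that("time-averaged MSD matches hand-enumerated pair averages", {
  tr <- toy_traj_1d(c(0, 1, 3, 2, 4))
  cv <- time_averaged_msd(tr, lags = 1:2)
  # tau = 1: squares (1, 4, 1, 4) -> 2.5 ; tau = 2: (9, 1, 1) -> 11/3
  expect_equal(cv$msd, c(2.5, 11 / 3))
  expect_equal(cv$n_pairs, c(4L, 3L))
})

test_that("MSD closed forms: ballistic is v^2 tau^2, static is zero", {
  v <- 50; fr <- 100
  tr <- toy_traj_1d(v * (0:199) / fr, framerate = fr)
  cv <- time_averaged_msd(tr, lags = c(1L, 5L, 20L))
  expect_equal(cv$msd, (v * cv$lag_s)^2)
  st <- toy_traj_1d(rep(2, 100))
  expect_true(all(time_averaged_msd(st, lags = 1:5)$msd == 0))
})

test_that("MSD is invariant under time reversal", {
  set.seed(21)
  for (rep in 1:3) {
    x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
    a <- ispt_trajectory(x, y, framerate = 10)
    b <- ispt_trajectory(rev(x), rev(y), framerate = 10)
    la <- time_averaged_msd(a, lags = c(1L, 7L, 31L))
    lb <- time_averaged_msd(b, lags = c(1L, 7L, 31L))
    expect_equal(la$msd, lb$msd)
  }
})

test_that("lag bookkeeping: oversized lags dropped, empty lag list errors", {
  tr <- toy_traj_1d(1:20)
  expect_warning(cv <- time_averaged_msd(tr, lags = c(1, 25)), "dropped")
  expect_equal(cv$lag_frames, 1L)
  expect_error(time_averaged_msd(tr, lags = integer(0)), "empty")
})

test_that("power-law fit recovers an exact power law", {
  cv <- msd_curve(lag_s = 1:10, msd = 2 * (1:10)^0.5)
  ft <- fit_temporal_exponent(cv)
  expect_equal(ft$alpha, 0.5, tolerance = 1e-10)
  expect_equal(ft$gamma, 2, tolerance = 1e-10)
})

test_that("static-error offset is subtracted before fitting", {
  # MSD = 2 tau^0.5 + 36 with sigma = 3 nm: offset 4 sigma^2 = 36.
  # All values sit below the default precision floor (2 x 36), so the
  # floor is relaxed here to isolate the offset-subtraction property.
  lag <- 3:20
  cv <- msd_curve(lag_s = lag, msd = 2 * lag^0.5 + 36)
  ft <- fit_temporal_exponent(cv, sigma_xy = 3, exclusion_factor = 1)
  expect_equal(ft$alpha, 0.5, tolerance = 1e-8)
  # and the offset can instead be co-fitted as a free parameter
  ff <- fit_temporal_exponent(cv, error_mode = "fit")
  expect_equal(ff$alpha, 0.5, tolerance = 1e-3)
  expect_equal(ff$offset, 36, tolerance = 1e-2)
})

test_that("lags below the precision floor are excluded and counted", {
  # first lags have measured MSD < 2 * 4 sigma^2 = 72
  cv <- msd_curve(lag_s = 1:10, msd = c(40, 60, 71, 80, 90, 100,
                                        110, 120, 130, 140))
  ft <- fit_temporal_exponent(cv, sigma_xy = 3)
  expect_equal(ft$n_excluded_low, 3L)
  expect_equal(ft$n_lags_used, 7L)
  # too few surviving lags is a descriptive error
  cv2 <- msd_curve(lag_s = 1:4, msd = c(40, 50, 60, 80))
  expect_error(fit_temporal_exponent(cv2, sigma_xy = 3), "below precision")
})

test_that("noise inflates the measured MSD by 4 sigma^2 at all lags", {
  tr <- simulate_trajectory(sim_config("brownian", 1000, 1e5, 1e4, seed = 31))
  lags <- c(1L, 5L, 25L)
  clean <- time_averaged_msd(tr, lags = lags)
  deltas <- vapply(1:5, function(k) {
    noisy <- add_localization_noise(tr, 3, seed = 400 + k)
    time_averaged_msd(noisy, lags = lags)$msd - clean$msd
  }, numeric(length(lags)))
  expect_lt(max(abs(rowMeans(deltas) - 36) / 36), 0.1)
})

test_that("ensemble and time-averaged MSD agree for Brownian motion", {
  D <- 1e4; fr <- 1000; lag <- 10L
  set.seed(33)
  ens <- vapply(1:200, function(k) {
    tr <- simulate_trajectory(sim_config("brownian", fr, lag + 1, D,
                                         seed = 600 + k))
    (tr$x[lag + 1] - tr$x[1])^2 + (tr$y[lag + 1] - tr$y[1])^2
  }, numeric(1))
  tr <- simulate_trajectory(sim_config("brownian", fr, 5e4, D, seed = 34))
  ta <- time_averaged_msd(tr, lags = lag)$msd
  se <- stats::sd(ens) / sqrt(length(ens))
  expect_lt(abs(mean(ens) - ta), 3 * se)
})

test_that("rolling exponent is 2 for ballistic motion and windows tile correctly", {
  fr <- 100
  tr <- toy_traj_1d(30 * (0:4999) / fr, framerate = fr)
  ws <- rolling_exponent(tr, window = 500, stride = 500)
  expect_equal(nrow(ws), floor(5000 / 500))   # stride = window: partition
  expect_true(all(abs(ws$alpha - 2) < 1e-6))
  expect_equal(attr(ws, "T_w"), 5)
  # overlapping default stride
  ws2 <- rolling_exponent(tr, window = 500, stride = 100)
  expect_equal(nrow(ws2), floor((5000 - 500) / 100) + 1)
})

test_that("rolling exponent localizes a Brownian-to-ballistic transition", {
  fr <- 1000; n <- 2e4
  br <- simulate_trajectory(sim_config("brownian", fr, n, 1e4, seed = 41))
  x <- c(br$x, br$x[n] + 300 * seq_len(n) / fr)
  y <- c(br$y, rep(br$y[n], n))
  tr <- ispt_trajectory(x, y, framerate = fr)
  ws <- rolling_exponent(tr, window = 2000, stride = 2000)
  first <- mean(ws$alpha[ws$end <= n], na.rm = TRUE)
  second <- mean(ws$alpha[ws$start > n], na.rm = TRUE)
  expect_lt(abs(first - 1), 0.15)
  expect_gt(second, 1.8)
})

test_that("whole-trajectory fits separate directed, free and confined motion", {
  drift <- simulate_trajectory(sim_config("brownian", 1000, 2e4, 1e3,
                                          drift = c(1000, 0), seed = 51))
  expect_gt(whole_trajectory_msd(drift)$fit$alpha, 1.3)
  corral <- simulate_trajectory(sim_config("corral", 30000, 5e4, 5e5,
                                           corral_radius = 50, seed = 52))
  lags <- unique(round(exp(seq(log(3), log(300), length.out = 20))))
  expect_lt(whole_trajectory_msd(corral, lags = lags)$fit$alpha, 0.9)
  free <- simulate_trajectory(sim_config("brownian", 1000, 5e4, 1e4,
                                         seed = 53))
  ft <- whole_trajectory_msd(free)$fit
  expect_lt(abs(ft$alpha - 1), 0.1)
  expect_lt(abs(ft$gamma - 4e4) / 4e4, 0.25)   # Gamma ~ 4 D at alpha ~ 1
})
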