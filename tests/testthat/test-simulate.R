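test_that("config validation names the missing model parameter", {
  expect_error(sim_config("fbm", 1000, 100, 1e4), "alpha_true")
  expect_error(sim_config("corral", 1000, 100, 1e4), "corral_radius")
  expect_error(sim_config("hop", 1000, 100, 1e4,
                          compartment_side = 100), "hop_probability")
  expect_error(sim_config("stepper", 1000, 100, step_size = 8), "dwell_rate")
  expect_error(sim_config("landing", 1000, 100, 1e4,
                          start_height = 50), "binding_probability")
  expect_error(sim_config("fbm", 1000, 100, 1e4, alpha_true = 2.5),
               "alpha_true")
  expect_error(sim_config("hop", 1000, 100, 1e4, compartment_side = 100,
                          hop_probability = 1.5), "hop_probability")
  expect_error(sim_config("brownian", framerate = 0, n_frames = 10))
})

test_that("every generator is seed-deterministic", {
  cfgs <- list(
    sim_config("brownian", 1000, 200, 1e4, seed = 3),
    sim_config("fbm", 1000, 200, 1e4, alpha_true = 0.6, seed = 3),
    sim_config("corral", 1000, 200, 1e5, corral_radius = 60, seed = 3),
    sim_config("hop", 1000, 200, 1e5, compartment_side = 100,
               hop_probability = 0.2, seed = 3),
    sim_config("bowl", 1000, 200, 1e5, bowl_radius = 175,
               bowl_cap_half_angle = pi / 3, seed = 3),
    sim_config("stepper", 1000, 200, step_size = 8, dwell_rate = 10,
               jitter_sigma = 2, seed = 3),
    sim_config("landing", 1000, 200, 1e5, start_height = 100,
               binding_probability = 0.5, seed = 3))
  for (cfg in cfgs) {
    a <- simulate_trajectory(cfg)
    b <- simulate_trajectory(cfg)
    expect_identical(traj_positions(a), traj_positions(b), info = cfg$model)
    expect_silent(validate_trajectory(a))
  }
})

test_that("zero-diffusion Brownian motion stays at the start point", {
  tr <- simulate_trajectory(sim_config("brownian", 1000, 50, 0, seed = 1))
  expect_true(all(tr$x == 0) && all(tr$y == 0))
})

test_that("Brownian sample MSD matches 4 D dt within 3 standard errors", {
  D <- 1e5; fr <- 1000; n <- 2e4
  tr <- simulate_trajectory(sim_config("brownian", fr, n, D, seed = 7))
  inc2 <- diff(tr$x)^2 + diff(tr$y)^2
  expected <- 4 * D / fr
  se <- stats::sd(inc2) / sqrt(length(inc2))
  expect_lt(abs(mean(inc2) - expected), 3 * se)
  # 3D: 6 D dt
  tr3 <- simulate_trajectory(sim_config("brownian", fr, n, D,
                                        dimensionality = 3, seed = 8))
  inc3 <- diff(tr3$x)^2 + diff(tr3$y)^2 + diff(tr3$z)^2
  se3 <- stats::sd(inc3) / sqrt(length(inc3))
  expect_lt(abs(mean(inc3) - 6 * D / fr), 3 * se3)
})

test_that("hop model with crossing probability 1 is plain Brownian motion", {
  D <- 1e5; fr <- 1000; n <- 2e4
  tr <- simulate_trajectory(sim_config("hop", fr, n, D,
                                       compartment_side = 100,
                                       hop_probability = 1, seed = 5))
  inc <- c(diff(tr$x), diff(tr$y))
  expect_lt(abs(stats::sd(inc) - sqrt(2 * D / fr)),
            3 * stats::sd(inc) / sqrt(2 * length(inc)))
  ks <- stats::ks.test(inc / sqrt(2 * D / fr), "pnorm")
  expect_gt(ks$p.value, 1e-4)
})

test_that("hop model with low crossing probability is sub-diffusive", {
  tr <- simulate_trajectory(sim_config("hop", 30000, 5e4, 5e5,
                                       compartment_side = 80,
                                       hop_probability = 0.005, seed = 6))
  fit <- whole_trajectory_msd(tr)$fit
  expect_lt(fit$alpha, 0.8)
})

test_that("corral ensemble MSD plateaus at R^2 (uniform-in-disk pairs)", {
  R <- 60; D <- 5e5; fr <- 10000; n <- 2000
  set.seed(42)
  plateau <- vapply(1:100, function(k) {
    tr <- simulate_trajectory(sim_config("corral", fr, n, D,
                                         corral_radius = R, seed = 1000 + k))
    cv <- time_averaged_msd(tr, lags = c(900L, 1200L, 1500L))
    mean(cv$msd)
  }, numeric(1))
  # Monte-Carlo oracle: mean over independent corral trajectories
  expect_lt(abs(mean(plateau) - R^2) / R^2, 0.1)
  # and every point stays inside the corral
  tr <- simulate_trajectory(sim_config("corral", fr, n, D,
                                       corral_radius = R, seed = 1))
  expect_true(all(tr$x^2 + tr$y^2 <= R^2 + 1e-9))
})

test_that("fBm generator recovers its temporal exponent", {
  # ensemble whole-trajectory fits, alpha_true = 0.5 (H = 0.25)
  alphas <- vapply(1:10, function(k) {
    tr <- simulate_trajectory(sim_config("fbm", 1000, 1e5, 1e4,
                                         alpha_true = 0.5, seed = 200 + k))
    whole_trajectory_msd(tr)$fit$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.5), 0.05)
})

test_that("fGn increments have the exact fractional covariance at lag 1 and 2", {
  set.seed(9)
  H <- 0.3
  x <- isptrack:::fgn_sample(2e5, H)
  g1 <- 0.5 * (2^(2 * H) - 2)           # corr at lag 1 for unit-var fGn
  expect_lt(abs(stats::sd(x) - 1), 0.02)
  expect_lt(abs(stats::cor(x[-1], x[-length(x)]) - g1), 0.02)
})

test_that("stepper staircase has exactly delta-sized jumps and axis geometry", {
  cfg <- sim_config("stepper", 1000, 2000, step_size = 8, dwell_rate = 4,
                    jitter_sigma = 0, seed = 11)
  tr <- simulate_trajectory(cfg)
  md <- attr(tr, "metadata")
  s <- tr$x * md$track_axis[1] + tr$y * md$track_axis[2]
  jumps <- diff(s)
  moved <- which(jumps != 0)
  expect_equal(unname(jumps[moved]), rep(8, length(moved)))
  expect_equal(length(moved), length(md$jump_frames))
})

test_that("landing sticks at height zero after binding and spans start_height", {
  cfg <- sim_config("landing", 5000, 2000, 1e5, start_height = 150,
                    binding_probability = 1, seed = 13)
  tr <- simulate_trajectory(cfg)
  bf <- attr(tr, "metadata")$bind_frame
  expect_false(is.na(bf))
  expect_true(all(tr$z[(bf + 1):nrow(tr)] == 0))
  expect_true(all(tr$z >= 0))
  expect_equal(tr$z[1], 150)
  # binding_probability 0: never binds, reflects instead
  tr0 <- simulate_trajectory(sim_config("landing", 5000, 2000, 1e5,
                                        start_height = 150,
                                        binding_probability = 0, seed = 13))
  expect_true(is.na(attr(tr0, "metadata")$bind_frame))
  expect_true(all(tr0$z >= 0))
})

test_that("bowl trajectories live on the cap surface within its half-angle", {
  R <- 175; th <- pi / 3
  tr <- simulate_trajectory(sim_config("bowl", 10000, 5000, 1e5,
                                       bowl_radius = R,
                                       bowl_cap_half_angle = th, seed = 17))
  ctr <- attr(tr, "metadata")$bowl_center
  d <- sqrt((tr$x - ctr[1])^2 + (tr$y - ctr[2])^2 + (tr$z - ctr[3])^2)
  expect_lt(max(abs(d - R)), 1e-6)
  polar <- acos(pmin(1, pmax(-1, (ctr[3] - tr$z) / R)))
  expect_lte(max(polar), th + 1e-9)
})

test_that("localization noise obeys its observation model", {
  tr <- simulate_trajectory(sim_config("brownian", 1000, 500, 1e4, seed = 2))
  expect_identical(add_localization_noise(tr, 0)$x, tr$x)
  n1 <- add_localization_noise(tr, 3, seed = 4)
  n2 <- add_localization_noise(tr, 3, seed = 4)
  expect_identical(n1$x, n2$x)
  expect_equal(unique(n1$sigma_xy), 3)
  expect_error(add_localization_noise(tr, -1), ">= 0")
  # static trajectory: measured MSD at any lag ~ 4 sigma^2
  st <- ispt_trajectory(x = rep(0, 2e5), y = rep(0, 2e5), framerate = 1000)
  sn <- add_localization_noise(st, 3, seed = 5)
  cv <- time_averaged_msd(sn, lags = c(1L, 10L, 100L))
  expect_lt(max(abs(cv$msd - 36) / 36), 0.05)
})
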