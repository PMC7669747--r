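test_that("frame synthesis follows the interference model", {
  m <- ipsf_model(scattering_amplitude = 0.2, phase_offset = 0,
                  pixel_size = 40, medium_index = 1.33, wavelength = 550)
  ctr <- c(23.5, 23.5) * 40           # exactly a pixel centre
  # phase theta0 + 4 pi n z / lambda = 0 at z = 0: central value 1 + 2s
  fr <- synthesize_frame(m, c(ctr, 0), c(48, 48))
  expect_equal(fr[24, 24], 1 + 2 * 0.2, tolerance = 1e-12)
  # s -> 0 limit: uniform reference level (model validation forbids s = 0,
  # so check the analytic center at the smallest allowed amplitude)
  m2 <- ipsf_model(scattering_amplitude = 1e-6)
  fr2 <- synthesize_frame(m2, c(24 * 40, 24 * 40, 0), c(48, 48))
  expect_lt(max(abs(fr2 - 1)), 3e-6)
  # axial phase period: z and z + lambda / (2 n) give identical contrast
  z2 <- 550 / (2 * 1.33)
  fa <- synthesize_frame(m, c(ctr, 10), c(48, 48))
  fb <- synthesize_frame(m, c(ctr, 10 + z2), c(48, 48))
  expect_equal(isptrack:::central_contrast(m, 10),
               isptrack:::central_contrast(m, 10 + z2), tolerance = 1e-12)
  expect_equal(fa[24, 24], fb[24, 24], tolerance = 1e-9)
  expect_error(synthesize_frame(m, c(-100, 24 * 40, 0), c(48, 48)),
               "outside")
  expect_error(synthesize_frame(m, c(ctr, 0), c(8, 8)), "16")
  expect_error(ipsf_model(scattering_amplitude = 0.7), "0.5")
})

test_that("speckle background has the stated statistics", {
  # amplitude 0: frames are exactly 1 plus shot noise
  st0 <- synthesize_background_stack(c(32, 32), 5, amplitude = 0,
                                     shot_sigma = 0.001, seed = 1)
  expect_lt(max(abs(st0$pixels - 1)), 0.006)
  expect_lt(abs(mean(st0$pixels) - 1), 3 * 0.001 / sqrt(length(st0$pixels)))
  # AR coefficient 1: frozen speckle, identical frames
  stf <- synthesize_background_stack(c(32, 32), 4, amplitude = 0.05,
                                     ar_coefficient = 1, shot_sigma = 0,
                                     seed = 2)
  expect_identical(stf$pixels[, , 1], stf$pixels[, , 4])
  # spatial autocorrelation width ~ kernel width
  stc <- synthesize_background_stack(c(256, 256), 1, amplitude = 0.05,
                                     correlation_length = 3,
                                     ar_coefficient = 1, shot_sigma = 0,
                                     seed = 3)
  f <- stc$pixels[, , 1] - mean(stc$pixels[, , 1])
  # autocorrelation along x at small lags: for a Gaussian kernel of sigma
  # s the field autocorrelation is exp(-d^2 / (4 s^2))
  ac <- vapply(1:6, function(d) {
    mean(f[, 1:(256 - d)] * f[, (d + 1):256]) / mean(f * f)
  }, numeric(1))
  expect_equal(ac, exp(-(1:6)^2 / (4 * 9)), tolerance = 0.15)
  expect_error(synthesize_background_stack(c(32, 32), 2,
                                           correlation_length = 0.5),
               "correlation_length")
})

test_that("temporal median removes a static background and keeps the particle", {
  # static background, no particle: output is exactly 1
  stf <- synthesize_background_stack(c(32, 32), 21, amplitude = 0.05,
                                     ar_coefficient = 1, shot_sigma = 0,
                                     seed = 4)
  out <- remove_background(stf, 7)
  expect_lt(max(abs(out$pixels - 1)), 1e-12)
  expect_error(remove_background(stf, 23), "exceeds")
  expect_error(remove_background(stf, 6), "odd")
  # frozen speckle + particle sweeping fast across the field: the ring
  # pattern touches any given pixel for well under half the window, so the
  # per-pixel median stays background-dominated and the particle contrast
  # survives within 5%
  m <- test_ipsf_model()
  n <- 55
  x_px <- 8 + 1.5 * (0:(n - 1))                 # 1.5 px per frame
  tr <- ispt_trajectory(x = (x_px - 48) * 40, y = rep(0, n),
                        z = rep(10, n), framerate = 1000)
  bg <- synthesize_background_stack(c(96, 96), n, amplitude = 0.05,
                                    ar_coefficient = 1, shot_sigma = 0,
                                    seed = 5)
  st <- synthesize_trajectory_stack(m, tr, c(96, 96), background = bg)
  stc <- remove_background(st, 41)
  k <- 27
  truth <- st$background_params$truth_px
  ic <- round(truth[k, 2] + 0.5); jc <- round(truth[k, 1] + 0.5)
  clean <- synthesize_frame(m, c(truth[k, 1] * 40, truth[k, 2] * 40, 10),
                            c(96, 96))
  expect_lt(abs(stc$pixels[ic, jc, k] - clean[ic, jc]),
            0.05 * abs(clean[ic, jc] - 1))
})

test_that("radial-symmetry localization is subpixel-accurate", {
  m <- test_ipsf_model()
  # particle exactly at a pixel centre: recovered to ~1e-3 px by symmetry
  p0 <- c(23.5, 24.5) * 40
  fr <- synthesize_frame(m, c(p0, 0), c(48, 48))
  ctr <- localize_lateral(fr, p0 / 40, crop_radius = 10)
  expect_lt(max(abs(ctr - p0 / 40)), 1e-3)
  # +0.30 px offset: recovered within 0.05 px
  p1 <- p0 + c(0.30, 0) * 40
  fr1 <- synthesize_frame(m, c(p1, 0), c(48, 48))
  ctr1 <- localize_lateral(fr1, p0 / 40, crop_radius = 10)
  expect_lt(max(abs(ctr1 - p1 / 40)), 0.05)
  # flat frame: no-detection error
  expect_error(localize_lateral(matrix(1, 48, 48), c(24, 24), 10),
               "no-detection")
  expect_error(localize_lateral(fr, c(3, 3), 10), "outside")
})

test_that("axial calibration has cosine branch structure and inverts", {
  m <- test_ipsf_model()
  cal <- build_axial_calibration(m, c(0, 600), dz = 0.5)
  br <- cal$branches
  # interior branch length = half cosine period = lambda / (4 n)
  half_period <- 550 / (4 * 1.33)
  lens <- br$z_hi - br$z_lo
  interior <- lens[-c(1, length(lens))]
  expect_true(all(abs(interior - half_period) <= 1))
  # contrast extremes are +-2s
  expect_equal(max(cal$contrast), 2 * 0.15, tolerance = 1e-4)
  expect_equal(min(cal$contrast), -2 * 0.15, tolerance = 1e-4)
  # round-trip inversion on a branch interior
  b <- 2
  zs <- seq(br$z_lo[b] + 3, br$z_hi[b] - 3, length.out = 11)
  for (z in zs) {
    cc <- isptrack:::central_contrast(m, z)
    inv <- isptrack:::invert_branch(cal, b, cc)
    expect_false(inv$clipped)
    expect_lt(abs(inv$z - z), 0.5)
  }
  # contrast beyond the branch extremum: clipped to endpoint with flag
  ext <- isptrack:::invert_branch(cal, b, 10)
  expect_true(ext$clipped)
  expect_error(build_axial_calibration(m, c(5, 5), 0.5), "empty")
  # calibration table round-trips through delimited text
  tf <- tempfile(fileext = ".csv")
  write_axial_calibration(cal, tf)
  cal2 <- read_axial_calibration(tf)
  expect_equal(cal2$contrast, cal$contrast)
  expect_equal(nrow(cal2$branches), nrow(cal$branches))
})

test_that("single-frame 3D localization recovers a z ramp within one branch", {
  m <- test_ipsf_model()
  cal <- build_axial_calibration(m, c(-55, 160), dz = 0.5)
  zs <- seq(-35, 35, length.out = 25)
  prev <- -35
  errs <- vapply(zs, function(z) {
    fr <- synthesize_frame(m, c(24.3 * 40, 23.8 * 40, z), c(48, 48))
    loc <- localize_frame(fr, cal, c(24, 24), previous_z = prev,
                          crop_radius = 10, pixel_size = 40)
    prev <<- loc$z
    loc$z - z
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 2)
  # missing previous_z on the first frame is an error
  fr <- synthesize_frame(m, c(24 * 40, 24 * 40, 0), c(48, 48))
  expect_error(localize_frame(fr, cal, c(24, 24), previous_z = NULL,
                              crop_radius = 10, pixel_size = 40),
               "previous_z")
})

test_that("frame stacks round-trip through multi-page TIFF", {
  st <- synthesize_background_stack(c(32, 32), 3, amplitude = 0.04,
                                    ar_coefficient = 0.9, shot_sigma = 0,
                                    seed = 6)
  tf <- tempfile(fileext = ".tif")
  write_frame_stack(st, tf)
  st2 <- read_frame_stack(tf, pixel_size = 40, framerate = 1000)
  expect_equal(dim(st2$pixels), dim(st$pixels))
  expect_equal(st2$pixels, st$pixels, tolerance = 1e-6)
})
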