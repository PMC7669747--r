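# deterministic toy trajectories used across test files

toy_traj_1d <- function(x, framerate = 1) {
  ispt_trajectory(x = x, y = rep(0, length(x)), framerate = framerate)
}

# straight staircase: plateaus of `plateau_len` frames, steps of `delta` nm
staircase_traj <- function(n_steps = 2, delta = 8, plateau_len = 100,
                           framerate = 1000) {
  s <- rep(seq(0, by = delta, length.out = n_steps + 1),
           each = plateau_len)
  ispt_trajectory(x = s, y = rep(0, length(s)), framerate = framerate)
}

# points sampled on a spherical cap (lower hemisphere by default)
hemisphere_points <- function(n, R, center = c(0, 0, 0), cth_range = c(-1, 0),
                              noise_sd = 0) {
  phi <- stats::runif(n, 0, 2 * pi)
  cth <- stats::runif(n, cth_range[1], cth_range[2])
  sth <- sqrt(1 - cth^2)
  p <- cbind(R * sth * cos(phi), R * sth * sin(phi), R * cth)
  p <- sweep(p, 2L, center, "+")
  if (noise_sd > 0) p <- p + stats::rnorm(3 * n, sd = noise_sd)
  p
}

# standard imaging model used by the imaging tests: focal plane 400 nm
# below the membrane so the particle is always defocused (visible rings)
test_ipsf_model <- function() {
  ipsf_model(wavelength = 550, medium_index = 1.33,
             scattering_amplitude = 0.15, phase_offset = -pi / 2,
             envelope_waist = 2.5, axial_range = 400,
             ring_phase_coefficient = 5e-4, pixel_size = 40,
             focus_height = -400)
}
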