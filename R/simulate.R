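#' Simulation configuration for ground-truth trajectories
#'
#' Builds and validates the parameter set for [simulate_trajectory()]. Each
#' mobility model emulates one of the membrane scenarios the analysis stages
#' are designed to quantify:
#'
#' * `brownian` — free diffusion; Gaussian increments with per-axis variance
#'   `2 * D * dt`; an optional constant `drift` (nm/s per axis) turns it into
#'   drift-diffusion (directed transport).
#' * `fbm` — fractional Brownian motion with temporal exponent
#'   `alpha_true` (Hurst exponent `H = alpha_true / 2`), generated by exact
#'   circulant embedding of the fractional Gaussian noise covariance.
#' * `corral` — Brownian motion with specular reflection at a circular
#'   boundary of radius `corral_radius` (nm).
#' * `hop` — compartmentalized (picket-fence) diffusion on a square lattice
#'   of side `compartment_side` nm; wall crossings succeed with probability
#'   `hop_probability`, otherwise the step reflects off the wall.
#' * `bowl` — diffusion confined to a spherical-cap surface
#'   (radius `bowl_radius`, polar half-angle `bowl_cap_half_angle`);
#'   tangent-plane proposal, radial reprojection, reflecting cap rim.
#' * `stepper` — processive transport: instantaneous jumps of `step_size` nm
#'   along `track_axis` at exponential dwell times (`dwell_rate` per second)
#'   plus isotropic Gaussian positional jitter `jitter_sigma` nm per frame.
#' * `landing` — 3D Brownian motion above a membrane plane at height 0,
#'   starting at `start_height`; each contact binds with probability
#'   `binding_probability` (then the motion continues in-plane at z = 0),
#'   otherwise reflects.
#'
#' @param model one of `"brownian"`, `"fbm"`, `"corral"`, `"hop"`, `"bowl"`,
#'   `"stepper"`, `"landing"`.
#' @param framerate frames per second.
#' @param n_frames number of frames (>= 2).
#' @param diffusion_coefficient D in nm^2/s.
#' @param seed integer; fully determines the output.
#' @param dimensionality 2 or 3 (3 forced for `bowl`/`landing`).
#' @param alpha_true temporal exponent in (0, 2), `fbm` only.
#' @param corral_radius,compartment_side,bowl_radius length scales, nm.
#' @param hop_probability,binding_probability probabilities in [0, 1].
#' @param bowl_cap_half_angle cap half-angle, radians in (0, pi/2].
#' @param step_size,dwell_rate,track_axis,jitter_sigma stepper parameters:
#'   jump size (nm), jump rate (1/s), unit direction, per-frame jitter (nm).
#' @param start_height landing start height, nm.
#' @param drift optional constant velocity (nm/s), recycled per axis.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(model, framerate, n_frames,
                       diffusion_coefficient = 0, seed = NULL,
                       dimensionality = 2L,
                       alpha_true = NULL, corral_radius = NULL,
                       compartment_side = NULL, hop_probability = NULL,
                       bowl_radius = NULL, bowl_cap_half_angle = NULL,
                       step_size = NULL, dwell_rate = NULL,
                       track_axis = NULL, jitter_sigma = 0,
                       start_height = NULL, binding_probability = NULL,
                       drift = NULL) {
  model <- match.arg(model, c("brownian", "fbm", "corral", "hop", "bowl",
                              "stepper", "landing"))
  if (!is.numeric(framerate) || framerate <= 0) stop("framerate must be > 0")
  if (!is.numeric(n_frames) || n_frames < 2) stop("n_frames must be >= 2")
  if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0")
  if (!dimensionality %in% c(2L, 3L)) stop("dimensionality must be 2 or 3")
  if (model %in% c("bowl", "landing")) dimensionality <- 3L

  need <- function(value, name) {
    if (is.null(value))
      stop(sprintf("model '%s' requires parameter '%s'", model, name),
           call. = FALSE)
    value
  }
  check_prob <- function(p, name) {
    if (p < 0 || p > 1) stop(name, " must be in [0, 1]")
    p
  }
  switch(model,
    fbm = {
      alpha_true <- need(alpha_true, "alpha_true")
      if (alpha_true <= 0 || alpha_true >= 2)
        stop("alpha_true must be in (0, 2)")
    },
    corral = {
      corral_radius <- need(corral_radius, "corral_radius")
      if (corral_radius <= 0) stop("corral_radius must be > 0")
    },
    hop = {
      compartment_side <- need(compartment_side, "compartment_side")
      hop_probability <- check_prob(need(hop_probability, "hop_probability"),
                                    "hop_probability")
      if (compartment_side <= 0) stop("compartment_side must be > 0")
    },
    bowl = {
      bowl_radius <- need(bowl_radius, "bowl_radius")
      bowl_cap_half_angle <- need(bowl_cap_half_angle, "bowl_cap_half_angle")
      if (bowl_radius <= 0) stop("bowl_radius must be > 0")
      if (bowl_cap_half_angle <= 0 || bowl_cap_half_angle > pi / 2)
        stop("bowl_cap_half_angle must be in (0, pi/2]")
    },
    stepper = {
      step_size <- need(step_size, "step_size")
      dwell_rate <- need(dwell_rate, "dwell_rate")
      if (step_size <= 0) stop("step_size must be > 0")
      if (dwell_rate <= 0) stop("dwell_rate must be > 0")
      if (is.null(track_axis))
        track_axis <- c(1, rep(0, dimensionality - 1L))
      track_axis <- track_axis / sqrt(sum(track_axis^2))
      if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
    },
    landing = {
      start_height <- need(start_height, "start_height")
      binding_probability <- check_prob(
        need(binding_probability, "binding_probability"),
        "binding_probability")
      if (start_height <= 0) stop("start_height must be > 0")
    },
    brownian = NULL)
  structure(list(model = model, framerate = framerate,
                 n_frames = as.integer(n_frames),
                 diffusion_coefficient = diffusion_coefficient,
                 dimensionality = as.integer(dimensionality),
                 alpha_true = alpha_true, corral_radius = corral_radius,
                 compartment_side = compartment_side,
                 hop_probability = hop_probability,
                 bowl_radius = bowl_radius,
                 bowl_cap_half_angle = bowl_cap_half_angle,
                 step_size = step_size, dwell_rate = dwell_rate,
                 track_axis = track_axis, jitter_sigma = jitter_sigma,
                 start_height = start_height,
                 binding_probability = binding_probability,
                 drift = drift, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> model=%s, %d frames @ %g fps, D=%g nm^2/s\n",
              x$model, x$n_frames, x$framerate, x$diffusion_coefficient))
  invisible(x)
}

#' Simulate a ground-truth trajectory
#'
#' Generates a noiseless trajectory for the mobility model described by
#' `config` (see [sim_config()] for the models). Localization noise is a
#' separate observation step, [add_localization_noise()]. The config seed
#' fully determines the output.
#'
#' Model ground truth is recorded in the trajectory metadata (e.g. the
#' stepper's true jump frames and the landing's binding frame) so that
#' downstream estimators can be scored against it.
#'
#' @param config a [sim_config()].
#' @return an [ispt_trajectory()].
#' @examples
#' cfg <- sim_config("brownian", framerate = 1000, n_frames = 100,
#'                   diffusion_coefficient = 1e5, seed = 1)
#' simulate_trajectory(cfg)
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- switch(config$model,
    brownian = sim_brownian(config),
    fbm      = sim_fbm(config),
    corral   = sim_corral(config),
    hop      = sim_hop(config),
    bowl     = sim_bowl(config),
    stepper  = sim_stepper(config),
    landing  = sim_landing(config))
  attr(out, "metadata")$model <- config$model
  attr(out, "metadata")$config <- unclass(config)
  out
}

# ---- model generators (internal) -------------------------------------------

sim_brownian <- function(cfg) {
  n <- cfg$n_frames; d <- cfg$dimensionality
  dt <- 1 / cfg$framerate
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  inc <- matrix(stats::rnorm((n - 1L) * d, sd = sd_step), ncol = d)
  if (!is.null(cfg$drift)) {
    v <- rep_len(cfg$drift, d)
    inc <- sweep(inc, 2L, v * dt, "+")
  }
  pos <- apply(rbind(0, inc), 2L, cumsum)
  ispt_trajectory(pos[, 1], pos[, 2], if (d == 3L) pos[, 3],
                  framerate = cfg$framerate)
}

# Exact fractional Gaussian noise by Davies-Harte circulant embedding.
# Returns n increments of unit-variance fGn with Hurst exponent H.
fgn_sample <- function(n, H) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1L) return(stats::rnorm(1))
  # embed in a power-of-two circulant so the FFT length is composite
  m <- 2^ceiling(log2(2 * n))
  half <- m %/% 2L
  k <- 0:half
  g <- 0.5 * (abs(k - 1)^(2 * H) - 2 * k^(2 * H) + (k + 1)^(2 * H))
  lam <- Re(stats::fft(c(g, g[half:2])))
  lam[lam < 0 & lam > -1e-8 * max(lam)] <- 0
  if (any(lam < 0))
    stop("circulant embedding failed: negative eigenvalue; ",
         "n_frames too small for this alpha_true")
  w <- complex(length.out = m)
  w[1L] <- sqrt(lam[1L] / m) * stats::rnorm(1)
  w[half + 1L] <- sqrt(lam[half + 1L] / m) * stats::rnorm(1)
  j <- 2:half
  u <- stats::rnorm(half - 1L); v <- stats::rnorm(half - 1L)
  w[j] <- sqrt(lam[j] / (2 * m)) * complex(real = u, imaginary = v)
  w[m + 2L - j] <- Conj(w[j])
  Re(stats::fft(w))[seq_len(n)]
}

sim_fbm <- function(cfg) {
  n <- cfg$n_frames; d <- cfg$dimensionality
  H <- cfg$alpha_true / 2
  dt <- 1 / cfg$framerate
  # per-axis MSD over lag tau: 2 * D * tau^alpha  (nm^2, D in nm^2/s^alpha)
  scale <- sqrt(2 * cfg$diffusion_coefficient) * dt^H
  pos <- vapply(seq_len(d),
                function(i) cumsum(c(0, fgn_sample(n - 1L, H))) * scale,
                numeric(n))
  ispt_trajectory(pos[, 1], pos[, 2], if (d == 3L) pos[, 3],
                  framerate = cfg$framerate)
}

# reflect the out-of-bounds part of a 2D step off a circle of radius R
reflect_in_disk <- function(p, q, R) {
  for (it in 1:32) {
    if (sum(q^2) <= R^2) return(q)
    dvec <- q - p
    a <- sum(dvec^2); b <- 2 * sum(p * dvec); cc <- sum(p^2) - R^2
    tt <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    hit <- p + tt * dvec
    nrm <- hit / R
    rest <- (1 - tt) * dvec
    rest <- rest - 2 * sum(rest * nrm) * nrm
    p <- hit; q <- hit + rest
  }
  q * (R / sqrt(sum(q^2)))  # pathological: clamp to boundary
}

sim_corral <- function(cfg) {
  n <- cfg$n_frames; R <- cfg$corral_radius
  dt <- 1 / cfg$framerate
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  # substep so single-reflection geometry holds at high D * dt
  nsub <- max(1L, ceiling(sd_step / (R / 4)))
  sd_sub <- sd_step / sqrt(nsub)
  pos <- matrix(0, n, 2L)
  steps <- matrix(stats::rnorm(2L * (n - 1L) * nsub, sd = sd_sub),
                  ncol = 2L)
  p <- c(0, 0); k <- 1L
  for (i in 2:n) {
    for (s in seq_len(nsub)) {
      p <- reflect_in_disk(p, p + steps[k, ], R)
      k <- k + 1L
    }
    pos[i, ] <- p
  }
  tr <- ispt_trajectory(pos[, 1], pos[, 2], framerate = cfg$framerate)
  attr(tr, "metadata")$corral_radius <- R
  tr
}

# per-axis compartment walls at multiples of L; rejected crossings reflect
hop_axis <- function(x0, steps, L, p_hop, u) {
  n <- length(steps)
  x <- numeric(n + 1L); x[1L] <- x0
  for (i in seq_len(n)) {
    cur <- x[i]; prop <- cur + steps[i]
    for (it in 1:32) {
      if (floor(prop / L) == floor(cur / L)) break
      if (u[i] < p_hop) break  # crossing permitted
      wall <- L * (floor(cur / L) + (prop > cur))
      prop <- 2 * wall - prop
    }
    x[i + 1L] <- prop
  }
  x
}

sim_hop <- function(cfg) {
  n <- cfg$n_frames; L <- cfg$compartment_side
  dt <- 1 / cfg$framerate
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  sx <- stats::rnorm(n - 1L, sd = sd_step)
  sy <- stats::rnorm(n - 1L, sd = sd_step)
  ux <- stats::runif(n - 1L); uy <- stats::runif(n - 1L)
  x <- hop_axis(L / 2, sx, L, cfg$hop_probability, ux)
  y <- hop_axis(L / 2, sy, L, cfg$hop_probability, uy)
  tr <- ispt_trajectory(x, y, framerate = cfg$framerate)
  attr(tr, "metadata")$compartment_side <- L
  tr
}

sim_bowl <- function(cfg) {
  n <- cfg$n_frames; R <- cfg$bowl_radius
  th_max <- cfg$bowl_cap_half_angle
  dt <- 1 / cfg$framerate
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  down <- c(0, 0, -1)
  pos <- matrix(0, n, 3L)
  p <- R * down                     # start at cap bottom
  pos[1L, ] <- p
  xi <- matrix(stats::rnorm(2L * (n - 1L), sd = sd_step), ncol = 2L)
  for (i in 2:n) {
    ph <- p / R
    # tangent basis at p
    a <- if (abs(ph[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- a - sum(a * ph) * ph; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ph[2] * e1[3] - ph[3] * e1[2],
            ph[3] * e1[1] - ph[1] * e1[3],
            ph[1] * e1[2] - ph[2] * e1[1])
    q <- p + xi[i - 1L, 1L] * e1 + xi[i - 1L, 2L] * e2
    q <- q * (R / sqrt(sum(q^2)))   # reproject to sphere
    th <- acos(max(-1, min(1, sum(q * down) / R)))
    if (th > th_max) {              # reflect polar angle at the cap rim
      th_new <- 2 * th_max - th
      # rotate q toward `down` in the plane spanned by q and down
      w <- q / R - cos(th) * down
      wn <- sqrt(sum(w^2))
      q <- if (wn < 1e-12) R * down else
        R * (cos(th_new) * down + sin(th_new) * (w / wn))
    }
    p <- q
    pos[i, ] <- p
  }
  # shift so the sphere centre sits at (0, 0, R): cap bottom at z = 0
  pos[, 3] <- pos[, 3] + R
  tr <- ispt_trajectory(pos[, 1], pos[, 2], pos[, 3],
                        framerate = cfg$framerate)
  attr(tr, "metadata")$bowl_center <- c(0, 0, R)
  attr(tr, "metadata")$bowl_radius <- R
  tr
}

sim_stepper <- function(cfg) {
  n <- cfg$n_frames; d <- cfg$dimensionality
  dt <- 1 / cfg$framerate
  duration <- (n - 1L) * dt
  # jump times: homogeneous Poisson process with rate dwell_rate
  jump_t <- numeric(0); tcur <- 0
  repeat {
    tcur <- tcur + stats::rexp(1, rate = cfg$dwell_rate)
    if (tcur >= duration) break
    jump_t <- c(jump_t, tcur)
  }
  t_frames <- (seq_len(n) - 1L) * dt
  s_true <- cfg$step_size * findInterval(t_frames, jump_t)
  axis <- rep_len(cfg$track_axis, d)
  pos <- outer(s_true, axis)
  if (cfg$jitter_sigma > 0)
    pos <- pos + matrix(stats::rnorm(n * d, sd = cfg$jitter_sigma), ncol = d)
  dd <- cfg$diffusion_coefficient
  if (dd > 0) {
    inc <- matrix(stats::rnorm((n - 1L) * d, sd = sqrt(2 * dd * dt)),
                  ncol = d)
    pos <- pos + apply(rbind(0, inc), 2L, cumsum)
  }
  tr <- ispt_trajectory(pos[, 1], pos[, 2], if (d == 3L) pos[, 3],
                        framerate = cfg$framerate)
  attr(tr, "metadata")$jump_frames <- findInterval(jump_t, t_frames) + 1L
  attr(tr, "metadata")$s_true <- s_true
  attr(tr, "metadata")$track_axis <- axis
  tr
}

sim_landing <- function(cfg) {
  n <- cfg$n_frames
  dt <- 1 / cfg$framerate
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  xy_inc <- matrix(stats::rnorm(2L * (n - 1L), sd = sd_step), ncol = 2L)
  xy <- apply(rbind(0, xy_inc), 2L, cumsum)
  z <- numeric(n); z[1L] <- cfg$start_height
  zi <- stats::rnorm(n - 1L, sd = sd_step)
  u <- stats::runif(n - 1L)
  bound <- FALSE; bind_frame <- NA_integer_
  for (i in 2:n) {
    if (bound) { z[i] <- 0; next }
    zp <- z[i - 1L] + zi[i - 1L]
    if (zp <= 0) {
      if (u[i - 1L] < cfg$binding_probability) {
        bound <- TRUE; bind_frame <- i - 1L; z[i] <- 0
      } else z[i] <- -zp
    } else z[i] <- zp
  }
  tr <- ispt_trajectory(xy[, 1], xy[, 2], z, framerate = cfg$framerate)
  attr(tr, "metadata")$bind_frame <- bind_frame
  tr
}

#' Add localization noise to a trajectory
#'
#' Observation model for the localization step: independent zero-mean
#' Gaussian noise of standard deviation `sigma_xy` per lateral axis (and
#' `sigma_z` axially for 3D trajectories) is added to every point, and the
#' precisions are recorded in the output. The expected measured 2D MSD then
#' exceeds the true MSD by the static-error offset `4 * sigma_xy^2` at every
#' lag, which [fit_temporal_exponent()] corrects for.
#'
#' @param traj an [ispt_trajectory()].
#' @param sigma_xy lateral precision per axis, nm (>= 0).
#' @param sigma_z axial precision, nm (3D trajectories only).
#' @param seed integer seed; makes the noise reproducible.
#' @return a new `ispt_trajectory` with noisy coordinates and sigma columns.
#' @export
add_localization_noise <- function(traj, sigma_xy, sigma_z = 0, seed = NULL) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  if (sigma_xy < 0 || sigma_z < 0) stop("sigma values must be >= 0")
  out <- traj
  n <- nrow(traj)
  if (!is.null(seed)) set.seed(seed)
  if (sigma_xy > 0) {
    out$x <- out$x + stats::rnorm(n, sd = sigma_xy)
    out$y <- out$y + stats::rnorm(n, sd = sigma_xy)
  }
  out$sigma_xy <- sigma_xy
  if (is_3d(traj)) {
    if (sigma_z > 0) out$z <- out$z + stats::rnorm(n, sd = sigma_z)
    out$sigma_z <- sigma_z
  }
  out
}
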