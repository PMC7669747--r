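#' Phenomenological interferometric PSF model
#'
#' Parametric model of the interferometric image of a sub-diffraction
#' scatterer. The recorded intensity, normalized to the reference level, is
#' the interference of the reference field (amplitude 1) with the scattered
#' field (relative amplitude `s`):
#' `I = |E_ref|^2 + |E_sca|^2 + 2 |E_ref||E_sca| cos(theta)`.
#' Here the pure scattering term `|E_sca|^2 <= s^2` is dropped (weak
#' scatterer, `s <= 0.5`), and the cross term is modelled as a
#' Gaussian-envelope ring pattern:
#'
#' `I(p) = 1 + 2 s exp(-r^2 / (2 w(z)^2)) cos(theta0 + 4 pi n_m z / lambda
#'         + beta (z - z_f) r^2)`
#'
#' with `r` the lateral pixel distance from the particle, and defocus
#' envelope `w(z) = w0 sqrt(1 + ((z - z_f)/z_R)^2)`. The axial phase
#' `4 pi n_m z / lambda` is the physically correct reflection path
#' difference: the central contrast `2 s cos(theta0 + 4 pi n_m z / lambda)`
#' alternates sign with height, which is what makes axial localization by
#' central-contrast calibration possible.
#'
#' @param wavelength illumination wavelength lambda, nm.
#' @param medium_index refractive index n_m of the medium.
#' @param scattering_amplitude s = |E_sca| / |E_ref| at the particle
#'   centre, in (0, 0.5].
#' @param phase_offset theta0, radians.
#' @param envelope_waist w0, pixels.
#' @param axial_range z_R of the defocus envelope, nm.
#' @param ring_phase_coefficient beta, radians / (nm * pixel^2); sets how
#'   quickly defocus rings appear.
#' @param pixel_size nm per pixel.
#' @param focus_height z_f, nm.
#' @return an `ipsf_model` list.
#' @export
ipsf_model <- function(wavelength = 550, medium_index = 1.33,
                       scattering_amplitude = 0.1, phase_offset = 0,
                       envelope_waist = 2.5, axial_range = 400,
                       ring_phase_coefficient = 5e-4,
                       pixel_size = 40, focus_height = 0) {
  if (scattering_amplitude <= 0 || scattering_amplitude > 0.5)
    stop("scattering_amplitude must be in (0, 0.5]")
  for (nm in c("wavelength", "medium_index", "envelope_waist",
               "axial_range", "pixel_size"))
    if (get(nm) <= 0) stop(nm, " must be > 0")
  structure(list(wavelength = wavelength, medium_index = medium_index,
                 scattering_amplitude = scattering_amplitude,
                 phase_offset = phase_offset,
                 envelope_waist = envelope_waist, axial_range = axial_range,
                 ring_phase_coefficient = ring_phase_coefficient,
                 pixel_size = pixel_size, focus_height = focus_height),
            class = "ipsf_model")
}

#' @export
print.ipsf_model <- function(x, ...) {
  cat(sprintf(
    "<ipsf_model> lambda %g nm, n_m %g, s %g, w0 %g px, %g nm/px\n",
    x$wavelength, x$medium_index, x$scattering_amplitude,
    x$envelope_waist, x$pixel_size))
  invisible(x)
}

# central contrast c(z) = 2 s cos(theta0 + 4 pi n_m z / lambda)
central_contrast <- function(model, z) {
  2 * model$scattering_amplitude *
    cos(model$phase_offset +
        4 * pi * model$medium_index * z / model$wavelength)
}

#' Synthesize one interferometric frame
#'
#' Renders the iPSF of a particle at `particle_xyz` into a frame of `shape`
#' pixels (see [ipsf_model()] for the image model). Pixel (row i, column j)
#' is centred at lateral position `((j - 0.5) px, (i - 0.5) px)` nm; the
#' localization routines use the same convention.
#'
#' @param model an [ipsf_model()].
#' @param particle_xyz length-3 numeric: lateral x, y (nm, frame
#'   coordinates) and height z (nm).
#' @param shape c(rows, cols), each >= 16.
#' @return numeric matrix of normalized intensities (1 = reference level).
#' @export
synthesize_frame <- function(model, particle_xyz, shape = c(48L, 48L)) {
  stopifnot(inherits(model, "ipsf_model"))
  if (any(shape < 16L)) stop("frame shape must be at least 16 x 16")
  px <- model$pixel_size
  xpx <- particle_xyz[1] / px; ypx <- particle_xyz[2] / px
  if (xpx < 0 || xpx > shape[2] || ypx < 0 || ypx > shape[1])
    stop("particle lies outside the frame")
  z <- particle_xyz[3]
  dz <- z - model$focus_height
  w <- model$envelope_waist * sqrt(1 + (dz / model$axial_range)^2)
  jj <- (seq_len(shape[2]) - 0.5) - xpx
  ii <- (seq_len(shape[1]) - 0.5) - ypx
  r2 <- outer(ii^2, jj^2, "+")        # squared pixel distance
  phase <- model$phase_offset +
    4 * pi * model$medium_index * z / model$wavelength +
    model$ring_phase_coefficient * dz * r2
  1 + 2 * model$scattering_amplitude * exp(-r2 / (2 * w^2)) * cos(phase)
}

#' Synthesize a dynamic speckle background stack
#'
#' Emulates the cell's interferometric speckle background: a spatially
#' correlated Gaussian field (white noise convolved with a Gaussian kernel
#' of width `correlation_length` pixels, normalized to unit variance)
#' evolving in time as a per-pixel AR(1) process with coefficient
#' `ar_coefficient` (1 = frozen speckle), scaled by `amplitude` around the
#' reference level 1, plus optional Gaussian shot noise.
#'
#' @param shape c(rows, cols).
#' @param n_frames number of frames.
#' @param amplitude speckle contrast (std of the field), >= 0.
#' @param correlation_length Gaussian kernel sigma in pixels (>= 1).
#' @param ar_coefficient temporal AR(1) coefficient in [0, 1].
#' @param shot_sigma per-pixel white noise std, >= 0.
#' @param framerate frames/second (for the frame time stamps).
#' @param seed integer seed.
#' @return a `frame_stack`: list with `pixels` (rows x cols x frames array),
#'   `pixel_size` (NA here; set by the imaging pipeline), `frame_times`,
#'   `background_params`.
#' @export
synthesize_background_stack <- function(shape, n_frames, amplitude = 0.03,
                                        correlation_length = 2,
                                        ar_coefficient = 0.99,
                                        shot_sigma = 0, framerate = 1000,
                                        seed = NULL) {
  if (correlation_length < 1) stop("correlation_length must be >= 1 pixel")
  if (ar_coefficient < 0 || ar_coefficient > 1)
    stop("ar_coefficient must be in [0, 1]")
  if (amplitude < 0 || shot_sigma < 0) stop("noise scales must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  smooth_field <- function() {
    f <- smooth_white_noise(shape, correlation_length)
    f / stats::sd(f)
  }
  pix <- array(0, dim = c(shape[1], shape[2], n_frames))
  if (amplitude > 0) {
    field <- smooth_field()
    pix[, , 1L] <- field
    innov_scale <- sqrt(1 - ar_coefficient^2)
    for (k in seq_len(n_frames - 1L)) {
      field <- ar_coefficient * field +
        (if (innov_scale > 0) innov_scale * smooth_field() else 0)
      pix[, , k + 1L] <- field
    }
    pix <- amplitude * pix
  }
  pix <- pix + 1
  if (shot_sigma > 0)
    pix <- pix + array(stats::rnorm(length(pix), sd = shot_sigma), dim = dim(pix))
  new_frame_stack(pix, pixel_size = NA_real_,
                  frame_times = (seq_len(n_frames) - 1L) / framerate,
                  background_params = list(amplitude = amplitude,
                                           correlation_length = correlation_length,
                                           ar_coefficient = ar_coefficient,
                                           shot_sigma = shot_sigma))
}

# white noise convolved with an isotropic Gaussian kernel (FFT, periodic)
smooth_white_noise <- function(shape, sigma_px) {
  wn <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  kx <- c(0:(shape[2] %/% 2), -((shape[2] - shape[2] %/% 2 - 1):1)) / shape[2]
  ky <- c(0:(shape[1] %/% 2), -((shape[1] - shape[1] %/% 2 - 1):1)) / shape[1]
  # Gaussian transfer function exp(-2 pi^2 sigma^2 k^2)
  tf <- exp(-2 * pi^2 * sigma_px^2 *
            outer(ky^2, kx^2, "+"))
  Re(stats::fft(stats::fft(wn) * tf, inverse = TRUE)) / length(wn)
}

new_frame_stack <- function(pixels, pixel_size, frame_times,
                            background_params = list()) {
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_times = frame_times,
                 background_params = background_params),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%s nm/px)\n",
              d[3], d[1], d[2],
              if (is.na(x$pixel_size)) "?" else format(x$pixel_size)))
  invisible(x)
}

#' Synthesize an image stack for a 3D trajectory
#'
#' Renders one frame per trajectory point (particle iPSF added on top of
#' the speckle background as `background + (particle - 1)`), producing the
#' input expected by the localization pipeline. The trajectory's lateral
#' origin is mapped to the frame centre.
#'
#' @param model an [ipsf_model()].
#' @param traj a 3D [ispt_trajectory()] (heights in nm).
#' @param shape frame shape in pixels.
#' @param background optional `frame_stack` from
#'   [synthesize_background_stack()] with matching shape and frame count;
#'   `NULL` gives a clean background of 1.
#' @return a `frame_stack` with `pixel_size` from the model and the true
#'   particle pixel positions recorded in `background_params$truth_px`.
#' @export
synthesize_trajectory_stack <- function(model, traj, shape = c(48L, 48L),
                                        background = NULL) {
  stopifnot(inherits(model, "ipsf_model"), inherits(traj, "ispt_trajectory"))
  if (!is_3d(traj)) stop("imaging needs a 3D trajectory")
  n <- n_points(traj)
  ctr <- c(shape[2] / 2, shape[1] / 2) * model$pixel_size
  if (!is.null(background)) {
    stopifnot(inherits(background, "frame_stack"))
    if (!all(dim(background$pixels) == c(shape, n)))
      stop("background stack shape/frames do not match")
  }
  pix <- array(1, dim = c(shape[1], shape[2], n))
  for (k in seq_len(n)) {
    xyz <- c(traj$x[k] + ctr[1], traj$y[k] + ctr[2], traj$z[k])
    pix[, , k] <- synthesize_frame(model, xyz, shape)
    if (!is.null(background))
      pix[, , k] <- pix[, , k] + background$pixels[, , k] - 1
  }
  truth <- cbind(x_px = (traj$x + ctr[1]) / model$pixel_size,
                 y_px = (traj$y + ctr[2]) / model$pixel_size,
                 z_nm = traj$z)
  new_frame_stack(pix, pixel_size = model$pixel_size,
                  frame_times = traj$t,
                  background_params = list(truth_px = truth))
}

#' Remove the slowly varying background of a stack
#'
#' Subtracts the sliding per-pixel temporal median (window `median_window`
#' frames, odd) and re-adds the reference level 1. A background that is
#' static — or slowly varying relative to the window — is removed exactly,
#' while a particle that occupies any given pixel for less than half the
#' window leaves the median untouched and so survives with its contrast
#' intact.
#'
#' @param stack a `frame_stack`.
#' @param median_window odd integer, 3 <= window <= n_frames.
#' @return a background-corrected `frame_stack`.
#' @export
remove_background <- function(stack, median_window) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$pixels)[3]
  if (median_window %% 2 != 1 || median_window < 3)
    stop("median_window must be odd and >= 3")
  if (median_window > n) stop("median_window exceeds stack length")
  d <- dim(stack$pixels)
  flat <- matrix(aperm(stack$pixels, c(3L, 1L, 2L)), nrow = n)
  med <- apply(flat, 2L, stats::runmed, k = median_window,
               endrule = "median")
  corrected <- aperm(array(flat - med + 1, dim = c(n, d[1], d[2])),
                     c(2L, 3L, 1L))
  out <- stack
  out$pixels <- corrected
  out$background_params$median_window <- median_window
  out
}

#' Axial calibration of the central iPSF contrast
#'
#' Tabulates the central contrast
#' `c(z) = 2 s cos(theta0 + 4 pi n_m z / lambda)` on a z grid and splits it
#' into monotonic branches between consecutive extrema. Within a branch,
#' `c(z)` is single-valued and invertible, which is how a measured central
#' contrast is turned into a height; across branches the cosine is
#' ambiguous and must be resolved by temporal continuity
#' (see [localize_frame()]).
#'
#' @param model an [ipsf_model()].
#' @param z_range length-2 numeric, nm.
#' @param dz grid spacing, nm (> 0).
#' @return an `axial_calibration`: list with `z_grid`, `contrast`, and
#'   `branches` (data frame `z_lo`, `z_hi`, `i_lo`, `i_hi`).
#' @export
build_axial_calibration <- function(model, z_range, dz) {
  stopifnot(inherits(model, "ipsf_model"))
  if (dz <= 0) stop("dz must be > 0")
  if (diff(z_range) <= 0) stop("empty z_range")
  z <- seq(z_range[1], z_range[2], by = dz)
  if (length(z) < 3L) stop("z_range must contain at least 3 grid points")
  cc <- central_contrast(model, z)
  dsign <- sign(diff(cc))
  ext <- which(diff(dsign) != 0 & dsign[-1] != 0) + 1L
  bounds <- unique(c(1L, ext, length(z)))
  branches <- data.frame(i_lo = bounds[-length(bounds)],
                         i_hi = bounds[-1L])
  branches$z_lo <- z[branches$i_lo]
  branches$z_hi <- z[branches$i_hi]
  structure(list(z_grid = z, contrast = cc, branches = branches,
                 model = model),
            class = "axial_calibration")
}

#' @export
print.axial_calibration <- function(x, ...) {
  cat(sprintf("<axial_calibration> z in [%g, %g] nm, %d branches\n",
              min(x$z_grid), max(x$z_grid), nrow(x$branches)))
  invisible(x)
}

#' Write / read an axial calibration as delimited text
#'
#' Two-column format `z_nm, contrast`; branch structure is recomputed on
#' read.
#'
#' @param calib an `axial_calibration`.
#' @param path file path.
#' @return `read_axial_calibration` returns an `axial_calibration` (with
#'   no model attached).
#' @export
write_axial_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "axial_calibration"))
  utils::write.csv(data.frame(z_nm = calib$z_grid,
                              contrast = calib$contrast),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_axial_calibration
#' @export
read_axial_calibration <- function(path) {
  df <- utils::read.csv(path)
  z <- df$z_nm; cc <- df$contrast
  dsign <- sign(diff(cc))
  ext <- which(diff(dsign) != 0 & dsign[-1] != 0) + 1L
  bounds <- unique(c(1L, ext, length(z)))
  branches <- data.frame(i_lo = bounds[-length(bounds)], i_hi = bounds[-1L])
  branches$z_lo <- z[branches$i_lo]
  branches$z_hi <- z[branches$i_hi]
  structure(list(z_grid = z, contrast = cc, branches = branches,
                 model = NULL),
            class = "axial_calibration")
}

#' Write / read a frame stack as multi-page TIFF
#'
#' 32-bit float, one page per frame in time order. TIFF samples are stored
#' as `gain * I`: the writer requires values in [0, 1], and normalized
#' interferometric intensities live around the reference level 1 (up to
#' `1 + 2s <= 2`), so the default gain of 0.5 maps them losslessly into
#' range. The reader inverts the same gain.
#'
#' @param stack a `frame_stack`.
#' @param path file path.
#' @param gain intensity-to-sample scale factor (default 0.5).
#' @param pixel_size,framerate metadata to attach on read.
#' @return `read_frame_stack` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path, gain = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  if (any(stack$pixels * gain < 0) || any(stack$pixels * gain > 1))
    stop("intensities out of TIFF sample range at this gain")
  n <- dim(stack$pixels)[3]
  pages <- lapply(seq_len(n), function(k) stack$pixels[, , k] * gain)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, pixel_size = NA_real_, framerate = 1,
                             gain = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pix <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) pix[, , k] <- pages[[k]] / gain
  new_frame_stack(pix, pixel_size = pixel_size,
                  frame_times = (seq_along(pages) - 1L) / framerate)
}
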