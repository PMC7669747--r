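#' Lateral localization by radial symmetry
#'
#' Finds the centre of the ring-patterned iPSF within a crop around
#' `approximate_center`. Because the rings alternate in sign, the squared
#' contrast `(I - 1)^2` is used, which is radially symmetric about the
#' particle regardless of ring polarity. The centre is the point that all
#' image-gradient lines pass closest to, in the least-squares sense: with
#' unit gradient direction `g_k` at pixel position `p_k` and weight
#' `w_k = |grad|^2`, solve `sum w_k (I - g g') (c - p_k) = 0` (a 2x2
#' system). The direction-vector form avoids slope singularities.
#'
#' @param frame numeric intensity matrix (reference level 1).
#' @param approximate_center length-2 c(x, y) in pixels.
#' @param crop_radius half-width of the square crop, pixels; the crop must
#'   lie fully inside the frame.
#' @param pixel_size nm per pixel; when given, the returned positions are
#'   in nm instead of pixels.
#' @return length-2 c(x, y), pixels (or nm when `pixel_size` is given),
#'   in the frame coordinate convention of [synthesize_frame()].
#' @export
localize_lateral <- function(frame, approximate_center, crop_radius = 10L,
                             pixel_size = NULL) {
  dims <- dim(frame)
  cx <- approximate_center[1]; cy <- approximate_center[2]
  j0 <- round(cx - crop_radius + 0.5); j1 <- round(cx + crop_radius - 0.5)
  i0 <- round(cy - crop_radius + 0.5); i1 <- round(cy + crop_radius - 0.5)
  if (i0 < 1 || j0 < 1 || i1 > dims[1] || j1 > dims[2])
    stop("crop window extends outside the frame")
  u <- (frame[i0:i1, j0:j1] - 1)^2
  ni <- nrow(u); nj <- ncol(u)
  # central gradients at interior pixels, lightly smoothed (3x3 mean)
  gx <- (u[2:(ni - 1), 3:nj] - u[2:(ni - 1), 1:(nj - 2)]) / 2
  gy <- (u[3:ni, 2:(nj - 1)] - u[1:(ni - 2), 2:(nj - 1)]) / 2
  gx <- mean3(gx); gy <- mean3(gy)
  g2 <- gx^2 + gy^2
  tot <- sum(g2)
  if (tot <= 0 || !is.finite(tot))
    stop("no-detection: flat crop, no radial-symmetry signal")
  # pixel-centre coordinates of the interior grid, frame convention
  xs <- (j0 + (2:(nj - 1)) - 1) - 0.5
  ys <- (i0 + (2:(ni - 1)) - 1) - 0.5
  X <- matrix(xs, ni - 2, nj - 2, byrow = TRUE)
  Y <- matrix(ys, ni - 2, nj - 2)
  # damp far-from-centre gradients: weight by gradient power over distance
  # to the gradient-magnitude centroid (robust to residual background)
  xc0 <- sum(g2 * X) / tot; yc0 <- sum(g2 * Y) / tot
  dctr <- sqrt((X - xc0)^2 + (Y - yc0)^2)
  w <- g2 / (dctr + 0.5)
  gxn <- gx / sqrt(g2 + (g2 == 0)); gyn <- gy / sqrt(g2 + (g2 == 0))
  # M c = b with M = sum w (I - g g'), b = sum w (I - g g') p
  a11 <- sum(w * (1 - gxn * gxn)); a12 <- sum(w * (-gxn * gyn))
  a22 <- sum(w * (1 - gyn * gyn))
  b1 <- sum(w * ((1 - gxn * gxn) * X - gxn * gyn * Y))
  b2 <- sum(w * (-gxn * gyn * X + (1 - gyn * gyn) * Y))
  det <- a11 * a22 - a12 * a12
  if (!is.finite(det) || abs(det) < 1e-12 * tot^2)
    stop("no-detection: degenerate gradient structure in crop")
  ctr <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
  if (!is.null(pixel_size)) ctr <- ctr * pixel_size
  ctr
}

# 3x3 mean filter, edges kept (shrinking window)
mean3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  acc <- matrix(0, n1, n2); cnt <- matrix(0, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 + di):min(n1, n1 + di)
    sj <- max(1, 1 + dj):min(n2, n2 + dj)
    ti <- max(1, 1 - di):min(n1, n1 - di)
    tj <- max(1, 1 - dj):min(n2, n2 - dj)
    acc[ti, tj] <- acc[ti, tj] + m[si, sj]
    cnt[ti, tj] <- cnt[ti, tj] + 1
  }
  acc / cnt
}

# bilinear interpolation of matrix `m` at frame coordinates (x, y) px
bilinear_at <- function(m, x, y) {
  # pixel (i, j) centre at (j - 0.5, i - 0.5)
  fj <- x + 0.5; fi <- y + 0.5
  j0 <- floor(fj); i0 <- floor(fi)
  j0 <- min(max(j0, 1L), ncol(m) - 1L)
  i0 <- min(max(i0, 1L), nrow(m) - 1L)
  tx <- fj - j0; ty <- fi - i0
  m[i0, j0] * (1 - tx) * (1 - ty) + m[i0, j0 + 1L] * tx * (1 - ty) +
    m[i0 + 1L, j0] * (1 - tx) * ty + m[i0 + 1L, j0 + 1L] * tx * ty
}

# quadratic (3x3 least-squares) interpolation at frame coordinates (x, y);
# unlike bilinear it is exact to second order, which matters because the
# iPSF centre is strongly curved (ring phase), and a first-order scheme
# biases the read-out of the central contrast
quadratic_at <- function(m, x, y) {
  jc <- round(x + 0.5); ic <- round(y + 0.5)
  jc <- min(max(jc, 2L), ncol(m) - 1L)
  ic <- min(max(ic, 2L), nrow(m) - 1L)
  f <- m[(ic - 1L):(ic + 1L), (jc - 1L):(jc + 1L)]
  v <- matrix(-1:1, 3, 3)   # row (y) offset
  u <- t(v)                 # column (x) offset
  # closed-form LS quadratic a + b u + c v + d u^2 + e v^2 + g u v on 3x3
  b <- sum(u * f) / 6; cc <- sum(v * f) / 6
  d <- sum((u^2 - 2 / 3) * f) / 2
  e <- sum((v^2 - 2 / 3) * f) / 2
  g <- sum(u * v * f) / 4
  a <- sum(f) / 9 - 2 / 3 * (d + e)
  du <- (x + 0.5) - jc; dv <- (y + 0.5) - ic
  a + b * du + cc * dv + d * du^2 + e * dv^2 + g * du * dv
}

# branch of a calibration containing (or nearest to) z
pick_branch <- function(calib, z) {
  br <- calib$branches
  inside <- which(z >= br$z_lo & z <= br$z_hi)
  if (length(inside)) return(inside[1L])
  d <- pmin(abs(z - br$z_lo), abs(z - br$z_hi))
  which.min(d)
}

# invert contrast on one monotonic branch; clips outside with flag
invert_branch <- function(calib, branch, contrast) {
  idx <- calib$branches$i_lo[branch]:calib$branches$i_hi[branch]
  cc <- calib$contrast[idx]; zz <- calib$z_grid[idx]
  lo <- min(cc); hi <- max(cc)
  clipped <- contrast < lo || contrast > hi
  contrast <- min(max(contrast, lo), hi)
  ord <- order(cc)
  z <- stats::approx(cc[ord], zz[ord], xout = contrast, ties = "ordered")$y
  list(z = z, clipped = clipped)
}

#' Localize a particle in one frame (3D)
#'
#' Lateral centre by [localize_lateral()]; central contrast read as a
#' local quadratic (3x3 least-squares) interpolation of `I - 1` at the
#' recovered centre — second-order accuracy matters here because the iPSF
#' centre is curved by the ring phase; height by
#' inverting the axial calibration on the monotonic branch containing
#' `previous_z` (temporal continuity resolves the cosine's branch
#' ambiguity). A contrast outside the branch range is clipped to the branch
#' endpoint and flagged in `quality`.
#'
#' @param frame numeric intensity matrix (background-corrected, level 1).
#' @param calibration an `axial_calibration`.
#' @param approximate_center c(x, y) starting guess, pixels.
#' @param previous_z height of the previous frame, nm; required (on the
#'   first frame pass the known starting branch height).
#' @param crop_radius crop half-width, pixels.
#' @param pixel_size nm per pixel.
#' @return one-row data frame: `x`, `y` (nm), `z` (nm), `central_contrast`,
#'   `quality` (`"ok"` or `"clipped"`).
#' @export
localize_frame <- function(frame, calibration, approximate_center,
                           previous_z = NULL, crop_radius = 10L,
                           pixel_size) {
  stopifnot(inherits(calibration, "axial_calibration"))
  if (is.null(previous_z))
    stop("previous_z is required to select the calibration branch ",
         "(pass the starting height on the first frame)")
  ctr_px <- localize_lateral(frame, approximate_center, crop_radius)
  contrast <- quadratic_at(frame, ctr_px[1], ctr_px[2]) - 1
  branch <- pick_branch(calibration, previous_z)
  # continuity tracking: also consider the adjacent branches and keep the
  # un-clipped solution nearest to previous_z
  cand <- intersect(branch + (-1L:1L),
                    seq_len(nrow(calibration$branches)))
  invs <- lapply(cand, function(b) invert_branch(calibration, b, contrast))
  ok <- !vapply(invs, `[[`, logical(1), "clipped")
  pool <- if (any(ok)) invs[ok] else invs[cand == branch]
  inv <- pool[[which.min(vapply(pool, function(v) abs(v$z - previous_z),
                                numeric(1)))]]
  data.frame(x = ctr_px[1] * pixel_size, y = ctr_px[2] * pixel_size,
             z = inv$z, central_contrast = contrast,
             quality = if (inv$clipped) "clipped" else "ok")
}

#' Localize a particle through a frame stack
#'
#' Runs [localize_frame()] frame by frame, chaining the recovered lateral
#' centre and height as the next frame's starting guess, and returns the
#' result as an [ispt_trajectory()] in frame coordinates (nm).
#'
#' @param stack a background-corrected `frame_stack` with known
#'   `pixel_size`.
#' @param calibration an `axial_calibration`.
#' @param start_center c(x, y) guess for the first frame, pixels.
#' @param start_z starting height (selects the first branch), nm.
#' @param crop_radius crop half-width, pixels.
#' @param framerate frames/second of the recording.
#' @return an `ispt_trajectory` with metadata column `quality` and
#'   `central_contrast` kept in the metadata.
#' @export
localize_stack <- function(stack, calibration, start_center, start_z,
                           crop_radius = 10L, framerate) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixel_size
  if (is.na(px)) stop("stack has no pixel_size")
  n <- dim(stack$pixels)[3]
  out <- vector("list", n)
  ctr <- start_center; zprev <- start_z
  for (k in seq_len(n)) {
    loc <- localize_frame(stack$pixels[, , k], calibration, ctr,
                          previous_z = zprev, crop_radius = crop_radius,
                          pixel_size = px)
    out[[k]] <- loc
    ctr <- c(loc$x, loc$y) / px
    zprev <- loc$z
  }
  res <- do.call(rbind, out)
  tr <- ispt_trajectory(res$x, res$y, res$z, framerate = framerate,
                        metadata = list(source = "localize_stack",
                                        central_contrast = res$central_contrast,
                                        quality = res$quality))
  tr
}
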