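#' Fit a sphere to a 3D confined trajectory
#'
#' Least-squares sphere fit for trajectories confined to bowl/pit-like
#' membrane invaginations: first the linearized algebraic fit (the sphere
#' equation `|p|^2 - 2 p . c + |c|^2 - R^2 = 0` is linear in `(c, R^2)`),
#' then Gauss-Newton refinement of the geometric distance residuals
#' `|p_i - c| - R`. Because a bowl is a spherical *cap*, two diameters are
#' reported: the full sphere diameter `2R` (the headline figure) and the
#' opening diameter, the maximal extent of the points projected on the
#' plane perpendicular to the bowl axis. The axis points from the sphere
#' centre toward the point centroid (into the cap).
#'
#' @param traj an [ispt_trajectory()] with z, or a 3-column matrix (nm).
#' @param refine_iter Gauss-Newton iterations (default 5; 0 gives the
#'   purely algebraic fit).
#' @return a `bowl_fit`: list with `center` (nm), `radius` (nm),
#'   `sphere_diameter`, `opening_diameter`, `axis` (unit 3-vector),
#'   `rms_residual` (nm), `n_points`.
#' @export
fit_bowl <- function(traj, refine_iter = 5L) {
  p <- if (inherits(traj, "ispt_trajectory")) {
    if (!is_3d(traj)) stop("bowl fitting needs a 3D trajectory")
    traj_positions(traj, use_z = TRUE)
  } else as.matrix(traj)
  if (ncol(p) != 3L) stop("need 3 coordinate columns")
  if (nrow(p) < 4L) stop("need at least 4 points")
  A <- cbind(2 * p, 1)
  b <- rowSums(p * p)
  sv <- svd(A)
  if (sv$d[4] < 1e-10 * sv$d[1])
    stop("degenerate point set: points are (near-)coplanar, ",
         "sphere is unidentifiable")
  coef <- sv$v %*% ((crossprod(sv$u, b)) / sv$d)
  ctr <- coef[1:3]
  R2 <- coef[4] + sum(ctr^2)
  if (R2 <= 0) stop("degenerate point set: non-positive fitted radius")
  R <- sqrt(R2)
  for (it in seq_len(refine_iter)) {
    dvec <- sweep(p, 2L, ctr)
    dist <- sqrt(rowSums(dvec * dvec))
    if (any(dist < 1e-12)) break
    r <- dist - R
    J <- cbind(-dvec / dist, -1)
    upd <- try(qr.solve(J, -r), silent = TRUE)
    if (inherits(upd, "try-error")) break
    ctr <- ctr + upd[1:3]; R <- R + upd[4]
    if (sqrt(sum(upd^2)) < 1e-10 * R) break
  }
  dist <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
  rms <- sqrt(mean((dist - R)^2))
  ax <- colMeans(p) - ctr
  ax <- ax / sqrt(sum(ax^2))
  # opening diameter: maximal pairwise extent of in-plane projections
  q <- sweep(p, 2L, ctr)
  e1 <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  uv <- cbind(q %*% e1, q %*% e2)
  hull <- grDevices::chull(uv)
  opening <- if (length(hull) >= 2L) max(stats::dist(uv[hull, , drop = FALSE]))
             else 0
  structure(list(center = as.numeric(ctr), radius = R,
                 sphere_diameter = 2 * R, opening_diameter = opening,
                 axis = as.numeric(ax), rms_residual = rms,
                 n_points = nrow(p)),
            class = "bowl_fit")
}

#' @export
print.bowl_fit <- function(x, ...) {
  cat(sprintf("<bowl_fit> R = %.1f nm (sphere diameter %.1f nm), %d points\n",
              x$radius, x$sphere_diameter, x$n_points))
  cat(sprintf("  opening %.1f nm, rms residual %.2f nm, axis (%.2f, %.2f, %.2f)\n",
              x$opening_diameter, x$rms_residual,
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Angular position series about a bowl centre
#'
#' Projects each 3D point onto the plane perpendicular to the bowl axis
#' through the sphere centre and reports the signed, unwrapped azimuth
#' phi(t) relative to the first frame's in-plane direction. Points whose
#' in-plane projection is shorter than 1 nm (on the axis) carry the
#' previous phi, flagged.
#'
#' @param traj a 3D [ispt_trajectory()].
#' @param fit a `bowl_fit` for the same trajectory.
#' @return an `angular_series` data frame: `t` (s), `phi` (rad, unwrapped),
#'   `phi_wrapped` (rad in (-pi, pi]), `flagged`; attribute
#'   `reference_direction` (unit 3-vector).
#' @export
angular_series <- function(traj, fit) {
  stopifnot(inherits(traj, "ispt_trajectory"), inherits(fit, "bowl_fit"))
  if (!is_3d(traj)) stop("angular series needs a 3D trajectory")
  p <- traj_positions(traj, use_z = TRUE)
  q <- sweep(p, 2L, fit$center)
  ax <- fit$axis
  w <- q - outer(as.numeric(q %*% ax), ax)
  lens <- sqrt(rowSums(w * w))
  if (lens[1] < 1e-9) stop("first frame projects onto the bowl axis; ",
                           "no reference direction")
  ref <- w[1L, ] / lens[1L]
  e2 <- c(ax[2] * ref[3] - ax[3] * ref[2],
          ax[3] * ref[1] - ax[1] * ref[3],
          ax[1] * ref[2] - ax[2] * ref[1])
  phi_w <- atan2(as.numeric(w %*% e2), as.numeric(w %*% ref))
  flagged <- lens < 1
  for (i in which(flagged)) phi_w[i] <- if (i > 1L) phi_w[i - 1L] else 0
  dphi <- diff(phi_w)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  phi <- cumsum(c(phi_w[1L], dphi))
  structure(data.frame(t = traj$t, phi = phi, phi_wrapped = phi_w,
                       flagged = flagged),
            reference_direction = ref,
            class = c("angular_series", "data.frame"))
}
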