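#' Single-particle trajectory objects
#'
#' An `ispt_trajectory` is a data frame with one row per frame and columns
#' `frame` (0-based integer), `t` (seconds), `x`, `y` and optionally `z`
#' (nanometres), plus optional per-point localization precisions
#' `sigma_xy` and `sigma_z` (nanometres). The acquisition rate is stored in
#' the `framerate` attribute (frames/second) and free-form provenance in
#' `metadata`. All analysis stages in the package consume this object.
#'
#' Conventions, enforced everywhere: coordinates in nm, time in seconds,
#' frames 0-based and uniformly spaced at 1/framerate.
#'
#' @param x,y,z numeric coordinate vectors in nm (`z` optional).
#' @param framerate frames per second (> 0).
#' @param frame optional 0-based frame indices; defaults to `0:(n-1)`.
#' @param t optional time stamps in seconds; defaults to `frame / framerate`.
#' @param sigma_xy,sigma_z optional localization precision (nm), scalar or
#'   per point.
#' @param metadata named list of provenance information.
#' @return an object of class `ispt_trajectory` (also a `data.frame`).
#' @examples
#' tr <- ispt_trajectory(x = c(0, 1, 3, 2, 4), y = rep(0, 5), framerate = 100)
#' n_points(tr)
#' @export
ispt_trajectory <- function(x, y, z = NULL, framerate,
                            frame = NULL, t = NULL,
                            sigma_xy = NULL, sigma_z = NULL,
                            metadata = list()) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (!is.null(z) && length(z) != n) stop("z must match x/y length")
  if (!is.numeric(framerate) || length(framerate) != 1L || framerate <= 0)
    stop("framerate must be a single positive number")
  if (is.null(frame)) frame <- seq_len(n) - 1L
  if (is.null(t)) t <- frame / framerate
  df <- data.frame(frame = as.integer(frame), t = t, x = x, y = y)
  if (!is.null(z)) df$z <- z
  if (!is.null(sigma_xy)) df$sigma_xy <- rep_len(sigma_xy, n)
  if (!is.null(sigma_z)) df$sigma_z <- rep_len(sigma_z, n)
  structure(df,
            framerate = framerate,
            metadata = metadata,
            class = c("ispt_trajectory", "data.frame"))
}

#' Validate an `ispt_trajectory`
#'
#' Checks the invariants every analysis stage relies on: strictly increasing,
#' uniformly spaced time stamps; finite positions; non-negative precisions.
#'
#' @param traj an `ispt_trajectory`.
#' @param tol absolute tolerance (s) for uniform frame spacing.
#' @return `traj`, invisibly; errors describe the first violated invariant.
#' @export
validate_trajectory <- function(traj, tol = 1e-9) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  if (nrow(traj) < 2L) stop("trajectory needs at least 2 points")
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (any(abs(dt - 1 / framerate(traj)) > tol))
    stop("frames are not uniformly spaced at 1/framerate")
  pos <- traj_positions(traj)
  if (!all(is.finite(pos))) stop("positions must be finite")
  for (s in intersect(c("sigma_xy", "sigma_z"), names(traj)))
    if (any(traj[[s]] < 0)) stop(s, " must be >= 0")
  invisible(traj)
}

#' @export
print.ispt_trajectory <- function(x, ...) {
  dim3 <- if (is_3d(x)) "3D" else "2D"
  cat(sprintf("<ispt_trajectory> %d frames, %s, %g fps, %.4g s\n",
              nrow(x), dim3, framerate(x), nrow(x) / framerate(x)))
  md <- attr(x, "metadata")
  if (length(md) && !is.null(md$model))
    cat("  model:", md$model, "\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' @rdname ispt_trajectory
#' @param traj an `ispt_trajectory`.
#' @export
framerate <- function(traj) attr(traj, "framerate")

#' @rdname ispt_trajectory
#' @export
is_3d <- function(traj) "z" %in% names(traj)

#' @rdname ispt_trajectory
#' @export
n_points <- function(traj) nrow(traj)

#' Position matrix of a trajectory
#'
#' @param traj an `ispt_trajectory`.
#' @param use_z include the z column when present.
#' @return numeric matrix, one row per frame, columns x/y(/z) in nm.
#' @export
traj_positions <- function(traj, use_z = is_3d(traj)) {
  cols <- c("x", "y", if (use_z && is_3d(traj)) "z")
  as.matrix(as.data.frame(traj)[, cols, drop = FALSE])
}

# scalar sigma_xy for a trajectory: column median if per-point, else 0
traj_sigma_xy <- function(traj) {
  if ("sigma_xy" %in% names(traj)) stats::median(traj$sigma_xy) else 0
}
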