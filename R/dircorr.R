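#' Enumerate step pairs separated by tau frames
#'
#' For every start row `t` with `t + 2 tau` inside `[start, end]`, forms the
#' two consecutive lateral steps `dr1 = r(t + tau) - r(t)` and
#' `dr2 = r(t + 2 tau) - r(t + tau)` and the cosine of the angle between
#' them. Pairs where either step has zero length get `NA` cosine.
#'
#' @param traj an [ispt_trajectory()].
#' @param tau step separation in frames (>= 1).
#' @param start,end segment rows (1-based, inclusive).
#' @return data frame: `t` (start row), `dx1`, `dy1`, `dx2`, `dy2`,
#'   `len1`, `len2`, `cosine`.
#' @examples
#' tr <- ispt_trajectory(x = c(0, 1, 2, 1, 0, 1), y = rep(0, 6), framerate = 1)
#' step_vectors(tr, tau = 1)$cosine  # +1 -1 +1 -1
#' @export
step_vectors <- function(traj, tau, start = 1L, end = n_points(traj)) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1 frame")
  if (end - start < 2L * tau) stop("segment shorter than 2 * tau")
  ts <- start:(end - 2L * tau)
  x <- traj$x; y <- traj$y
  dx1 <- x[ts + tau] - x[ts];        dy1 <- y[ts + tau] - y[ts]
  dx2 <- x[ts + 2L * tau] - x[ts + tau]
  dy2 <- y[ts + 2L * tau] - y[ts + tau]
  len1 <- sqrt(dx1^2 + dy1^2); len2 <- sqrt(dx2^2 + dy2^2)
  cosine <- ifelse(len1 > 0 & len2 > 0,
                   (dx1 * dx2 + dy1 * dy2) / (len1 * len2), NA_real_)
  data.frame(t = ts, dx1 = dx1, dy1 = dy1, dx2 = dx2, dy2 = dy2,
             len1 = len1, len2 = len2, cosine = cosine)
}

#' Rolling directional correlation
#'
#' The directional correlation `C_i` of a window is the mean cosine of the
#' angle between consecutive tau-frame steps, over all (overlapping) step
#' pairs that fit inside the window. `C = 0` for a memoryless walk,
#' `C < 0` under knock-back from obstacles, `C > 0` under persistent
#' directed motion. The default step separation is tau = 5 frames.
#'
#' Pairs in which either step is shorter than `min_step` are skipped and
#' counted: the direction of a noise-dominated displacement is meaningless.
#' A sensible floor when localization noise dominates is
#' `sigma_xy * sqrt(8)` (the RMS length of a pure-noise displacement summed
#' over two axes and two points).
#'
#' @param traj an [ispt_trajectory()].
#' @param tau step separation in frames (default 5); `2 * tau < window`.
#' @param window,stride window length and step, frames.
#' @param min_step minimum step length (nm) for a pair to count.
#' @return a `window_series` data frame with columns `window`, `start`,
#'   `end`, `t_center`, `C`, `C_se`, `n_pairs`, `n_skipped`; windows with no
#'   valid pair carry `NA`.
#' @export
rolling_directional_correlation <- function(traj, tau = 5L, window,
                                            stride = max(1L, window %/% 10L),
                                            min_step = 0) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  tau <- as.integer(tau)
  n <- n_points(traj)
  if (tau < 1L) stop("tau must be >= 1")
  if (2L * tau >= window) stop("window must exceed 2 * tau")
  if (window > n) stop("window exceeds trajectory length")
  fr <- framerate(traj)
  sv <- step_vectors(traj, tau)
  valid <- !is.na(sv$cosine) & sv$len1 >= min_step & sv$len2 >= min_step
  cval <- ifelse(valid, sv$cosine, 0)
  cs1 <- c(0, cumsum(cval))            # sum of cosines
  cs2 <- c(0, cumsum(cval^2))          # sum of squared cosines
  csn <- c(0, cumsum(as.numeric(valid)))
  starts <- seq(1L, n - window + 1L, by = stride)
  npair_max <- window - 2L * tau       # start rows a .. a+window-1-2tau
  res <- data.frame(window = seq_along(starts), start = starts,
                    end = starts + window - 1L,
                    t_center = traj$t[starts] + (window - 1L) / (2 * fr),
                    C = NA_real_, C_se = NA_real_,
                    n_pairs = 0L, n_skipped = 0L)
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- a + npair_max  # pair start rows a .. b-1
    m <- csn[b] - csn[a]
    res$n_pairs[i] <- m
    res$n_skipped[i] <- npair_max - m
    if (m >= 1) {
      s1 <- cs1[b] - cs1[a]; s2 <- cs2[b] - cs2[a]
      res$C[i] <- s1 / m
      if (m >= 2) {
        var <- max(0, (s2 - s1^2 / m) / (m - 1))
        res$C_se[i] <- sqrt(var / m)
      }
    }
  }
  structure(res, T_w = window / fr, window = window, stride = stride,
            tau = tau, framerate = fr,
            class = c("window_series", "data.frame"))
}
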