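#' Project a directed segment onto its travel axis
#'
#' Estimates the global direction of travel of a trajectory segment as the
#' principal eigenvector of the lateral position covariance (robust to
#' back-and-forth legs), sign-oriented along the net displacement, and
#' decomposes every position into a signed on-axis coordinate `s(t)` and a
#' signed perpendicular residual `perp(t)` about the segment centroid.
#' `axis_mode = "endpoint"` instead uses the start-to-end displacement
#' vector as the axis.
#'
#' @param traj an [ispt_trajectory()].
#' @param start,end segment rows (1-based, inclusive; >= 10 frames).
#' @param axis_mode `"principal"` (default) or `"endpoint"`.
#' @return a `projected_walk`: list with `axis` (unit 2-vector), `origin`
#'   (centroid, nm), `s`, `perp` (nm), `t` (s), `frames` (rows),
#'   `isotropic` flag (eigenvalue ratio < 2 — axis poorly defined),
#'   `framerate`.
#' @export
project_onto_axis <- function(traj, start = 1L, end = n_points(traj),
                              axis_mode = c("principal", "endpoint")) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  axis_mode <- match.arg(axis_mode)
  if (end - start + 1L < 10L) stop("segment must span at least 10 frames")
  rows <- start:end
  p <- cbind(traj$x[rows], traj$y[rows])
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  if (all(abs(pc) < 1e-12)) stop("degenerate segment: all points identical")
  cv <- crossprod(pc) / (nrow(pc) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  isotropic <- eg$values[2] > 0 && eg$values[1] / eg$values[2] < 2
  axis <- switch(axis_mode,
    principal = eg$vectors[, 1L],
    endpoint = {
      v <- p[nrow(p), ] - p[1L, ]
      if (sum(v^2) == 0) stop("endpoint axis undefined: zero net displacement")
      v
    })
  axis <- axis / sqrt(sum(axis^2))
  net <- p[nrow(p), ] - p[1L, ]
  if (sum(axis * net) < 0) axis <- -axis
  perp_axis <- c(-axis[2], axis[1])
  if (isotropic)
    warning("segment is nearly isotropic; travel axis poorly defined")
  structure(list(axis = axis, origin = ctr,
                 s = as.numeric(pc %*% axis),
                 perp = as.numeric(pc %*% perp_axis),
                 t = traj$t[rows], frames = rows,
                 isotropic = isotropic, framerate = framerate(traj)),
            class = "projected_walk")
}

#' @export
print.projected_walk <- function(x, ...) {
  cat(sprintf("<projected_walk> %d frames, axis (%.3f, %.3f)%s\n",
              length(x$s), x$axis[1], x$axis[2],
              if (x$isotropic) " [isotropic warning]" else ""))
  cat(sprintf("  on-axis span %.1f nm, track width %.1f nm\n",
              diff(range(x$s)), track_width(x)))
  invisible(x)
}

# centred moving average with shrinking windows at the edges (no NAs)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- w %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract plateaus and step sizes from a projected walk
#'
#' Detects discrete steps in the on-axis coordinate `s(t)`: the signal is
#' smoothed with a centred moving average, a two-window difference detector
#' `d(t) = mean(s[t .. t+W-1]) - mean(s[t-W .. t-1])` is scanned for local
#' extrema with `|d| >= prominence`, and non-maximum suppression enforces a
#' minimum separation of one smoothing window between transitions. Each
#' plateau level is the median of the smoothed signal between consecutive
#' transitions (transition-adjacent frames excluded), and step sizes are
#' differences of consecutive plateau levels. Transitions whose resulting
#' plateau difference falls below `prominence` are merged away.
#'
#' @param walk a `projected_walk` from [project_onto_axis()].
#' @param smoothing_window frames (default 50).
#' @param prominence minimum step amplitude in nm (default 2).
#' @return a `step_analysis`: list with `transition_frames` (indices into
#'   the segment), `plateau_levels` (nm), `step_sizes` (nm, signed),
#'   `histogram` (1-nm bins of absolute step size), `detector` (the d(t)
#'   series), plus the parameters.
#' @export
extract_steps <- function(walk, smoothing_window = 50L, prominence = 2) {
  stopifnot(inherits(walk, "projected_walk"))
  w <- max(1L, as.integer(smoothing_window))
  if (prominence <= 0) stop("prominence must be > 0")
  s <- walk$s
  n <- length(s)
  s_sm <- moving_average(s, w)
  # forward-window minus backward-window mean; defined for t in (w, n-w+1]
  d <- rep(NA_real_, n)
  if (n >= 2L * w) {
    cs <- c(0, cumsum(s))
    tt <- (w + 1L):(n - w + 1L)
    fm <- (cs[tt + w] - cs[tt]) / w          # mean(s[t .. t+w-1])
    bm <- (cs[tt] - cs[tt - w]) / w          # mean(s[t-w .. t-1])
    d[tt] <- fm - bm
  }
  cand <- which(!is.na(d) & abs(d) >= prominence)
  # local-extremum filter on |d|, then greedy non-max suppression
  if (length(cand)) {
    admax <- abs(d)
    is_ext <- vapply(cand, function(t) {
      lo <- max(1L, t - 2L); hi <- min(n, t + 2L)
      admax[t] >= max(admax[lo:hi], na.rm = TRUE)
    }, logical(1))
    cand <- cand[is_ext]
  }
  trans <- integer(0)
  if (length(cand)) {
    for (t in cand[order(-abs(d[cand]))])
      if (!length(trans) || all(abs(trans - t) >= w))
        trans <- c(trans, t)
    trans <- sort(trans)
  }
  level_of <- function(a, b) {
    # plateau between transition frames a (exclusive) and b (exclusive)
    h <- ceiling(w / 2)
    lo <- min(n, a + h); hi <- max(1L, b - h)
    if (lo > hi) stats::median(s_sm[max(1L, min(a + 1L, n)):max(1L, b - 1L)])
    else stats::median(s_sm[lo:hi])
  }
  compute_levels <- function(trans) {
    bounds <- c(0L, trans, n + 1L)
    vapply(seq_len(length(bounds) - 1L),
           function(i) level_of(bounds[i], bounds[i + 1L]), numeric(1))
  }
  levels <- compute_levels(trans)
  # merge transitions with sub-prominence plateau differences
  while (length(trans)) {
    steps <- diff(levels)
    weak <- which(abs(steps) < prominence)
    if (!length(weak)) break
    drop <- weak[which.min(abs(steps[weak]))]
    trans <- trans[-drop]
    levels <- compute_levels(trans)
  }
  steps <- if (length(levels) > 1L) diff(levels) else numeric(0)
  hist <- if (length(steps)) {
    # 1-nm bins centred on integer step sizes
    br <- seq(-0.5, ceiling(max(abs(steps))) + 0.5)
    h <- graphics::hist(abs(steps), breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids)
  } else list(breaks = numeric(0), counts = integer(0), mids = numeric(0))
  structure(list(transition_frames = trans, plateau_levels = levels,
                 step_sizes = steps, histogram = hist,
                 smoothing_window = w, prominence = prominence,
                 detector = d),
            class = "step_analysis")
}

#' @export
print.step_analysis <- function(x, ...) {
  cat(sprintf("<step_analysis> %d plateaus, %d steps (smooth %d, prom %g nm)\n",
              length(x$plateau_levels), length(x$step_sizes),
              x$smoothing_window, x$prominence))
  if (length(x$step_sizes))
    cat(sprintf("  |step| median %.2f nm, range [%.2f, %.2f]\n",
                stats::median(abs(x$step_sizes)),
                min(abs(x$step_sizes)), max(abs(x$step_sizes))))
  invisible(x)
}

#' Track width of a projected walk
#'
#' Width of the transport track, defined as 4 standard deviations of the
#' perpendicular residual (~95% envelope of a Gaussian spread; population
#' standard deviation). The convention is recorded in the result's
#' `convention` attribute.
#'
#' @param walk a `projected_walk` with at least 10 points.
#' @return width in nm.
#' @export
track_width <- function(walk) {
  stopifnot(inherits(walk, "projected_walk"))
  if (length(walk$perp) < 10L) stop("need at least 10 points")
  p <- walk$perp
  structure(4 * sqrt(mean((p - mean(p))^2)), convention = "4*sd(perp)")
}
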