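#' Time-averaged mean square displacement of a trajectory segment
#'
#' For each lag tau (in frames) averages the squared lateral displacement
#' `|r(t_j + tau) - r(t_j)|^2` over all frame pairs with both ends inside
#' the segment `[start, end]` (1-based row indices, inclusive). Only the
#' lateral (x, y) components enter unless `use_z = TRUE`.
#'
#' @param traj an [ispt_trajectory()].
#' @param start,end first and last row of the segment (default: whole
#'   trajectory).
#' @param lags integer lags in frames; lags that do not fit in the segment
#'   are dropped with a warning.
#' @param use_z include the z component (3D MSD).
#' @return an `msd_curve`: data frame with columns `lag_frames`, `lag_s`,
#'   `msd` (nm^2) and `n_pairs`, plus a `framerate` attribute.
#' @examples
#' tr <- ispt_trajectory(x = c(0, 1, 3, 2, 4), y = rep(0, 5), framerate = 1)
#' time_averaged_msd(tr, lags = 1:2)  # 2.5 and 11/3 nm^2
#' @export
time_averaged_msd <- function(traj, start = 1L, end = n_points(traj),
                              lags = NULL, use_z = FALSE) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  n <- n_points(traj)
  if (!(start >= 1L && start < end && end <= n))
    stop("need 1 <= start < end <= n_frames")
  seg_len <- end - start + 1L
  if (is.null(lags)) lags <- default_fit_lags(seg_len)
  if (length(lags) == 0L) stop("empty lag list")
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be >= 1 frame")
  drop <- lags >= seg_len
  if (any(drop)) {
    warning(sum(drop), " lag(s) >= segment length dropped")
    lags <- lags[!drop]
    if (length(lags) == 0L) stop("no usable lags in segment")
  }
  pos <- traj_positions(traj, use_z = use_z)
  pos <- pos[start:end, , drop = FALSE]
  msd <- numeric(length(lags)); np <- integer(length(lags))
  for (k in seq_along(lags)) {
    tau <- lags[k]
    d <- pos[(tau + 1L):seg_len, , drop = FALSE] -
         pos[1L:(seg_len - tau), , drop = FALSE]
    msd[k] <- mean(rowSums(d * d))
    np[k] <- seg_len - tau
  }
  new_msd_curve(lags, msd, np, framerate(traj))
}

new_msd_curve <- function(lag_frames, msd, n_pairs, framerate) {
  structure(data.frame(lag_frames = lag_frames,
                       lag_s = lag_frames / framerate,
                       msd = msd, n_pairs = n_pairs),
            framerate = framerate,
            class = c("msd_curve", "data.frame"))
}

#' Construct an MSD curve from explicit values
#'
#' Mostly useful for testing fit routines against closed-form curves.
#'
#' @param lag_s lags in seconds.
#' @param msd MSD values in nm^2.
#' @param n_pairs pair counts per lag (default 1).
#' @param framerate frames/second used to annotate frame lags.
#' @return an `msd_curve`.
#' @export
msd_curve <- function(lag_s, msd, n_pairs = 1L, framerate = 1) {
  new_msd_curve(round(lag_s * framerate), msd,
                rep_len(n_pairs, length(lag_s)), framerate)
}

# every frame-lag from 1 to len/4, log-thinned to at most n_max lags
default_fit_lags <- function(seg_len, n_max = 20L) {
  lmax <- max(1L, floor(seg_len / 4))
  lags <- unique(round(exp(seq(log(1), log(lmax), length.out = n_max))))
  lags[lags >= 1L & lags < seg_len]
}

#' Fit the temporal exponent of an MSD curve
#'
#' Fits the anomalous-diffusion power law `MSD(tau) = Gamma * tau^alpha`
#' (tau in seconds) with handling of the static localization error:
#'
#' * `error_mode = "subtract"` (default): the known offset `4 * sigma_xy^2`
#'   (2D, per-axis precision `sigma_xy`) is subtracted from each MSD value,
#'   and lags whose *measured* MSD is below `exclusion_factor` times the
#'   offset are excluded — displacements comparable to the precision carry
#'   no exponent information.
#' * `error_mode = "fit"`: the offset is co-estimated as a free parameter of
#'   `Gamma * tau^alpha + offset` by nonlinear least squares.
#' * `error_mode = "none"`: no correction.
#'
#' The power law is fitted as weighted least squares of `log(msd)` on
#' `log(tau)` with weights proportional to the pair count per lag.
#'
#' @param curve an `msd_curve`.
#' @param sigma_xy per-axis lateral localization precision, nm.
#' @param fit_range optional numeric length-2 lag range in seconds; lags
#'   outside are ignored.
#' @param error_mode see above.
#' @param exclusion_factor multiple of the offset `4 sigma_xy^2` below which
#'   a measured lag is excluded (default 2).
#' @return a `power_law_fit` list: `alpha`, `gamma` (nm^2/s^alpha),
#'   `alpha_se`, `n_lags_used`, `fit_lag_range` (s), exclusion counts,
#'   `offset` (nm^2) and `error_mode`.
#' @examples
#' cv <- msd_curve(lag_s = 1:10, msd = 2 * (1:10)^0.5)
#' fit_temporal_exponent(cv)$alpha  # 0.5
#' @export
fit_temporal_exponent <- function(curve, sigma_xy = 0, fit_range = NULL,
                                  error_mode = c("subtract", "fit", "none"),
                                  exclusion_factor = 2) {
  error_mode <- match.arg(error_mode)
  stopifnot(inherits(curve, "msd_curve"))
  cv <- as.data.frame(curve)
  if (!is.null(fit_range))
    cv <- cv[cv$lag_s >= fit_range[1] & cv$lag_s <= fit_range[2], ]
  offset <- if (error_mode == "subtract") 4 * sigma_xy^2 else 0
  n_low <- 0L
  if (error_mode == "subtract" && sigma_xy > 0) {
    low <- cv$msd < exclusion_factor * offset
    n_low <- sum(low)
    cv <- cv[!low, , drop = FALSE]
  }
  y <- cv$msd - offset
  pos_ok <- y > 0
  n_nonpos <- sum(!pos_ok)
  cv <- cv[pos_ok, , drop = FALSE]; y <- y[pos_ok]
  if (nrow(cv) < 3L)
    stop(sprintf(paste0("power-law fit failed: %d usable lag(s) ",
                        "(%d below precision floor, %d non-positive ",
                        "after offset subtraction)"),
                 nrow(cv), n_low, n_nonpos))
  w <- cv$n_pairs / sum(cv$n_pairs)
  lx <- log(cv$lag_s); ly <- log(y)
  fit <- wls_line(lx, ly, w)
  alpha <- fit$slope; gamma <- exp(fit$intercept)
  alpha_se <- fit$slope_se
  if (error_mode == "fit") {
    # start from the offset-subtracted log-log fit: take 90% of the
    # smallest MSD value as the provisional offset
    b0 <- 0.9 * min(cv$msd)
    y0 <- cv$msd - b0
    f0 <- wls_line(log(cv$lag_s), log(pmax(y0, 1e-12)), w)
    st <- list(G = exp(f0$intercept), a = f0$slope, b = b0)
    nf <- try(stats::nls(msd ~ G * lag_s^a + b, data = cv, start = st,
                         weights = cv$n_pairs, algorithm = "port",
                         lower = c(G = 1e-12, a = -2, b = 0),
                         control = stats::nls.control(maxiter = 200,
                                                      warnOnly = TRUE)),
              silent = TRUE)
    if (!inherits(nf, "try-error")) {
      cf <- stats::coef(nf)
      alpha <- unname(cf["a"]); gamma <- unname(cf["G"])
      offset <- unname(cf["b"])
      se <- try(summary(nf)$coefficients["a", "Std. Error"], silent = TRUE)
      if (!inherits(se, "try-error")) alpha_se <- unname(se)
    }
  }
  structure(list(alpha = alpha, gamma = gamma, alpha_se = alpha_se,
                 n_lags_used = nrow(cv),
                 fit_lag_range = range(cv$lag_s),
                 n_excluded_low = n_low, n_excluded_nonpos = n_nonpos,
                 offset = offset, error_mode = error_mode),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> alpha = %.4f +/- %.4f, Gamma = %.4g nm^2/s^alpha\n",
    x$alpha, x$alpha_se, x$gamma))
  cat(sprintf("  %d lags in [%.3g, %.3g] s; %d excluded (low), %d (nonpos)\n",
              x$n_lags_used, x$fit_lag_range[1], x$fit_lag_range[2],
              x$n_excluded_low, x$n_excluded_nonpos))
  invisible(x)
}

# weighted least-squares line fit; slope stderr from weighted residuals
wls_line <- function(x, y, w) {
  w <- w / sum(w)
  xb <- sum(w * x); yb <- sum(w * y)
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("degenerate lag axis in fit")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  nn <- length(x)
  s2 <- sum(w * res^2) * nn / max(1, nn - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx / nn))
}

#' Rolling-window temporal exponent
#'
#' Slides a window of `window` frames across the trajectory in steps of
#' `stride` frames and fits the MSD power-law exponent inside each window
#' (see [time_averaged_msd()] and [fit_temporal_exponent()]). Each exponent
#' `alpha_i` is assigned to the window's centre time, which localizes
#' changes in mobility along the trajectory. Windows whose fit fails carry
#' `NA`, never a fabricated exponent.
#'
#' @param traj an [ispt_trajectory()].
#' @param window window length in frames (<= n_frames).
#' @param stride window step in frames; default `window / 10`
#'   (overlapping windows).
#' @param lags fit lags in frames; default log-spaced `1 .. window/4`,
#'   at most 20.
#' @param sigma_xy lateral localization precision, nm (see
#'   [fit_temporal_exponent()]).
#' @param error_mode passed to [fit_temporal_exponent()].
#' @return a `window_series` data frame: `window`, `start`, `end` (1-based
#'   rows), `t_center` (s), `alpha`, `alpha_se`, `gamma`, `n_lags`; attributes
#'   `T_w` (window duration, s), `window`, `stride`, `framerate`.
#' @export
rolling_exponent <- function(traj, window, stride = max(1L, window %/% 10L),
                             lags = NULL, sigma_xy = 0,
                             error_mode = "subtract") {
  stopifnot(inherits(traj, "ispt_trajectory"))
  n <- n_points(traj)
  if (window > n) stop("window exceeds trajectory length")
  if (stride < 1L) stop("stride must be >= 1")
  if (is.null(lags)) lags <- default_fit_lags(window)
  lags <- sort(unique(as.integer(lags)))
  lags <- lags[lags >= 1L & lags < window]
  fr <- framerate(traj)
  starts <- seq(1L, n - window + 1L, by = stride)
  pos <- traj_positions(traj, use_z = FALSE)
  # per-lag cumulative sums of squared displacements: O(n * n_lags) total
  cs <- lapply(lags, function(tau) {
    d <- pos[(tau + 1L):n, , drop = FALSE] - pos[1L:(n - tau), , drop = FALSE]
    c(0, cumsum(rowSums(d * d)))
  })
  res <- data.frame(window = seq_along(starts), start = starts,
                    end = starts + window - 1L,
                    t_center = traj$t[starts] + (window - 1L) / (2 * fr),
                    alpha = NA_real_, alpha_se = NA_real_,
                    gamma = NA_real_, n_lags = NA_integer_)
  for (i in seq_along(starts)) {
    a <- starts[i]
    msd <- vapply(seq_along(lags), function(k) {
      tau <- lags[k]
      (cs[[k]][a + window - tau] - cs[[k]][a]) / (window - tau)
    }, numeric(1))
    curve <- new_msd_curve(lags, msd, window - lags, fr)
    ft <- try(fit_temporal_exponent(curve, sigma_xy = sigma_xy,
                                    error_mode = error_mode), silent = TRUE)
    if (!inherits(ft, "try-error")) {
      res$alpha[i] <- ft$alpha; res$alpha_se[i] <- ft$alpha_se
      res$gamma[i] <- ft$gamma; res$n_lags[i] <- ft$n_lags_used
    }
  }
  structure(res, T_w = window / fr, window = window, stride = stride,
            framerate = fr, class = c("window_series", "data.frame"))
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("<window_series> %d windows of %d frames (T_w = %g s), stride %d\n",
              nrow(x), attr(x, "window"), attr(x, "T_w"), attr(x, "stride")))
  if ("alpha" %in% names(x) && any(is.finite(x$alpha)))
    cat(sprintf("  mean alpha = %.3f\n", mean(x$alpha, na.rm = TRUE)))
  if ("C" %in% names(x) && any(is.finite(x$C)))
    cat(sprintf("  mean C     = %.3f\n", mean(x$C, na.rm = TRUE)))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Whole-trajectory MSD and power-law fit
#'
#' Computes a single time-averaged MSD over the full trajectory with
#' log-spaced lags up to `max_lag_fraction` of the duration, and fits the
#' temporal exponent. This is the conventional "macroscopic" MSD analysis,
#' complementary to [rolling_exponent()].
#'
#' @param traj an [ispt_trajectory()].
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length, in (0, 0.25].
#' @param n_lags number of log-spaced lags.
#' @param lags optional explicit lags in frames (overrides the above).
#' @param sigma_xy,error_mode see [fit_temporal_exponent()].
#' @return list with elements `curve` (an `msd_curve`) and `fit`
#'   (a `power_law_fit`).
#' @export
whole_trajectory_msd <- function(traj, max_lag_fraction = 0.25, n_lags = 30L,
                                 lags = NULL, sigma_xy = 0,
                                 error_mode = "subtract") {
  n <- n_points(traj)
  if (is.null(lags)) {
    if (max_lag_fraction <= 0 || max_lag_fraction > 0.25)
      stop("max_lag_fraction must be in (0, 0.25]")
    lmax <- max(2L, floor(max_lag_fraction * n))
    lags <- unique(round(exp(seq(log(1), log(lmax), length.out = n_lags))))
  }
  curve <- time_averaged_msd(traj, lags = lags)
  fit <- fit_temporal_exponent(curve, sigma_xy = sigma_xy,
                               error_mode = error_mode)
  list(curve = curve, fit = fit)
}
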