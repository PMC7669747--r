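#' Read a trajectory from delimited text
#'
#' The canonical trajectory CSV dialect: a header row with at least
#' `frame`, `x_nm`, `y_nm`; optional `t_s`, `z_nm`, `sigma_xy_nm`,
#' `sigma_z_nm`; optional comment lines starting `#`, in particular
#' `# framerate_hz=<value>`. When no framerate header is present the rate
#' is inferred from the `t_s` spacing, which must be uniform to 1e-6
#' relative. Rows are sorted by frame (with a warning if they arrived
#' unsorted); duplicate frame indices are an error.
#'
#' @param path file path.
#' @return an [ispt_trajectory()].
#' @export
read_trajectory <- function(path) {
  head_lines <- readLines(path, n = 50L)
  fr <- NA_real_
  m <- regmatches(head_lines,
                  regexpr("^#\\s*framerate_hz\\s*=\\s*([0-9.eE+-]+)",
                          head_lines))
  if (length(m))
    fr <- as.numeric(sub("^#\\s*framerate_hz\\s*=\\s*", "", m[1]))
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("frame", "x_nm", "y_nm"))
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path)
  if (anyDuplicated(df$frame))
    stop("duplicate frame index in ", path)
  if (is.unsorted(df$frame)) {
    warning("rows not sorted by frame; sorting")
    df <- df[order(df$frame), ]
  }
  if (is.na(fr)) {
    if (!"t_s" %in% names(df))
      stop("no '# framerate_hz=' header and no t_s column: ",
           "framerate unknown")
    dt <- diff(df$t_s) / diff(df$frame)
    if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
      stop("non-uniform time spacing: analyses assume uniform frames")
    fr <- 1 / mean(dt)
  }
  ispt_trajectory(x = df$x_nm, y = df$y_nm,
                  z = if ("z_nm" %in% names(df)) df$z_nm,
                  framerate = fr, frame = df$frame,
                  t = if ("t_s" %in% names(df)) df$t_s,
                  sigma_xy = if ("sigma_xy_nm" %in% names(df)) df$sigma_xy_nm,
                  sigma_z = if ("sigma_z_nm" %in% names(df)) df$sigma_z_nm,
                  metadata = list(source = path))
}

#' Write a trajectory as delimited text
#'
#' Inverse of [read_trajectory()]; the framerate is stored in a
#' `# framerate_hz=` comment header.
#'
#' @param traj an [ispt_trajectory()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  df <- data.frame(frame = traj$frame, t_s = traj$t,
                   x_nm = traj$x, y_nm = traj$y)
  if (is_3d(traj)) df$z_nm <- traj$z
  if ("sigma_xy" %in% names(traj)) df$sigma_xy_nm <- traj$sigma_xy
  if ("sigma_z" %in% names(traj)) df$sigma_z_nm <- traj$sigma_z
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# framerate_hz=%.10g", framerate(traj)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Validated parameter set for [run_pipeline()]. Defaults follow the
#' package-wide conventions: tau = 5 frames for directional correlation,
#' 4 nm occupancy bins, 1 ms residence threshold for patches.
#'
#' @param window,stride rolling-window length and step, frames.
#' @param tau directional-correlation step separation, frames.
#' @param sigma_xy lateral localization precision, nm.
#' @param bin_size ATOM bin side, nm.
#' @param residence_threshold patch threshold, s.
#' @param smoothing_window,prominence step-detection parameters
#'   (frames, nm).
#' @param seed integer seed for any stochastic stage.
#' @param output_directory where [run_pipeline()] writes its tables.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(window = 1000L, stride = 100L, tau = 5L,
                            sigma_xy = 0, bin_size = 4,
                            residence_threshold = 1e-3,
                            smoothing_window = 50L, prominence = 2,
                            seed = 1L, output_directory = ".") {
  stopifnot(window >= 2, stride >= 1, tau >= 1, sigma_xy >= 0,
            bin_size > 0, residence_threshold > 0,
            smoothing_window >= 1, prominence > 0)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 tau = as.integer(tau), sigma_xy = sigma_xy,
                 bin_size = bin_size,
                 residence_threshold = residence_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 prominence = prominence, seed = as.integer(seed),
                 output_directory = output_directory),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Reads the `analyze:` section (or the whole document if no section) of a
#' flat key-value YAML file. Unknown keys are rejected with an error
#' listing them.
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$analyze)) y <- y$analyze
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, y)
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes, on one trajectory: the rolling temporal exponent and rolling
#' directional correlation on a shared window grid, the whole-trajectory
#' MSD and fit, the occupancy (ATOM) map and patch detection, and — for 3D
#' input — the bowl fit and angular series. Every stage is attempted even
#' if an earlier one fails; failures are recorded in the machine-readable
#' run manifest (`manifest.json`) along with the package version, the
#' configuration, the seed and an MD5 checksum of the input file.
#'
#' Output tables (UTF-8 CSV, written to `config$output_directory`):
#' `windows.csv` (shared window grid: alpha, alpha_se, gamma, C, C_se),
#' `msd.csv`, `msd_fit.csv`, `atom.csv` (count matrix with a geometry
#' header), `patches.csv`, and for 3D input `bowl.csv` and `phi.csv`.
#'
#' @param traj an [ispt_trajectory()] or a path readable by
#'   [read_trajectory()].
#' @param config an [analysis_config()].
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(traj, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  input_path <- NULL
  if (is.character(traj)) {
    input_path <- traj
    traj <- read_trajectory(traj)
  }
  validate_trajectory(traj)
  dir.create(config$output_directory, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$output_directory, f)
  set.seed(config$seed)
  manifest <- list(
    package = "isptrack",
    version = as.character(utils::packageVersion("isptrack")),
    config = unclass(config),
    seed = config$seed,
    input = if (is.null(input_path)) "in-memory trajectory" else input_path,
    input_md5 = if (is.null(input_path)) NA else
      unname(tools::md5sum(input_path)),
    n_frames = n_points(traj),
    framerate = framerate(traj),
    stages = list())
  results <- list()
  stage <- function(name, expr) {
    r <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (r$ok) "ok" else
      paste("failed:", r$error)
    if (r$ok) results[[name]] <<- r$value
    r$ok
  }
  sig <- if (config$sigma_xy > 0) config$sigma_xy else traj_sigma_xy(traj)

  if (stage("rolling_alpha",
            rolling_exponent(traj, window = config$window,
                             stride = config$stride, sigma_xy = sig))) NULL
  if (stage("rolling_dircorr",
            rolling_directional_correlation(traj, tau = config$tau,
                                            window = config$window,
                                            stride = config$stride,
                                            min_step = sig * sqrt(8)))) NULL
  if (!is.null(results$rolling_alpha) && !is.null(results$rolling_dircorr)) {
    win <- as.data.frame(results$rolling_alpha)
    dc <- as.data.frame(results$rolling_dircorr)
    win$C <- dc$C; win$C_se <- dc$C_se
    utils::write.csv(win, outp("windows.csv"), row.names = FALSE)
  }
  if (stage("whole_msd", whole_trajectory_msd(traj, sigma_xy = sig))) {
    utils::write.csv(as.data.frame(results$whole_msd$curve),
                     outp("msd.csv"), row.names = FALSE)
    ft <- results$whole_msd$fit
    utils::write.csv(data.frame(alpha = ft$alpha, alpha_se = ft$alpha_se,
                                gamma = ft$gamma,
                                n_lags = ft$n_lags_used),
                     outp("msd_fit.csv"), row.names = FALSE)
  }
  if (stage("atom", compute_atom(traj, bin_size = config$bin_size))) {
    atom <- results$atom
    con <- file(outp("atom.csv"), "w")
    writeLines(sprintf("# origin_nm=%g,%g bin_nm=%g exposure_s=%g",
                       atom$origin[1], atom$origin[2], atom$bin_size,
                       atom$exposure_time), con)
    utils::write.table(atom$counts, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    close(con)
    if (stage("patches",
              detect_patches(atom,
                             residence_threshold = config$residence_threshold)))
      utils::write.csv(as.data.frame(results$patches), outp("patches.csv"),
                       row.names = FALSE)
  }
  if (is_3d(traj)) {
    if (stage("bowl", fit_bowl(traj))) {
      bf <- results$bowl
      utils::write.csv(data.frame(cx = bf$center[1], cy = bf$center[2],
                                  cz = bf$center[3], radius = bf$radius,
                                  sphere_diameter = bf$sphere_diameter,
                                  opening_diameter = bf$opening_diameter,
                                  rms_residual = bf$rms_residual),
                       outp("bowl.csv"), row.names = FALSE)
      if (stage("phi", angular_series(traj, results$bowl)))
        utils::write.csv(as.data.frame(results$phi), outp("phi.csv"),
                         row.names = FALSE)
    }
  } else {
    manifest$stages$bowl <- "skipped: no z"
  }
  manifest$n_failed <- sum(grepl("^failed", unlist(manifest$stages)))
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
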