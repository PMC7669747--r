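#' Accumulated total occupancy map (ATOM)
#'
#' Bins the lateral trajectory into square bins of side `bin_size` nm and
#' counts the trajectory points per bin. Because frames are uniformly
#' spaced, counts convert directly to residence time:
#' `residence(bin) = counts(bin) * exposure_time`, with
#' `exposure_time = 1 / framerate`. Bins are half-open,
#' `[origin + k b, origin + (k+1) b)` per axis, so a point exactly on an
#' edge belongs to the upper bin.
#'
#' @param traj an [ispt_trajectory()].
#' @param bin_size bin side b in nm (default 4).
#' @param origin length-2 lower-left corner in nm; default: the data's
#'   minimum, snapped down to a multiple of `bin_size`.
#' @return an `atom_map`: list with `counts` (integer matrix, x along rows),
#'   `origin`, `bin_size`, `exposure_time`, `framerate`, `occupied_bins`.
#' @export
compute_atom <- function(traj, bin_size = 4, origin = NULL) {
  stopifnot(inherits(traj, "ispt_trajectory"))
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (n_points(traj) == 0L) stop("empty trajectory")
  x <- traj$x; y <- traj$y
  if (is.null(origin))
    origin <- floor(c(min(x), min(y)) / bin_size) * bin_size
  ix <- floor((x - origin[1]) / bin_size)
  iy <- floor((y - origin[2]) / bin_size)
  if (any(ix < 0) || any(iy < 0))
    stop("origin must not exceed the data minimum")
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  counts <- matrix(0L, nx, ny)
  tab <- tabulate(ix + nx * iy + 1L, nbins = nx * ny)
  counts[] <- tab
  structure(list(counts = counts, origin = origin, bin_size = bin_size,
                 exposure_time = 1 / framerate(traj),
                 framerate = framerate(traj),
                 occupied_bins = sum(counts > 0L)),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map> %d x %d bins of %g nm, %d occupied, %d points\n",
              nrow(x$counts), ncol(x$counts), x$bin_size,
              x$occupied_bins, sum(x$counts)))
  cat(sprintf("  origin (%g, %g) nm, exposure %g s/frame\n",
              x$origin[1], x$origin[2], x$exposure_time))
  invisible(x)
}

#' Residence-time matrix of an ATOM map
#'
#' @param atom an `atom_map`.
#' @return matrix of per-bin residence times in seconds.
#' @export
residence_time <- function(atom) {
  stopifnot(inherits(atom, "atom_map"))
  atom$counts * atom$exposure_time
}

# 8-connected labelling of occupied cells by union-find
label8 <- function(ix, iy) {
  n <- length(ix)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(ix, iy)
  for (off in list(c(1L, -1L), c(1L, 0L), c(1L, 1L), c(0L, 1L))) {
    j <- match(paste(ix + off[1], iy + off[2]), key)
    for (i in which(!is.na(j))) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Detect extended-residency patches in an ATOM map
#'
#' Thresholds bins at `residence >= residence_threshold` (default 1 ms, the
#' "sticky" criterion: orders of magnitude longer residency than the
#' surrounding membrane), labels 8-connected components, and discards
#' components smaller than `min_bins`. Each surviving patch is summarized
#' by its area `n_bins * b^2` and equivalent circular diameter
#' `d_eq = 2 sqrt(area / pi)`.
#'
#' @param atom an `atom_map`.
#' @param residence_threshold seconds (> 0), default 1e-3.
#' @param min_bins smallest component kept, default 3.
#' @return an `atom_patches` data frame sorted by total residence,
#'   descending: `id`, `n_bins`, `area_nm2`, `d_eq_nm`, `residence_s`,
#'   `cx_nm`, `cy_nm`; the member bin indices are kept in the `bins`
#'   attribute (list of two-column matrices).
#' @export
detect_patches <- function(atom, residence_threshold = 1e-3, min_bins = 3L) {
  stopifnot(inherits(atom, "atom_map"))
  if (residence_threshold <= 0) stop("residence_threshold must be > 0")
  rt <- residence_time(atom)
  sel <- which(rt >= residence_threshold, arr.ind = TRUE)
  empty <- structure(data.frame(id = integer(), n_bins = integer(),
                                area_nm2 = numeric(), d_eq_nm = numeric(),
                                residence_s = numeric(), cx_nm = numeric(),
                                cy_nm = numeric()),
                     bins = list(), class = c("atom_patches", "data.frame"))
  if (nrow(sel) == 0L) return(empty)
  lab <- label8(sel[, 1L], sel[, 2L])
  b <- atom$bin_size
  keep <- which(tabulate(lab) >= min_bins)
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(g) {
    cells <- sel[lab == g, , drop = FALSE]
    nb <- nrow(cells)
    area <- nb * b^2
    centers_x <- atom$origin[1] + (cells[, 1L] - 0.5) * b
    centers_y <- atom$origin[2] + (cells[, 2L] - 0.5) * b
    data.frame(n_bins = nb, area_nm2 = area,
               d_eq_nm = 2 * sqrt(area / pi),
               residence_s = sum(rt[cells]),
               cx_nm = mean(centers_x), cy_nm = mean(centers_y))
  })
  out <- do.call(rbind, rows)
  ord <- order(out$residence_s, decreasing = TRUE)
  out <- out[ord, , drop = FALSE]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out,
            bins = lapply(keep[ord],
                          function(g) sel[lab == g, , drop = FALSE]),
            class = c("atom_patches", "data.frame"))
}
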