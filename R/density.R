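#' Arcsinh transform of ADT counts
#'
#' `asinh(x / cofactor)` — near-linear at zero, logarithmic for large counts.
#' Strictly increasing; maps 0 to 0.
#'
#' @param x non-negative numeric counts (vector or matrix). `NA` passes through.
#' @param cofactor positive scaling cofactor (default 5).
#' @return transformed values, same shape as `x`.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a positive scalar")
  if (any(!is.na(x) & !is.finite(x))) stop("non-finite input values")
  asinh(x / cofactor)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Gaussian kernel density estimate on a fixed grid
#'
#' The density is renormalized to integrate to 1 over the grid (kernel mass
#' leaking left of the origin for near-zero counts would otherwise deflate the
#' integral).
#'
#' @param values numeric vector, at least 2 values.
#' @param bandwidth Gaussian kernel standard deviation (> 0).
#' @param grid strictly increasing, equally spaced evaluation grid.
#' @return An object of class `density_curve`: list with `grid`, `density`,
#'   `bandwidth_used`, `n_cells`.
#' @export
estimate_density <- function(values, bandwidth, grid) {
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      from = grid[1], to = grid[length(grid)],
                      n = length(grid))
  dens <- d$y
  total <- trapz(grid, dens)
  if (total <= 0) stop("degenerate density")
  structure(list(grid = grid, density = dens / total,
                 bandwidth_used = bandwidth, n_cells = length(values)),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat("density_curve:", length(x$grid), "grid points on [",
      format(x$grid[1]), ",", format(x$grid[length(x$grid)]), "], bw =",
      format(x$bandwidth_used), ", n =", x$n_cells, "\n")
  invisible(x)
}

#' Shared density grid for one marker across batches
#'
#' `grid_size` equally spaced points from 0 (arcsinh of a zero count) to the
#' maximum observed arcsinh value padded by 3 widest-ladder bandwidths, so all
#' batches of a marker share `[T_start, T_end]`.
#'
#' @param values_list list of per-batch arcsinh value vectors.
#' @param config an [adt_config()].
#' @return numeric grid vector.
#' @export
shared_grid <- function(values_list, config = adt_config()) {
  vmax <- max(unlist(lapply(values_list, max, na.rm = TRUE)))
  seq(0, vmax + 3 * config$bandwidth_ladder[1], length.out = config$grid_size)
}

#' Bandwidth ladder search
#'
#' Starting from the widest rung, finds the first bandwidth whose density
#' resolves at least 2 peaks (or `peak_count_prior` peaks when given); if no
#' rung succeeds, the narrowest rung is used. For markers with a multimodal
#' prior (`peak_count_prior >= 2`, e.g. 3 for trimodal CD4-like markers) an
#' even narrower bandwidth is then applied: the narrowest rung resolving
#' exactly the expected number of peaks, which minimizes the smoothing bias of
#' the peak modes while rejecting rungs that fragment into noise peaks.
#'
#' @param values numeric vector of arcsinh values.
#' @param ladder strictly decreasing bandwidths.
#' @param grid shared evaluation grid.
#' @param peak_count_prior optional expected number of peaks.
#' @param min_height_frac passed to [detect_peaks()].
#' @param min_prominence_frac passed to [filter_low_prominence()]; rungs are
#'   judged on prominent peaks only.
#' @return list with `bandwidth`, `curve` (the [estimate_density()] result at
#'   the selected rung) and `n_peaks` (raw peak count there).
#' @export
select_bandwidth <- function(values, ladder, grid, peak_count_prior = NULL,
                             min_height_frac = 0.01,
                             min_prominence_frac = 0.05) {
  if (length(ladder) == 0) stop("bandwidth ladder must be non-empty")
  if (!is.null(peak_count_prior) && anyNA(peak_count_prior))
    peak_count_prior <- NULL
  want <- if (is.null(peak_count_prior)) 2L else as.integer(peak_count_prior)
  curves <- vector("list", length(ladder))
  n_peaks <- integer(length(ladder))
  for (i in seq_along(ladder)) {
    curves[[i]] <- estimate_density(values, ladder[i], grid)
    pk <- detect_peaks(curves[[i]], min_height_frac)
    n_peaks[i] <- nrow(filter_low_prominence(curves[[i]], pk,
                                             min_prominence_frac))
  }
  base <- which(n_peaks >= want)
  base <- if (length(base) > 0) base[1] else length(ladder)
  idx <- base
  if (!is.null(peak_count_prior) && want >= 2) {
    exact <- which(seq_along(ladder) >= base & n_peaks == want)
    if (length(exact) > 0) idx <- max(exact)
  }
  list(bandwidth = ladder[idx], curve = curves[[idx]], n_peaks = n_peaks[idx])
}
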