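#' Run configuration
#'
#' All tunable parameters of the normalization pipeline. Defaults follow
#' common cytometry practice where the method itself leaves them open.
#'
#' @param arcsinh_cofactor positive cofactor c of the `asinh(x / c)` transform.
#'   Default 5, the usual choice for ADT counts.
#' @param grid_size number of equally spaced density grid points. Default 512.
#' @param bandwidth_ladder strictly decreasing Gaussian KDE bandwidths
#'   (arcsinh units) tried from widest to narrowest. Default `c(1, 0.5, 0.25, 0.1)`.
#' @param neg_candidate_thres arcsinh-scale threshold below which peaks are
#'   treated as background candidates and merged. Default `asinh(10 / cofactor)`
#'   (counts up to ~10 are candidate background).
#' @param mad_multiplier MAD multiplier for outlier peak/valley flagging.
#'   Default 3.
#' @param lambda_penalty curvature penalty weight of the warp objective;
#'   recorded on warp objects. The fitted warp is the minimal-curvature
#'   monotone interpolant (the large-penalty limit), see the methods vignette.
#' @param min_height_frac peaks below this fraction of the maximal density are
#'   not "high-density" and are ignored. Default 0.01.
#' @param min_prominence_frac peaks must rise above their saddle by this
#'   fraction of the maximal density (see [filter_low_prominence()]).
#'   Default 0.05.
#' @param slope_valley_frac for single-peak curves, the valley is the first
#'   grid point right of the steepest descent where `|slope|` falls below this
#'   fraction of that steepest descent. Default 0.3.
#' @param spurious_height_frac a leftmost near-zero peak is dropped as a
#'   spurious empty-droplet peak when its height is below this fraction of the
#'   next peak's height. Default 0.5.
#' @param k_neighbors number of smallest-EMD neighbor batches averaged when
#'   imputing an outlier valley. Default 2.
#' @param target_landmark_location optional named list (by marker) of strictly
#'   increasing target landmark positions overriding the cross-batch means.
#' @param positive_peak_only optional data frame with columns `batch`,
#'   `marker`: combinations whose single detected peak is a positive (not
#'   background) population.
#' @param peak_count_prior optional named integer vector (by marker) of
#'   expected peak counts steering bandwidth selection (e.g. `c(CD4 = 3)`).
#' @param quality_threshold stain-quality score below which a marker is
#'   flagged in [quality_report()]. Default 5.
#' @return An object of class `adt_config` (a validated list).
#' @export
adt_config <- function(arcsinh_cofactor = 5,
                       grid_size = 512,
                       bandwidth_ladder = c(1, 0.5, 0.25, 0.1),
                       neg_candidate_thres = asinh(10 / arcsinh_cofactor),
                       mad_multiplier = 3,
                       lambda_penalty = 1e-6,
                       min_height_frac = 0.01,
                       min_prominence_frac = 0.05,
                       slope_valley_frac = 0.3,
                       spurious_height_frac = 0.5,
                       k_neighbors = 2,
                       target_landmark_location = NULL,
                       positive_peak_only = NULL,
                       peak_count_prior = NULL,
                       quality_threshold = 5) {
  cfg <- list(arcsinh_cofactor = arcsinh_cofactor, grid_size = grid_size,
              bandwidth_ladder = bandwidth_ladder,
              neg_candidate_thres = neg_candidate_thres,
              mad_multiplier = mad_multiplier, lambda_penalty = lambda_penalty,
              min_height_frac = min_height_frac,
              min_prominence_frac = min_prominence_frac,
              slope_valley_frac = slope_valley_frac,
              spurious_height_frac = spurious_height_frac,
              k_neighbors = k_neighbors,
              target_landmark_location = target_landmark_location,
              positive_peak_only = positive_peak_only,
              peak_count_prior = peak_count_prior,
              quality_threshold = quality_threshold)
  validate_config(cfg)
  structure(cfg, class = "adt_config")
}

validate_config <- function(cfg) {
  num <- c("arcsinh_cofactor", "grid_size", "bandwidth_ladder",
           "neg_candidate_thres", "mad_multiplier", "lambda_penalty",
           "min_height_frac", "min_prominence_frac", "slope_valley_frac",
           "spurious_height_frac", "k_neighbors", "quality_threshold")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || anyNA(cfg[[f]]) || any(!is.finite(cfg[[f]])))
      stop("config field '", f, "' must be finite numeric")
  if (cfg$arcsinh_cofactor <= 0) stop("arcsinh_cofactor must be positive")
  if (cfg$grid_size < 16) stop("grid_size too small")
  if (any(diff(cfg$bandwidth_ladder) >= 0))
    stop("bandwidth_ladder must be strictly decreasing")
  if (any(cfg$bandwidth_ladder <= 0)) stop("bandwidths must be positive")
  if (cfg$neg_candidate_thres < 0) stop("neg_candidate_thres must be >= 0")
  if (cfg$mad_multiplier <= 0) stop("mad_multiplier must be positive")
  if (cfg$lambda_penalty < 0) stop("lambda_penalty must be >= 0")
  if (cfg$min_height_frac <= 0 || cfg$min_height_frac >= 1)
    stop("min_height_frac must be in (0, 1)")
  if (cfg$k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (!is.null(cfg$target_landmark_location)) {
    for (m in names(cfg$target_landmark_location)) {
      v <- cfg$target_landmark_location[[m]]
      if (any(diff(v) <= 0))
        stop("target_landmark_location for '", m, "' must be strictly increasing")
    }
  }
  if (!is.null(cfg$positive_peak_only) &&
      !all(c("batch", "marker") %in% names(cfg$positive_peak_only)))
    stop("positive_peak_only needs 'batch' and 'marker' columns")
  invisible(cfg)
}

#' Read / write a run configuration as JSON
#'
#' The file mirrors [adt_config()] field names exactly; unknown keys are an
#' error (catches typos in per-marker overrides).
#'
#' @param path JSON file path.
#' @return [read_adt_config()] returns an `adt_config`.
#' @export
read_adt_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(adt_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", toString(unknown))
  if (!is.null(raw$target_landmark_location))
    raw$target_landmark_location <- as.list(raw$target_landmark_location)
  if (!is.null(raw$positive_peak_only))
    raw$positive_peak_only <- as.data.frame(raw$positive_peak_only)
  if (!is.null(raw$peak_count_prior))
    raw$peak_count_prior <- unlist(raw$peak_count_prior)
  do.call(adt_config, raw)
}

#' @rdname read_adt_config
#' @param config an [adt_config()].
#' @export
write_adt_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
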