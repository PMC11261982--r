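#' Per-peak summaries feeding the stain-quality formulas
#'
#' Peak intervals are delimited by the flanking valleys (or by the grid
#' endpoints). For each peak: the mode location, the density height at the
#' mode, the population standard deviation of the cells whose value falls in
#' the interval, and the trapezoid area under the density curve over the
#' interval. Also reports each valley height, the right-tail area beyond the
#' last valley, and the standard deviation of all cells.
#'
#' @param curve a `density_curve`.
#' @param landmarks a [landmark_set()].
#' @param values the batch's arcsinh values for the marker.
#' @return An object of class `peak_summary`: list with `peaks` (data frame:
#'   `mode`, `height`, `sd`, `auc`), `valleys` (`location`, `height`),
#'   `auc_right_tail`, `sd_all`, `n_peaks`.
#' @export
summarize_peaks <- function(curve, landmarks, values) {
  values <- values[!is.na(values)]
  g <- curve$grid
  d <- curve$density
  pk <- landmarks$peaks
  vl <- landmarks$valleys
  bounds <- c(g[1], vl$location, g[length(g)])
  # interval of peak i: between the valleys flanking it
  pk_int <- t(vapply(pk$location, function(p) {
    lo <- max(bounds[bounds <= p])
    hi <- min(bounds[bounds >= p])
    c(lo, hi)
  }, numeric(2)))
  pop_sd <- function(x) if (length(x) == 0) 0 else sqrt(mean((x - mean(x))^2))
  seg_auc <- function(lo, hi) {
    if (hi <= lo) return(0)
    xs <- unique(sort(c(lo, g[g > lo & g < hi], hi)))
    ys <- stats::approx(g, d, xout = xs, rule = 2)$y
    trapz(xs, ys)
  }
  sds <- aucs <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    lo <- pk_int[i, 1]; hi <- pk_int[i, 2]
    # half-open on the right except the last interval, so cells split cleanly
    inside <- if (i < nrow(pk)) values >= lo & values < hi
              else values >= lo & values <= hi
    if (!any(inside)) warning("empty peak interval at mode ",
                              round(pk$location[i], 3))
    sds[i] <- pop_sd(values[inside])
    aucs[i] <- seg_auc(lo, hi)
  }
  last_valley <- if (nrow(vl) > 0) vl$location[nrow(vl)] else g[length(g)]
  structure(list(
    peaks = data.frame(mode = pk$location, height = pk$height, sd = sds,
                       auc = aucs),
    valleys = data.frame(location = vl$location, height = vl$height),
    auc_right_tail = seg_auc(last_valley, g[length(g)]),
    sd_all = pop_sd(values),
    n_peaks = nrow(pk)), class = "peak_summary")
}

#' Stain index
#'
#' The classical flow-cytometry separation statistic:
#' `(PosPeakMode - NegPeakMode) / (2 * SD(NegPeak))`, using the leftmost peak
#' as negative and the rightmost as positive.
#'
#' @param summary a [summarize_peaks()] result with at least 2 peaks.
#' @return numeric scalar.
#' @export
stain_index <- function(summary) {
  p <- summary$peaks
  if (nrow(p) < 2) stop("stain index needs at least 2 peaks")
  if (p$sd[1] == 0) stop("degenerate negative population (SD = 0)")
  (p$mode[nrow(p)] - p$mode[1]) / (2 * p$sd[1])
}

#' Stain quality score
#'
#' A density-based extension of the stain index covering one, two, and three
#' or more peaks, comparable across peak counts:
#' \describe{
#'   \item{2 peaks}{`(PosMode - NegMode) / (SD(Neg) + SD(Pos)) *
#'     (PosHeight - ValleyHeight + 1) * (AUC(Pos) + 1)`}
#'   \item{3+ peaks}{`(RightmostMode - NegMode) / sum(SD(each peak)) *
#'     (RightmostHeight - RightmostValleyHeight + 1) *
#'     (AUC(all non-negative peaks) + 1)`}
#'   \item{1 peak}{`(Valley - PeakMode) / SD(all cells) *
#'     (0 - ValleyHeight + 1) * (AUC(right tail) + 1)` — the peak-to-valley
#'     distance bounds the separation from below, the missing positive peak
#'     height is 0, and the right-tail area distinguishes background-only
#'     markers from shoulder/heavy-tail markers.}
#' }
#'
#' @param summary a [summarize_peaks()] result.
#' @param n_peaks number of identified peaks; defaults to the summary's.
#' @return numeric scalar.
#' @export
stain_quality_score <- function(summary, n_peaks = summary$n_peaks) {
  p <- summary$peaks
  v <- summary$valleys
  if (n_peaks != nrow(p)) stop("summary is inconsistent with n_peaks")
  if (n_peaks >= 3) {
    if (sum(p$sd) == 0) stop("zero total peak SD")
    k <- nrow(p)
    (p$mode[k] - p$mode[1]) / sum(p$sd) *
      (p$height[k] - v$height[nrow(v)] + 1) * (sum(p$auc[-1]) + 1)
  } else if (n_peaks == 2) {
    if (p$sd[1] + p$sd[2] == 0) stop("zero peak SDs")
    if (nrow(v) < 1) stop("2-peak score needs the separating valley")
    (p$mode[2] - p$mode[1]) / (p$sd[1] + p$sd[2]) *
      (p$height[2] - v$height[1] + 1) * (p$auc[2] + 1)
  } else {
    if (summary$sd_all == 0) stop("zero SD of all data")
    if (nrow(v) < 1) stop("1-peak score needs the slope-derived valley")
    (v$location[1] - p$mode[1]) / summary$sd_all *
      (0 - v$height[1] + 1) * (summary$auc_right_tail + 1)
  }
}

#' Stain-quality report over all markers and batches
#'
#' Runs landmark detection on the raw (pre-normalization) arcsinh values of
#' every available (marker, batch) and tabulates peak counts, stain-quality
#' scores and stain indices. Markers are flagged when the score falls below
#' the threshold (default 5, the conventional sufficient-separation line).
#'
#' @param ds an [adt_dataset()] with batches attached.
#' @param config an [adt_config()].
#' @return list with `table` (marker, batch, n_peaks, score, stain_index,
#'   flagged) and `by_marker` (per-marker mean score across batches).
#' @export
quality_report <- function(ds, config = adt_config()) {
  stopifnot(inherits(ds, "adt_dataset"), !is.null(ds$batch))
  rows <- list()
  for (mk in marker_names(ds)) {
    col <- ds$counts[, mk]
    for (b in levels(ds$batch)) {
      vals <- col[ds$batch == b]
      if (all(is.na(vals))) next
      y <- arcsinh_transform(vals, config$arcsinh_cofactor)
      grid <- shared_grid(list(y), config)
      row <- tryCatch({
        det <- detect_landmarks(y, grid, config,
                                config$peak_count_prior[mk],
                                positive_only_flags(config, mk, b))
        sm <- summarize_peaks(det$curve, det$landmarks, y)
        sc <- stain_quality_score(sm)
        si <- if (sm$n_peaks >= 2) stain_index(sm) else NA_real_
        data.frame(marker = mk, batch = b, n_peaks = sm$n_peaks, score = sc,
                   stain_index = si, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(marker = mk, batch = b, n_peaks = NA_integer_,
                   score = NA_real_, stain_index = NA_real_,
                   stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  tab$flagged <- !is.na(tab$score) & tab$score < config$quality_threshold
  by_marker <- stats::aggregate(score ~ marker, data = tab, FUN = mean,
                                na.action = stats::na.omit)
  names(by_marker)[2] <- "mean_score"
  list(table = tab, by_marker = by_marker)
}
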