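#' Landmark set for one (marker, batch)
#'
#' Ordered peaks and valleys of a density curve. Peaks and valleys strictly
#' interleave: between any two adjacent peaks lies exactly one valley. A
#' trailing (slope-derived) valley right of a single peak, or a leading valley
#' left of a positive-only peak, is also permitted.
#'
#' @param peaks data frame with columns `location`, `height` and optionally
#'   `provenance`, `outlier`, `label`.
#' @param valleys data frame with columns `location`, `height` and optionally
#'   `provenance`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(peaks, valleys = empty_landmarks()) {
  peaks <- complete_landmarks(peaks, label = TRUE)
  valleys <- complete_landmarks(valleys)
  if (nrow(peaks) < 1) stop("a landmark set needs at least one peak")
  ls <- structure(list(peaks = peaks, valleys = valleys), class = "landmark_set")
  validate_interleaving(ls)
  ls
}

empty_landmarks <- function() {
  data.frame(location = numeric(0), height = numeric(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

complete_landmarks <- function(df, label = FALSE) {
  df <- as.data.frame(df)
  if (is.null(df$provenance)) df$provenance <- rep("detected", nrow(df))
  if (label) {
    if (is.null(df$outlier)) df$outlier <- rep(FALSE, nrow(df))
    if (is.null(df$label)) df$label <- rep(NA_character_, nrow(df))
  }
  df[order(df$location), , drop = FALSE]
}

validate_interleaving <- function(ls) {
  if (nrow(ls$valleys) == 0) return(invisible(ls))  # valleys not detected yet
  locs <- c(ls$peaks$location, ls$valleys$location)
  type <- rep(c("P", "V"), c(nrow(ls$peaks), nrow(ls$valleys)))
  if (anyDuplicated(locs)) stop("landmark locations must be distinct")
  type <- type[order(locs)]
  if (any(type[-1] == type[-length(type)]))
    stop("peaks and valleys must strictly interleave")
  invisible(ls)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", nrow(x$peaks), "peak(s) at",
      toString(round(x$peaks$location, 3)), "|", nrow(x$valleys),
      "valley(s) at", toString(round(x$valleys$location, 3)), "\n")
  invisible(x)
}

#' Detect peaks of a density curve
#'
#' Peaks are grid-local maxima inside high-density regions: their height must
#' reach `min_height_frac` of the maximal density. A plateau of equal maximal
#' values yields one peak at its leftmost grid point. Boundary modes count
#' (a monotone decreasing curve has its peak at the left edge).
#'
#' @param curve a [estimate_density()] result.
#' @param min_height_frac minimum height as a fraction of `max(density)`.
#' @return data frame with `location`, `height`, `index`, ordered by location.
#' @export
detect_peaks <- function(curve, min_height_frac = 0.01) {
  d <- curve$density
  r <- rle(d)
  k <- length(r$values)
  run_start <- cumsum(c(1L, r$lengths[-k]))
  up <- c(TRUE, diff(r$values) > 0)        # run higher than previous run
  down <- c(r$values[-1] < r$values[-k], TRUE)  # run higher than next run
  is_peak <- up & down
  idx <- run_start[is_peak]
  keep <- d[idx] >= min_height_frac * max(d)
  idx <- idx[keep]
  data.frame(location = curve$grid[idx], height = d[idx], index = idx)
}

#' Drop peaks of low topographic prominence
#'
#' A local maximum only counts as a population peak when it rises clearly
#' above the saddle separating it from higher terrain. Peaks whose prominence
#' (height minus the highest saddle on a path to a taller peak) is below
#' `prominence_frac` of the maximal density are discarded, least prominent
#' first. The tallest peak is always kept. This keeps KDE noise bumps at
#' narrow bandwidths from masquerading as positive populations.
#'
#' @param curve a `density_curve`.
#' @param peaks data frame from [detect_peaks()].
#' @param prominence_frac minimum prominence as a fraction of `max(density)`.
#' @return filtered peak data frame.
#' @export
filter_low_prominence <- function(curve, peaks, prominence_frac = 0.05) {
  d <- curve$density
  repeat {
    if (nrow(peaks) <= 1 || prominence_frac <= 0) return(peaks)
    prom <- vapply(seq_len(nrow(peaks)), function(i) {
      h <- peaks$height[i]
      side_saddle <- function(step) {
        j <- peaks$index[i]; lowest <- h
        while (j >= 1 && j <= length(d)) {
          if (d[j] > h) return(lowest)
          lowest <- min(lowest, d[j])
          j <- j + step
        }
        -Inf
      }
      saddle <- max(side_saddle(-1L), side_saddle(1L))
      if (is.finite(saddle)) h - saddle else h
    }, numeric(1))
    low <- which(prom < prominence_frac * max(d))
    if (length(low) == 0) return(peaks)
    peaks <- peaks[-low[which.min(prom[low])], , drop = FALSE]
  }
}

#' Detect valleys between peaks (or a slope-derived valley for one peak)
#'
#' With `k >= 2` peaks, the valley between each adjacent pair is the
#' minimum-density grid point strictly between them (ties broken at the middle
#' tied index). With a single peak (including shoulder-peak shapes), the
#' valley is slope-derived: the first grid point right of the steepest descent
#' where the absolute slope drops below `slope_frac` of that steepest descent,
#' marking the transition from the background peak to the right tail or
#' shoulder.
#'
#' @param curve a `density_curve`.
#' @param peaks data frame from [detect_peaks()].
#' @param slope_frac slope threshold fraction for the single-peak rule.
#' @return data frame with `location`, `height`, `index`, `provenance`.
#' @export
detect_valleys <- function(curve, peaks, slope_frac = 0.3) {
  if (nrow(peaks) < 1) stop("need at least one peak")
  d <- curve$density
  g <- curve$grid
  if (is.null(peaks$index))
    peaks$index <- vapply(peaks$location,
                          function(l) which.min(abs(g - l)), integer(1))
  if (nrow(peaks) >= 2) {
    out <- lapply(seq_len(nrow(peaks) - 1), function(k) {
      lo <- peaks$index[k]; hi <- peaks$index[k + 1]
      if (hi - lo < 2) {
        i <- if (d[lo] < d[hi]) lo else hi  # degenerate: adjacent grid points
        return(data.frame(location = g[i], height = d[i], index = i,
                          provenance = "detected"))
      }
      span <- (lo + 1):(hi - 1)
      cand <- span[d[span] == min(d[span])]
      i <- cand[ceiling(length(cand) / 2)]
      data.frame(location = g[i], height = d[i], index = i,
                 provenance = "detected")
    })
    do.call(rbind, out)
  } else {
    slope_valley(curve, peaks$index[1], slope_frac, side = "right")
  }
}

# valley from the slope criterion on one side of a single peak
slope_valley <- function(curve, peak_index, slope_frac, side = c("right", "left")) {
  side <- match.arg(side)
  d <- curve$density
  g <- curve$grid
  dt <- g[2] - g[1]
  s <- diff(d) / dt  # s[i] = slope between grid i and i+1
  if (side == "right") {
    if (peak_index >= length(d) - 1)
      return(data.frame(location = g[length(g)], height = d[length(d)],
                        index = length(g), provenance = "slope-derived"))
    span <- peak_index:(length(d) - 1)
    steep_rel <- which.min(s[span])                 # most negative slope
    steep <- abs(s[span][steep_rel])
    after <- span[span > span[steep_rel]]
    hit <- after[abs(s[after]) < slope_frac * steep]
    i <- if (length(hit) > 0) hit[1] + 1L else {
      flat <- after[which.min(abs(s[after]))]
      flat + 1L
    }
    # the transition to the right tail also requires the peak's own bulk to
    # have ended: walk on while the density still carries > 2% of the peak,
    # so a heavy tail or shoulder pushes the valley outward
    while (i < length(d) && d[i] > 0.02 * d[peak_index]) i <- i + 1L
  } else {
    if (peak_index <= 2)
      return(data.frame(location = g[1], height = d[1], index = 1L,
                        provenance = "slope-derived"))
    span <- 1:(peak_index - 1)                      # slopes left of the peak
    steep_rel <- which.max(s[span])                 # steepest ascent
    steep <- abs(s[span][steep_rel])
    before <- span[span < span[steep_rel]]
    hit <- before[abs(s[before]) < slope_frac * steep]
    i <- if (length(hit) > 0) hit[length(hit)] else {
      if (length(before) > 0) before[which.min(abs(s[before]))] else 1L
    }
    while (i > 1 && d[i] > 0.02 * d[peak_index]) i <- i - 1L
  }
  data.frame(location = g[i], height = d[i], index = i,
             provenance = "slope-derived")
}

#' Merge candidate background peaks near zero
#'
#' Discrete counts near zero can produce several artificial peaks under the
#' arcsinh transform. All peaks located below `neg_candidate_thres` are
#' replaced by a single negative peak at the location of the tallest among
#' them; valleys between merged peaks are removed and interleaving restored.
#'
#' @param landmarks a [landmark_set()].
#' @param neg_candidate_thres arcsinh-scale threshold.
#' @return a [landmark_set()].
#' @export
merge_low_peaks <- function(landmarks, neg_candidate_thres) {
  pk <- landmarks$peaks
  low <- pk$location < neg_candidate_thres
  if (sum(low) <= 1) return(landmarks)
  tallest <- which(low)[which.max(pk$height[low])]
  merged <- pk[tallest, , drop = FALSE]
  merged$provenance <- "merged"
  pk2 <- rbind(merged, pk[!low, , drop = FALSE])
  pk2 <- pk2[order(pk2$location), , drop = FALSE]
  reinterleave(pk2, landmarks$valleys)
}

#' Drop a spurious empty-droplet peak near zero
#'
#' If quality filtering left empty droplets, a minor enriched peak can appear
#' near zero before the true negative peak. The leftmost peak is removed when
#' it lies well below the background-candidate region (below half of
#' `neg_candidate_thres`, i.e. clearly nearer zero than any plausible
#' background mode) and its height is below `height_frac` of the next peak's
#' height. The sole peak is never removed.
#'
#' @param landmarks a [landmark_set()].
#' @param neg_candidate_thres arcsinh-scale threshold.
#' @param height_frac "minor" peak height fraction.
#' @return a [landmark_set()].
#' @export
drop_spurious_zero_peak <- function(landmarks, neg_candidate_thres,
                                    height_frac = 0.5) {
  pk <- landmarks$peaks
  if (nrow(pk) < 2) return(landmarks)
  if (pk$location[1] < neg_candidate_thres / 2 &&
      pk$height[1] < height_frac * pk$height[2]) {
    reinterleave(pk[-1, , drop = FALSE], landmarks$valleys)
  } else landmarks
}

# keep, for each adjacent pair of surviving peaks, the lowest valley between
# them; drop valleys not between surviving peaks (trailing slope valleys right
# of the last peak are retained)
reinterleave <- function(peaks, valleys) {
  if (nrow(valleys) == 0) return(landmark_set(peaks, valleys))
  keep <- list()
  locs <- peaks$location
  if (nrow(peaks) >= 2) {
    for (k in seq_len(nrow(peaks) - 1)) {
      inside <- valleys[valleys$location > locs[k] &
                        valleys$location < locs[k + 1], , drop = FALSE]
      if (nrow(inside) > 0)
        keep[[length(keep) + 1]] <- inside[which.min(inside$height), , drop = FALSE]
    }
  }
  # only a slope-derived valley legitimately trails the last peak; valleys
  # orphaned by a merged/dropped right peak must go
  trailing <- valleys[valleys$location > locs[length(locs)] &
                      valleys$provenance == "slope-derived", , drop = FALSE]
  if (nrow(trailing) > 0 && nrow(peaks) == 1)
    keep[[length(keep) + 1]] <- trailing[1, , drop = FALSE]
  landmark_set(peaks, if (length(keep)) do.call(rbind, keep) else empty_landmarks())
}

#' Flag outlier positive-peak locations across batches
#'
#' A batch's positive peak is an outlier when its distance from the
#' cross-batch median exceeds `mad_multiplier` scaled MADs (consistency
#' constant 1.4826, the [stats::mad()] default). Flagged peaks are excluded
#' from target computation and from warp pinning. Fewer than 3 available
#' locations give no flags (insufficient support).
#'
#' @param locations numeric vector of per-batch rightmost-peak locations
#'   (`NA` allowed for batches without a positive peak).
#' @param mad_multiplier flagging threshold.
#' @return logical vector, same length as `locations` (`FALSE` where `NA`).
#' @export
flag_outlier_positive_peaks <- function(locations, mad_multiplier = 3) {
  flags <- rep(FALSE, length(locations))
  ok <- !is.na(locations)
  if (sum(ok) < 3) return(flags)
  x <- locations[ok]
  dev <- abs(x - stats::median(x))
  s <- stats::mad(x)
  score <- if (s > 0) dev / s else ifelse(dev > 0, Inf, 0)
  flags[ok] <- score > mad_multiplier
  flags
}

#' Pairwise earth mover's distance between batch densities of one marker
#'
#' 1-D EMD (Wasserstein-1) computed as the integral of the absolute
#' difference between the two normalized CDFs over the shared grid.
#'
#' @param curves named list of `density_curve` objects sharing one grid.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
compute_emd_matrix <- function(curves) {
  n <- length(curves)
  g <- curves[[1]]$grid
  for (cu in curves)
    if (length(cu$grid) != length(g) || any(cu$grid != g))
      stop("density curves must share the same grid")
  cdfs <- vapply(curves, function(cu) {
    m <- c(0, cumsum(diff(g) * (utils::head(cu$density, -1) +
                                utils::tail(cu$density, -1)) / 2))
    m / m[length(m)]
  }, numeric(length(g)))
  emd <- matrix(0, n, n, dimnames = list(names(curves), names(curves)))
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
    v <- trapz(g, abs(cdfs[, a] - cdfs[, b]))
    emd[a, b] <- v
    emd[b, a] <- v
  }
  emd
}

#' Impute outlier valleys from distribution-similar batches
#'
#' For each valley slot, locations that are MAD outliers across batches are
#' replaced by the mean valley location of the `k_neighbors` batches with the
#' smallest EMD to the flagged batch (other flagged batches excluded). If no
#' clean neighbor exists the valley is left as detected, with a warning.
#'
#' @param valley_matrix numeric matrix, batches x valley slots (NA = absent).
#' @param emd EMD matrix from [compute_emd_matrix()] (same batch order).
#' @param mad_multiplier flagging threshold.
#' @param k_neighbors number of neighbors to average.
#' @return list with `locations` (imputed matrix) and `imputed` (logical matrix).
#' @export
impute_outlier_valleys <- function(valley_matrix, emd, mad_multiplier = 3,
                                   k_neighbors = 2) {
  vm <- as.matrix(valley_matrix)
  imputed <- matrix(FALSE, nrow(vm), ncol(vm), dimnames = dimnames(vm))
  for (j in seq_len(ncol(vm))) {
    flags <- flag_outlier_positive_peaks(vm[, j], mad_multiplier)
    for (b in which(flags)) {
      clean <- which(!flags & !is.na(vm[, j]))
      if (length(clean) == 0) {
        warning("no clean neighbor for valley imputation in batch ",
                rownames(vm)[b])
        next
      }
      nb <- clean[order(emd[b, clean])]
      nb <- nb[seq_len(min(k_neighbors, length(nb)))]
      vm[b, j] <- mean(vm[nb, j])
      imputed[b, j] <- TRUE
    }
  }
  list(locations = vm, imputed = imputed)
}

#' Apply a single-positive-peak prior
#'
#' For batches known to contain only positive cells for a marker (e.g. a
#' T-cell-only batch stained for CD3), the sole detected peak is a positive
#' population, not background. The peak is labeled `positive` and its
#' slope-derived valley is placed to its left (mirrored slope criterion), so
#' alignment later maps it to the positive target. With two or more detected
#' peaks the rightmost is treated as positive, with a warning.
#'
#' @param landmarks a [landmark_set()].
#' @param is_positive_only logical: does the prior apply?
#' @param curve the `density_curve` (needed to place the mirrored valley).
#' @param slope_frac slope threshold fraction.
#' @return a [landmark_set()] with peak `label`s set.
#' @export
apply_positive_peak_prior <- function(landmarks, is_positive_only, curve = NULL,
                                      slope_frac = 0.1) {
  pk <- landmarks$peaks
  if (!is_positive_only) {
    pk$label <- c("negative", rep("positive", nrow(pk) - 1))
    return(landmark_set(pk, landmarks$valleys))
  }
  if (nrow(pk) >= 2) {
    warning("positive-only prior set but ", nrow(pk), " peaks detected; ",
            "treating the rightmost as positive")
    pk$label <- c("negative", rep("positive", nrow(pk) - 1))
    pk$provenance[nrow(pk)] <- "prior-override"
    return(landmark_set(pk, landmarks$valleys))
  }
  pk$label <- "positive"
  pk$provenance <- "prior-override"
  valleys <- landmarks$valleys
  if (!is.null(curve)) {
    idx <- which.min(abs(curve$grid - pk$location[1]))
    valleys <- slope_valley(curve, idx, slope_frac, side = "left")
  }
  landmark_set(pk, valleys)
}
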