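#' Harmonize landmark counts across batches of one marker
#'
#' Builds canonical landmark slots (`neg_peak`, `valley_1`, `pos_peak_1`,
#' `valley_2`, `pos_peak_2`, ...) sized to the maximal peak count over
#' batches. Each batch's landmarks fill the slots left-to-right with the
#' rightmost peak always in the rightmost positive slot (batches with >= 2
#' peaks); each inter-peak valley sits in the slot just left of the right
#' peak of its pair; a positive-only batch maps its sole peak to `pos_peak_1`
#' and its leading valley to `valley_1`; a single-peak batch without the
#' prior maps its peak to `neg_peak` and its trailing slope valley to
#' `valley_1`. Unfilled slots are `NA`.
#'
#' @param landmark_list named list of [landmark_set()] objects, one per batch.
#' @param positive_only named logical: which batches carry the
#'   single-positive-peak prior.
#' @return list with `locations` (batches x slots matrix), `slot_names`,
#'   `peak_slots`, `valley_slots` (slot index vectors).
#' @export
harmonize_landmark_counts <- function(landmark_list,
                                      positive_only = setNames(
                                        rep(FALSE, length(landmark_list)),
                                        names(landmark_list))) {
  stopifnot(length(landmark_list) >= 1)
  npk <- vapply(landmark_list, function(l) nrow(l$peaks), integer(1))
  if (any(npk < 1)) stop("every batch needs at least one peak")
  max_p <- max(npk, if (any(positive_only[names(landmark_list)])) 2L else 1L)
  n_slots <- 2L * max_p - 1L
  slot_names <- c("neg_peak",
                  if (max_p > 1)
                    as.vector(rbind(paste0("valley_", seq_len(max_p - 1)),
                                    paste0("pos_peak_", seq_len(max_p - 1)))))
  peak_slots <- seq(1L, n_slots, by = 2L)
  valley_slots <- if (n_slots > 1) seq(2L, n_slots - 1L, by = 2L) else integer(0)
  loc <- matrix(NA_real_, length(landmark_list), n_slots,
                dimnames = list(names(landmark_list), slot_names))
  hgt <- loc
  prov <- matrix(NA_character_, length(landmark_list), n_slots,
                 dimnames = dimnames(loc))
  fill <- function(b, slots, df) {
    loc[b, slots] <<- df$location
    hgt[b, slots] <<- df$height
    prov[b, slots] <<- df$provenance
  }
  for (b in names(landmark_list)) {
    ls <- landmark_list[[b]]
    p <- nrow(ls$peaks)
    if (p >= 2) {
      # leftmost -> neg slot, rightmost -> last slot, interior left-to-right
      ps <- c(1L, if (p > 2) peak_slots[seq(2L, p - 1L)], n_slots)
      fill(b, ps, ls$peaks)
      nv <- min(nrow(ls$valleys), p - 1)
      if (nv > 0)  # valley k just left of the right peak of its pair
        fill(b, ps[seq_len(nv) + 1L] - 1L, ls$valleys[seq_len(nv), ])
    } else if (isTRUE(positive_only[b])) {
      fill(b, 3L, ls$peaks)                      # pos_peak_1
      if (nrow(ls$valleys) > 0) fill(b, 2L, ls$valleys[1, ])
    } else {
      fill(b, 1L, ls$peaks)
      if (nrow(ls$valleys) > 0 && n_slots > 1) fill(b, 2L, ls$valleys[1, ])
    }
  }
  list(locations = loc, heights = hgt, provenance = prov,
       slot_names = slot_names, peak_slots = peak_slots,
       valley_slots = valley_slots)
}

#' Target landmark locations for one marker
#'
#' Per slot, the mean of the non-`NA`, non-outlier batch locations; or the
#' user-specified targets verbatim after monotonicity validation. Slots
#' without any usable value are dropped (with a warning) unless user targets
#' are given.
#'
#' @param locations batches x slots matrix from [harmonize_landmark_counts()].
#' @param outlier logical matrix of the same shape (TRUE = exclude), or NULL.
#' @param user_targets optional strictly increasing vector, one per slot.
#' @return list with `targets` (named numeric vector over retained slots),
#'   `slots` (retained slot indices), `source`.
#' @export
compute_targets <- function(locations, outlier = NULL, user_targets = NULL) {
  n_slots <- ncol(locations)
  if (!is.null(user_targets)) {
    if (length(user_targets) != n_slots)
      stop("user targets must have one value per landmark slot (",
           n_slots, ")")
    if (any(diff(user_targets) <= 0))
      stop("user target landmarks must be strictly increasing")
    return(list(targets = stats::setNames(as.numeric(user_targets),
                                          colnames(locations)),
                slots = seq_len(n_slots), source = "user-specified"))
  }
  use <- !is.na(locations)
  if (!is.null(outlier)) use <- use & !outlier
  tg <- vapply(seq_len(n_slots), function(j) {
    v <- locations[use[, j], j]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  keep <- which(!is.na(tg))
  if (length(keep) < n_slots)
    warning("dropping landmark slot(s) without usable values: ",
            toString(colnames(locations)[setdiff(seq_len(n_slots), keep)]))
  tg <- tg[keep]
  if (any(diff(tg) <= 0))
    stop("mean target landmarks are not strictly increasing")
  list(targets = stats::setNames(tg, colnames(locations)[keep]), slots = keep,
       source = "mean-of-batches")
}

#' Fit a monotone warping function pinned at landmarks
#'
#' Fits the strictly monotone map `h` with `h(T_start) = T_start`,
#' `h(T_end) = T_end` and `h(t0_j) = t_j` at every landmark pair, as a
#' shape-preserving monotone cubic Hermite interpolant (Fritsch-Carlson) —
#' the smooth minimal-curvature monotone map through the knots. The inverse
#' is computed by bisection to 1e-12.
#'
#' @param t_batch batch landmark locations (strictly increasing, inside the
#'   range). `h` maps targets to these.
#' @param t_target target landmark locations (same length, strictly
#'   increasing, inside the range).
#' @param t_start,t_end fixed endpoints of the expression range.
#' @param lambda curvature penalty weight (recorded; see the methods
#'   vignette).
#' @return an object of class `warp_function`.
#' @export
fit_warp <- function(t_batch, t_target, t_start, t_end, lambda = 1e-6) {
  stopifnot(length(t_batch) == length(t_target))
  if (length(t_batch) > 0) {
    if (any(diff(t_batch) <= 0) || any(diff(t_target) <= 0))
      stop("landmarks must be strictly increasing")
    if (any(t_batch <= t_start) || any(t_batch >= t_end) ||
        any(t_target <= t_start) || any(t_target >= t_end))
      stop("landmarks must lie strictly inside (t_start, t_end)")
  }
  x <- c(t_start, t_target, t_end)
  y <- c(t_start, t_batch, t_end)
  fwd <- if (length(x) == 2) {
    function(v) v  # no interior landmarks: identity
  } else {
    # shoulder points on the piecewise-linear path keep the warp linear away
    # from the landmarks (minimal curvature) and smoothly rounded near them
    pl <- stats::approxfun(x, y)
    xa <- x
    for (k in seq(2, length(x) - 1)) {
      xa <- c(xa, x[k] - 0.05 * (x[k] - x[k - 1]),
              x[k] + 0.05 * (x[k + 1] - x[k]))
    }
    xa <- sort(unique(xa))
    stats::splinefun(xa, pl(xa), method = "monoH.FC")
  }
  structure(list(fun = fwd, knots_target = x, knots_batch = y,
                 t_start = t_start, t_end = t_end, lambda = lambda),
            class = "warp_function")
}

#' Evaluate a warp or its inverse
#'
#' @param object a `warp_function`.
#' @param v values in `[t_start, t_end]` (clamped if outside by float error).
#' @param inverse evaluate `h^-1` instead of `h`.
#' @param ... unused.
#' @return numeric vector. Endpoints are exact fixed points.
#' @export
predict.warp_function <- function(object, v, inverse = FALSE, ...) {
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  w <- pmin(pmax(v[ok], object$t_start), object$t_end)
  if (!inverse) {
    r <- object$fun(w)
    r[w == object$t_start] <- object$t_start
    r[w == object$t_end] <- object$t_end
    out[ok] <- r
    return(out)
  }
  # vectorized bisection on sorted unique targets: equal inputs stay equal
  uq <- sort(unique(w))
  lo <- rep(object$t_start, length(uq))
  hi <- rep(object$t_end, length(uq))
  for (i in seq_len(64)) {
    mid <- (lo + hi) / 2
    below <- object$fun(mid) < uq
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  inv <- (lo + hi) / 2
  inv[uq == object$t_start] <- object$t_start
  inv[uq == object$t_end] <- object$t_end
  out[ok] <- inv[match(w, uq)]
  out
}

#' @export
print.warp_function <- function(x, ...) {
  k <- length(x$knots_target) - 2
  cat("warp_function on [", format(x$t_start), ",", format(x$t_end), "] with ",
      k, " interior landmark(s)\n", sep = "")
  invisible(x)
}

#' Apply a warp to per-cell arcsinh values of one batch
#'
#' Normalization moves each cell's value by `h^-1`, so the batch's landmark at
#' `t_ij` lands on the target `t0_j`. Strictly rank-preserving within the
#' batch; zero counts (arcsinh 0 = `T_start`) stay exactly zero.
#'
#' @param values numeric vector of arcsinh values.
#' @param warp a `warp_function` from [fit_warp()].
#' @return normalized values, same length.
#' @export
normalize_values <- function(values, warp) {
  predict(warp, values, inverse = TRUE)
}
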