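#' Detect and clean landmarks for one (marker, batch)
#'
#' The per-sample detection pipeline: bandwidth ladder search, peak detection,
#' spurious empty-droplet peak rejection, near-zero peak merging, valley
#' detection, and the optional single-positive-peak prior.
#'
#' @param values arcsinh values of the batch for one marker.
#' @param grid shared density grid for the marker.
#' @param config an [adt_config()].
#' @param peak_count_prior optional expected peak count.
#' @param positive_only logical: single-positive-peak prior for this batch.
#' @param neg_candidate_thres background-candidate threshold; defaults to the
#'   config value. Post-alignment re-detection passes the aligned valley
#'   instead, because "near zero in raw counts" is meaningless after warping.
#' @return list with `landmarks` (a [landmark_set()]) and `curve`.
#' @export
detect_landmarks <- function(values, grid, config = adt_config(),
                             peak_count_prior = NULL, positive_only = FALSE,
                             neg_candidate_thres = config$neg_candidate_thres) {
  clean <- function(curve) {
    pk <- detect_peaks(curve, config$min_height_frac)
    pk <- filter_low_prominence(curve, pk, config$min_prominence_frac)
    ls <- landmark_set(pk)
    ls <- drop_spurious_zero_peak(ls, neg_candidate_thres,
                                  config$spurious_height_frac)
    merge_low_peaks(ls, neg_candidate_thres)
  }
  sel <- select_bandwidth(values, config$bandwidth_ladder, grid,
                          peak_count_prior, config$min_height_frac,
                          config$min_prominence_frac)
  curve <- sel$curve
  ls <- clean(curve)
  if (nrow(ls$peaks) == 1) {
    # unimodal outcome: the ladder rung was chosen for mode hunting, not for
    # representing a single population. Re-estimate at a data-driven
    # bandwidth (Silverman) floored by the spacing of distinct values, so
    # count discreteness cannot atomize the curve.
    bw <- unimodal_bandwidth(values)
    if (is.finite(bw) && bw > 0) {
      bw <- min(bw, config$bandwidth_ladder[1])
      curve <- estimate_density(values, bw, grid)
      ls <- clean(curve)
    }
  }
  valleys <- detect_valleys(curve, ls$peaks, config$slope_valley_frac)
  ls <- landmark_set(ls$peaks, valleys)
  ls <- apply_positive_peak_prior(ls, positive_only, curve,
                                  config$slope_valley_frac)
  list(landmarks = ls, curve = curve)
}

# Silverman rule-of-thumb bandwidth with a discreteness floor: the kernel
# must span adjacent distinct values (arcsinh count atoms) in the central
# mass, or the KDE resolves individual counts as peaks
unimodal_bandwidth <- function(values) {
  values <- values[!is.na(values)]
  s <- min(stats::sd(values), stats::IQR(values) / 1.34)
  bw <- 0.9 * s * length(values)^(-1 / 5)
  qs <- stats::quantile(values, c(0.1, 0.9), names = FALSE)
  u <- sort(unique(values))
  central <- u[u >= qs[1] & u <= qs[2]]
  if (length(central) > 1)
    bw <- max(bw, 2 * stats::median(diff(central)))
  bw
}

positive_only_flags <- function(config, marker, batches) {
  flags <- stats::setNames(rep(FALSE, length(batches)), batches)
  po <- config$positive_peak_only
  if (!is.null(po))
    flags[batches %in% po$batch[po$marker == marker]] <- TRUE
  flags
}

slot_type <- function(slot_names) {
  ifelse(slot_names == "neg_peak", "neg_peak",
         ifelse(grepl("^valley", slot_names), "valley", "pos_peak"))
}

slot_index <- function(slot_names) {
  idx <- sub("^[a-z_]+_", "", slot_names)
  as.integer(ifelse(slot_names == "neg_peak", 1L, idx))
}

# long-format landmark table from a harmonization result
harmonization_table <- function(marker, hm, outlier) {
  rows <- which(!is.na(hm$locations), arr.ind = TRUE)
  if (nrow(rows) == 0) return(NULL)
  data.frame(
    marker = marker,
    batch = rownames(hm$locations)[rows[, 1]],
    landmark_type = slot_type(hm$slot_names)[rows[, 2]],
    index = slot_index(hm$slot_names)[rows[, 2]],
    location = hm$locations[rows],
    height = hm$heights[rows],
    provenance = hm$provenance[rows],
    outlier_flag = outlier[rows],
    stringsAsFactors = FALSE)
}

apply_landmark_override <- function(hm, marker, override) {
  ov <- override[override$marker == marker, , drop = FALSE]
  if (nrow(ov) == 0) return(hm)
  for (i in seq_len(nrow(ov))) {
    slot <- if (ov$landmark_type[i] == "neg_peak") "neg_peak"
            else paste0(sub("_peak", "", ov$landmark_type[i]), "_",
                        ov$index[i])
    slot <- sub("^pos_", "pos_peak_", slot)
    if (!slot %in% hm$slot_names)
      stop("override references unknown landmark slot '", slot,
           "' for marker ", marker)
    if (!ov$batch[i] %in% rownames(hm$locations))
      stop("override references unknown batch '", ov$batch[i], "'")
    hm$locations[ov$batch[i], slot] <- ov$location[i]
    hm$provenance[ov$batch[i], slot] <- "override"
  }
  hm
}

# imputed/overridden valleys may break within-batch ordering; drop offending
# slots from the warp pins rather than fitting an invalid warp
usable_slots <- function(locs, outlier_row, t_start, t_end) {
  ok <- which(!is.na(locs) & !outlier_row & locs > t_start & locs < t_end)
  while (length(ok) > 1 && any(diff(locs[ok]) <= 0)) {
    bad <- which(diff(locs[ok]) <= 0)[1] + 1L
    ok <- ok[-bad]
  }
  ok
}

#' Run the full normalization pipeline
#'
#' Per marker (independently): arcsinh transform, per-batch landmark
#' detection and cleanup, MAD outlier flagging of positive peaks, EMD-neighbor
#' valley imputation, target computation (cross-batch means or user targets),
#' monotone warp fitting pinned at the landmarks, and application of the
#' inverse warp to every cell. Markers absent in a batch are skipped for that
#' batch and reported as `NA`. Per-marker failures are aggregated and reported
#' at the end, not fail-fast.
#'
#' @param ds an [adt_dataset()] with batches attached.
#' @param config an [adt_config()].
#' @param landmark_override optional data frame (columns `marker`, `batch`,
#'   `landmark_type`, `index`, `location`) replacing detected landmark
#'   locations — the file-based counterpart of manual landmark editing.
#' @param target_landmarks optional named list (by marker) of target landmark
#'   vectors for cross-run integration; takes precedence over the config's
#'   `target_landmark_location` and the cross-batch means.
#' @return An object of class `adt_normalization`: list with `values`
#'   (cells x markers normalized arcsinh matrix), `landmarks_pre`,
#'   `landmarks_post` (long-format tables), `targets`, `warps`, `emd`,
#'   `failures`, `dataset`, `config`.
#' @export
run_normalization <- function(ds, config = adt_config(),
                              landmark_override = NULL,
                              target_landmarks = NULL) {
  stopifnot(inherits(ds, "adt_dataset"))
  if (is.null(ds$batch)) stop("attach batch labels first (attach_batches)")
  validate_availability(ds)
  batches <- levels(ds$batch)
  markers <- marker_names(ds)
  out <- matrix(NA_real_, nrow(ds$counts), ncol(ds$counts),
                dimnames = dimnames(ds$counts))
  pre_tabs <- list(); post_tabs <- list()
  warps <- list(); targets_out <- list(); emds <- list()
  failures <- list()
  for (mk in markers) {
    res <- tryCatch(
      normalize_one_marker(ds, mk, config, landmark_override, target_landmarks),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[mk]] <- conditionMessage(res)
      next
    }
    out[, mk] <- res$values
    pre_tabs[[mk]] <- res$pre
    post_tabs[[mk]] <- res$post
    warps[[mk]] <- res$warps
    targets_out[[mk]] <- res$targets
    emds[[mk]] <- res$emd
  }
  if (length(failures) > 0)
    warning("normalization failed for marker(s): ",
            toString(paste0(names(failures), " (", unlist(failures), ")")))
  structure(list(values = out,
                 landmarks_pre = do.call(rbind, unname(pre_tabs)),
                 landmarks_post = do.call(rbind, unname(post_tabs)),
                 targets = targets_out, warps = warps, emd = emds,
                 failures = failures, dataset = ds, config = config),
            class = "adt_normalization")
}

normalize_one_marker <- function(ds, mk, config, landmark_override,
                                 target_landmarks) {
  batches <- levels(ds$batch)
  col <- ds$counts[, mk]
  avail <- vapply(batches, function(b) any(!is.na(col[ds$batch == b])),
                  logical(1))
  use_b <- batches[avail]
  if (length(use_b) == 0) stop("marker absent in every batch")
  yvals <- lapply(use_b, function(b) arcsinh_transform(
    col[ds$batch == b], config$arcsinh_cofactor))
  names(yvals) <- use_b
  grid <- shared_grid(yvals, config)
  t_start <- grid[1]; t_end <- grid[length(grid)]
  pos_flags <- positive_only_flags(config, mk, use_b)
  prior_k <- config$peak_count_prior[mk]
  if (!is.null(prior_k) && is.na(prior_k)) prior_k <- NULL
  det <- lapply(use_b, function(b) detect_landmarks(
    yvals[[b]], grid, config, prior_k, pos_flags[b]))
  names(det) <- use_b
  lm_list <- lapply(det, `[[`, "landmarks")
  curves <- lapply(det, `[[`, "curve")
  hm <- harmonize_landmark_counts(lm_list, pos_flags)
  # landmarks stranded on the grid boundary are degenerate fallbacks (e.g. a
  # mirrored slope valley that ran off the support): treat as absent
  hm$locations[hm$locations <= t_start | hm$locations >= t_end] <- NA
  # a slope-derived valley is a weak surrogate for a real inter-peak valley:
  # wherever any batch exhibits the real one, surrogates sit out the slot
  for (j in hm$valley_slots) {
    prov <- hm$provenance[, j]
    if (any(prov == "detected", na.rm = TRUE) &&
        any(prov == "slope-derived", na.rm = TRUE))
      hm$locations[which(prov == "slope-derived"), j] <- NA
  }
  if (!is.null(landmark_override))
    hm <- apply_landmark_override(hm, mk, landmark_override)
  emd <- compute_emd_matrix(curves)
  # flag outlier positive peaks (rightmost filled positive slot per batch)
  outlier <- matrix(FALSE, nrow(hm$locations), ncol(hm$locations),
                    dimnames = dimnames(hm$locations))
  pos_slots <- hm$peak_slots[hm$peak_slots > 1]
  rslot <- apply(hm$locations, 1, function(r) {
    filled <- intersect(pos_slots, which(!is.na(r)))
    if (length(filled) == 0) NA_integer_ else max(filled)
  })
  rloc <- ifelse(is.na(rslot), NA_real_,
                 hm$locations[cbind(seq_along(rslot), rslot)])
  pk_flags <- flag_outlier_positive_peaks(rloc, config$mad_multiplier)
  for (b in which(pk_flags)) outlier[b, rslot[b]] <- TRUE
  # impute outlier valleys from EMD-nearest batches
  if (length(hm$valley_slots) > 0 && length(use_b) >= 3) {
    vm <- hm$locations[, hm$valley_slots, drop = FALSE]
    imp <- impute_outlier_valleys(vm, emd, config$mad_multiplier,
                                  config$k_neighbors)
    hm$locations[, hm$valley_slots] <- imp$locations
    hm$provenance[, hm$valley_slots][imp$imputed] <- "imputed"
  }
  pre <- harmonization_table(mk, hm, outlier)
  # targets: explicit per-run > config override > cross-batch means
  user_tg <- NULL
  if (!is.null(target_landmarks) && mk %in% names(target_landmarks))
    user_tg <- target_landmarks[[mk]]
  else if (!is.null(config$target_landmark_location) &&
           mk %in% names(config$target_landmark_location))
    user_tg <- config$target_landmark_location[[mk]]
  tg <- compute_targets(hm$locations, outlier, user_tg)
  # fit and apply one warp per batch
  values_out <- rep(NA_real_, length(col))
  wlist <- list()
  tg_full <- stats::setNames(rep(NA_real_, ncol(hm$locations)),
                             colnames(hm$locations))
  tg_full[tg$slots] <- tg$targets
  for (b in use_b) {
    i <- match(b, rownames(hm$locations))
    slots <- usable_slots(hm$locations[i, ], outlier[i, ], t_start, t_end)
    slots <- slots[!is.na(tg_full[slots])]
    t_batch <- hm$locations[i, slots]
    t_tg <- tg_full[slots]
    # pins must be increasing on both axes; drop target-side violations too
    keep <- usable_slots_pair(t_batch, t_tg)
    w <- fit_warp(t_batch[keep], t_tg[keep], t_start, t_end,
                  config$lambda_penalty)
    wlist[[b]] <- w
    values_out[ds$batch == b] <- normalize_values(yvals[[b]], w)
  }
  # post-normalization landmark re-detection confirms alignment; background
  # candidates now live below the aligned valley, not below a raw-count level
  post_thres <- config$neg_candidate_thres
  if ("valley_1" %in% names(tg_full) && !is.na(tg_full["valley_1"]))
    post_thres <- max(post_thres, tg_full[["valley_1"]])
  post_det <- lapply(use_b, function(b) detect_landmarks(
    values_out[ds$batch == b], grid, config, prior_k, pos_flags[b],
    neg_candidate_thres = post_thres))
  names(post_det) <- use_b
  hm_post <- harmonize_landmark_counts(lapply(post_det, `[[`, "landmarks"),
                                       pos_flags)
  post <- harmonization_table(mk, hm_post,
                              matrix(FALSE, nrow(hm_post$locations),
                                     ncol(hm_post$locations)))
  list(values = values_out, pre = pre, post = post, warps = wlist,
       targets = stats::setNames(tg_full, colnames(hm$locations)), emd = emd)
}

usable_slots_pair <- function(t_batch, t_target) {
  ok <- seq_along(t_batch)
  while (length(ok) > 1 &&
         (any(diff(t_batch[ok]) <= 0) || any(diff(t_target[ok]) <= 0))) {
    d1 <- diff(t_batch[ok]); d2 <- diff(t_target[ok])
    bad <- which(d1 <= 0 | d2 <= 0)[1] + 1L
    ok <- ok[-bad]
  }
  ok
}

#' @export
print.adt_normalization <- function(x, ...) {
  cat("adt_normalization:", nrow(x$values), "cells x", ncol(x$values),
      "markers,", length(x$warps), "marker(s) normalized\n")
  if (length(x$failures) > 0)
    cat("failed markers:", toString(names(x$failures)), "\n")
  invisible(x)
}

#' Aligned valley thresholds of a normalization result
#'
#' After alignment every batch shares the target valleys, so one threshold
#' per (marker, valley slot) serves all batches — the basis of auto-gating.
#'
#' @param norm an [run_normalization()] result.
#' @return named list: per marker, the numeric vector of aligned valley
#'   locations (valley slot order).
#' @export
aligned_valleys <- function(norm) {
  lapply(norm$targets, function(tg) {
    v <- tg[grepl("^valley", names(tg))]
    v[!is.na(v)]
  })
}

#' Write the output bundle of a normalization run
#'
#' Dense normalized matrix, pre-/post-alignment landmark tables, per-batch
#' warp knot table and a machine-readable run manifest.
#'
#' @param norm an [run_normalization()] result.
#' @param dir output directory.
#' @param manifest_extra named list merged into the manifest JSON.
#' @return `dir`, invisibly.
#' @export
write_normalization <- function(norm, dir, manifest_extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_normalized(norm$values, norm$dataset,
                   file.path(dir, "normalized.csv"))
  for (nm in c("landmarks_pre", "landmarks_post"))
    utils::write.table(norm[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  knots <- do.call(rbind, lapply(names(norm$warps), function(mk) {
    do.call(rbind, lapply(names(norm$warps[[mk]]), function(b) {
      w <- norm$warps[[mk]][[b]]
      k <- length(w$knots_target)
      if (k <= 2) return(NULL)
      data.frame(marker = mk, batch = b,
                 target = w$knots_target[-c(1, k)],
                 batch_location = w$knots_batch[-c(1, k)])
    }))
  }))
  if (!is.null(knots))
    utils::write.table(knots, file.path(dir, "warp_knots.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tg <- do.call(rbind, lapply(names(norm$targets), function(mk)
    data.frame(marker = mk, slot = names(norm$targets[[mk]]),
               location = unname(norm$targets[[mk]]))))
  utils::write.table(tg[!is.na(tg$location), ],
                     file.path(dir, "target_landmarks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(list(tool = "adtwarp",
                     version = as.character(utils::packageVersion("adtwarp")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     n_cells = nrow(norm$values),
                     n_markers = ncol(norm$values),
                     batches = levels(norm$dataset$batch),
                     failed_markers = names(norm$failures),
                     config = unclass(norm$config)),
                manifest_extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read per-marker target landmarks from a TSV
#'
#' Accepts the `target_landmarks.tsv` written by [write_normalization()]
#' (columns `marker`, `slot`, `location`), enabling a later run to align to a
#' previous run's targets without joint processing.
#'
#' @param path TSV path.
#' @return named list of numeric target vectors, by marker.
#' @export
read_target_landmarks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  split(tab$location, tab$marker)[unique(tab$marker)]
}
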