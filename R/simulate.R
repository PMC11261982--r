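#' Marker specification for the synthetic generator
#'
#' Describes one surface marker as a mixture over cell populations on the
#' arcsinh scale: one mode and SD per population. Populations sharing a mode
#' (e.g. all CD3-negative lineages) merge into one density peak.
#'
#' @param name marker name.
#' @param modes named numeric vector: arcsinh-scale mode per population.
#' @param sds named numeric vector: arcsinh-scale SD per population (recycled
#'   if a single value).
#' @param expected_peaks expected number of density peaks (used as the
#'   bandwidth-search prior); default: number of distinct modes.
#' @return object of class `sim_marker`.
#' @export
sim_marker <- function(name, modes, sds, expected_peaks = NULL) {
  if (length(sds) == 1) sds <- stats::setNames(rep(sds, length(modes)),
                                               names(modes))
  stopifnot(length(sds) == length(modes), all(sds > 0))
  if (is.null(expected_peaks)) expected_peaks <- length(unique(modes))
  structure(list(name = name, modes = modes, sds = sds,
                 expected_peaks = expected_peaks), class = "sim_marker")
}

#' Simulation specification: populations, batches and markers
#'
#' The stated world of the generator: batch-specific cell-type composition
#' plus batch-specific location shifts and scale factors applied to every
#' marker (the technical effect to be removed), with cell populations drawn
#' once per cell and shared across markers.
#'
#' @param proportions batches x populations matrix of mixing proportions;
#'   rows must sum to 1. Dimnames give batch and population names.
#' @param markers list of [sim_marker()] objects (each covering every
#'   population).
#' @param batch_shift named numeric: additive arcsinh-scale shift per batch.
#' @param batch_scale named numeric: SD scale factor per batch.
#' @param cofactor arcsinh cofactor used to invert values to counts.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(proportions, markers, batch_shift = NULL,
                     batch_scale = NULL, cofactor = 5) {
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions)))
    rownames(proportions) <- paste0("batch", seq_len(nrow(proportions)))
  if (any(proportions < 0) ||
      any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("proportions must be non-negative and sum to 1 per batch")
  pops <- colnames(proportions)
  if (is.null(pops)) stop("proportions needs population column names")
  names(markers) <- vapply(markers, `[[`, character(1), "name")
  for (m in markers) {
    if (!setequal(names(m$modes), pops))
      stop("marker '", m$name, "' does not cover every population")
    if (any(diff(sort(unique(m$modes))) <= 0))
      stop("marker modes must be distinct where they differ")
  }
  bn <- rownames(proportions)
  if (is.null(batch_shift)) batch_shift <- stats::setNames(rep(0, length(bn)), bn)
  if (is.null(batch_scale)) batch_scale <- stats::setNames(rep(1, length(bn)), bn)
  structure(list(proportions = proportions, markers = markers,
                 batch_shift = batch_shift[bn], batch_scale = batch_scale[bn],
                 cofactor = cofactor), class = "sim_spec")
}

#' Default synthetic fixture specification
#'
#' 3 batches of PBMC-like cells (B, CD4 T, CD8 T, monocytes) with 4 markers:
#' CD3-like bimodal, CD4-like trimodal, CD19-like bimodal and an IgG1-like
#' unimodal isotype control. Batch shifts up to +/- 0.8 arcsinh units and
#' scale factors 0.9-1.1 emulate study-level technical variation.
#'
#' @param n_batches number of batches (1-3 supported; default 3).
#' @return a [sim_spec()].
#' @export
default_sim_spec <- function(n_batches = 3) {
  stopifnot(n_batches >= 1, n_batches <= 3)
  props <- rbind(batch1 = c(B = 0.12, CD4T = 0.33, CD8T = 0.22, Mono = 0.33),
                 batch2 = c(B = 0.15, CD4T = 0.30, CD8T = 0.25, Mono = 0.30),
                 batch3 = c(B = 0.10, CD4T = 0.35, CD8T = 0.20, Mono = 0.35))
  props <- props[seq_len(n_batches), , drop = FALSE]
  # background modes ~1.3-1.5 arcsinh (roughly 10 counts at cofactor 5), the
  # typical ADT background level; positives at 3.2-3.7 (~100-200 counts)
  markers <- list(
    sim_marker("CD3", c(B = 1.4, CD4T = 3.4, CD8T = 3.4, Mono = 1.4),
               c(B = 0.25, CD4T = 0.35, CD8T = 0.35, Mono = 0.25)),
    sim_marker("CD4", c(B = 1.3, CD4T = 3.7, CD8T = 1.3, Mono = 2.5),
               c(B = 0.22, CD4T = 0.30, CD8T = 0.22, Mono = 0.25)),
    sim_marker("CD19", c(B = 3.2, CD4T = 1.3, CD8T = 1.3, Mono = 1.3),
               c(B = 0.30, CD4T = 0.25, CD8T = 0.25, Mono = 0.25)),
    sim_marker("IgG1", c(B = 1.5, CD4T = 1.5, CD8T = 1.5, Mono = 1.5), 0.3))
  sim_spec(props, markers,
           batch_shift = c(batch1 = 0, batch2 = 0.8, batch3 = -0.5)[
             seq_len(n_batches)],
           batch_scale = c(batch1 = 1, batch2 = 1.1, batch3 = 0.9)[
             seq_len(n_batches)])
}

#' Recommended analysis configuration for a simulation spec
#'
#' Carries the per-marker expected peak counts into the bandwidth-search
#' prior, and the (batch, marker) pairs whose composition leaves no
#' background population into the single-positive-peak prior — the knowledge
#' an analyst of such a dataset would supply (e.g. CD3 in a T-cell-only
#' batch).
#'
#' @param spec a [sim_spec()].
#' @param ... further arguments to [adt_config()].
#' @return an [adt_config()].
#' @export
config_for_spec <- function(spec, ...) {
  prior <- vapply(spec$markers, `[[`, numeric(1), "expected_peaks")
  adt_config(arcsinh_cofactor = spec$cofactor, peak_count_prior = prior,
             positive_peak_only = positive_only_pairs(spec), ...)
}

#' (batch, marker) pairs where only a positive population is present
#'
#' A pair qualifies when the populations present in the batch all share one
#' marker mode that lies strictly above the marker's background (minimum)
#' mode, so a single positive peak is expected.
#'
#' @param spec a [sim_spec()].
#' @return data frame with columns `batch`, `marker` (zero rows if none).
#' @export
positive_only_pairs <- function(spec) {
  out <- list()
  for (b in rownames(spec$proportions)) {
    present <- colnames(spec$proportions)[spec$proportions[b, ] > 0]
    for (m in spec$markers) {
      pm <- unique(m$modes[present])
      if (length(pm) == 1 && pm > min(m$modes))
        out[[length(out) + 1]] <- data.frame(batch = b, marker = m$name)
    }
  }
  if (length(out) == 0)
    data.frame(batch = character(0), marker = character(0))
  else do.call(rbind, out)
}

# analytic landmark truth of a Gaussian mixture: local maxima/minima of the
# mixture density on a fine grid
mixture_landmarks <- function(means, sds, weights, n_grid = 4001) {
  keep <- weights > 0
  means <- means[keep]; sds <- sds[keep]; weights <- weights[keep]
  lo <- min(means - 4 * sds); hi <- max(means + 4 * sds)
  g <- seq(lo, hi, length.out = n_grid)
  d <- rowSums(vapply(seq_along(means), function(k)
    weights[k] * stats::dnorm(g, means[k], sds[k]), numeric(n_grid)))
  dd <- diff(d)
  peaks <- which(c(FALSE, dd > 0) & c(dd < 0, FALSE))
  vals <- which(c(FALSE, dd < 0) & c(dd > 0, FALSE))
  list(peaks = g[peaks], valleys = g[vals])
}

#' Simulate an ADT dataset with exact landmark ground truth
#'
#' Per cell: a population is drawn from its batch's proportions; per marker
#' the arcsinh value is Normal(mode + batch shift, SD x batch scale); counts
#' are recovered by inverting the arcsinh and rounding to the nearest
#' non-negative integer (the rounding noise reproduces the near-zero
#' discreteness of real ADT counts). Fully reproducible by seed.
#'
#' @param spec a [sim_spec()].
#' @param n_cells cells per batch (scalar or per-batch vector).
#' @param seed RNG seed.
#' @param discretize round to integer counts (default). `FALSE` keeps
#'   continuous pseudo-counts, isolating properties of the registration
#'   machinery from count-discreteness artifacts.
#' @return list with `dataset` (an [adt_dataset()] with batches attached) and
#'   `truth` (class `sim_truth`): `landmarks` (long data frame of analytic
#'   mixture peaks/valleys per marker x batch), `population` (per-cell
#'   labels), `components` (per marker x batch x population mixture table).
#' @export
simulate_dataset <- function(spec, n_cells = 2000, seed = 1,
                             discretize = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  batches <- rownames(spec$proportions)
  pops <- colnames(spec$proportions)
  n_cells <- rep(n_cells, length.out = length(batches))
  set.seed(seed)
  pop_all <- character(0); batch_all <- character(0)
  counts <- NULL
  for (bi in seq_along(batches)) {
    b <- batches[bi]
    pop <- sample(pops, n_cells[bi], replace = TRUE,
                  prob = spec$proportions[b, ])
    y <- vapply(spec$markers, function(m) {
      stats::rnorm(n_cells[bi],
                   m$modes[pop] + spec$batch_shift[b],
                   m$sds[pop] * spec$batch_scale[b])
    }, numeric(n_cells[bi]))
    cnt <- sinh(y) * spec$cofactor
    if (discretize) cnt <- round(cnt)
    cnt[cnt < 0] <- 0
    counts <- rbind(counts, cnt)
    pop_all <- c(pop_all, pop)
    batch_all <- c(batch_all, rep(b, n_cells[bi]))
  }
  colnames(counts) <- names(spec$markers)
  rownames(counts) <- paste0(batch_all, "_c", seq_along(batch_all))
  ds <- adt_dataset(counts, batch = batch_all)
  lm_rows <- list(); comp_rows <- list()
  for (m in spec$markers) for (b in batches) {
    w <- spec$proportions[b, ]
    mu <- m$modes + spec$batch_shift[b]
    sd <- m$sds * spec$batch_scale[b]
    truth <- mixture_landmarks(mu, sd, w)
    lm_rows[[length(lm_rows) + 1]] <- rbind(
      if (length(truth$peaks) > 0)
        data.frame(marker = m$name, batch = b, type = "peak",
                   location = truth$peaks),
      if (length(truth$valleys) > 0)
        data.frame(marker = m$name, batch = b, type = "valley",
                   location = truth$valleys))
    comp_rows[[length(comp_rows) + 1]] <- data.frame(
      marker = m$name, batch = b, population = pops, mode = unname(mu[pops]),
      sd = unname(sd[pops]), weight = unname(w[pops]))
  }
  truth <- structure(list(landmarks = do.call(rbind, lm_rows),
                          population = pop_all,
                          components = do.call(rbind, comp_rows)),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Imbalanced cell-type composition scenarios
#'
#' Restricts the composition of some batches to emulate increasingly skewed
#' designs: `mild` keeps everything except the last batch, which is
#' restricted to the T lineage; `moderate` restricts the last two batches to
#' the T lineage; `severe` additionally restricts the last batch to the CD8 T
#' sub-population alone. Lineage-restricted batches lose e.g. the CD19-positive
#' population entirely, the stress case for alignment.
#'
#' @param spec a [sim_spec()] with at least 2 populations and 2 batches.
#' @param scenario one of `"mild"`, `"moderate"`, `"severe"`.
#' @param lineage population names forming the restricted lineage.
#' @param sub_population single population used by the severe scenario.
#' @return a modified [sim_spec()]; generate data with [simulate_dataset()].
#' @export
simulate_imbalance <- function(spec, scenario = c("mild", "moderate", "severe"),
                               lineage = c("CD4T", "CD8T"),
                               sub_population = "CD8T") {
  scenario <- match.arg(scenario)
  props <- spec$proportions
  stopifnot(nrow(props) >= 2, all(lineage %in% colnames(props)),
            sub_population %in% colnames(props))
  restrict <- function(row, keep) {
    out <- row * 0
    out[keep] <- row[keep] / sum(row[keep])
    out
  }
  nb <- nrow(props)
  if (scenario == "mild") {
    props[nb, ] <- restrict(props[nb, ], lineage)
  } else if (scenario == "moderate") {
    for (b in (nb - 1):nb) props[b, ] <- restrict(props[b, ], lineage)
  } else {
    props[nb - 1, ] <- restrict(props[nb - 1, ], lineage)
    props[nb, ] <- restrict(props[nb, ], sub_population)
  }
  spec$proportions <- props
  spec
}

#' Antibody titration series
#'
#' Generates one batch per concentration level (relative to the recommended
#' 1x). Lower concentrations shrink the separation between the background
#' mode and each positive mode (multiplier `level^sep_exponent`) and broaden
#' the positive populations (SD multiplier `level^sd_exponent`), both
#' monotone in concentration by construction. Levels at or below
#' `min_detectable` lose the positive population(s) entirely, emulating a
#' stain too dilute to label any cell. Batch shifts/scales are not applied:
#' differences between levels are the titration effect alone.
#'
#' Diluting the antibody also leaves a growing share of truly-positive cells
#' effectively unstained: the fraction of positive cells still labeled scales
#' as `level^detect_exponent`, the rest fall back to the background
#' population.
#'
#' @param spec a [sim_spec()]; its first batch's composition is reused for
#'   every level.
#' @param levels concentration multipliers, increasing (default
#'   `c(1/25, 1/5, 1, 2)`).
#' @param n_cells cells per level.
#' @param seed RNG seed.
#' @param sep_exponent,sd_exponent,detect_exponent titration response
#'   exponents.
#' @param min_detectable concentration at or below which positive populations
#'   drop out entirely (`NULL` = never).
#' @return list with `dataset`, `truth` (as [simulate_dataset()]) and
#'   `levels` (named by the generated batch labels).
#' @export
simulate_titration <- function(spec, levels = c(1 / 25, 1 / 5, 1, 2),
                               n_cells = 2000, seed = 1,
                               sep_exponent = 0.15, sd_exponent = -0.05,
                               detect_exponent = 0.25,
                               min_detectable = 1 / 20) {
  stopifnot(all(levels > 0), !is.unsorted(levels))
  base_prop <- spec$proportions[1, , drop = TRUE]
  lev_names <- paste0("conc_", vapply(levels, function(l)
    format(signif(l, 3)), character(1)), "x")
  props <- NULL
  datasets <- list()
  all_counts <- NULL; all_batch <- character(0); all_pop <- character(0)
  lm_rows <- list(); comp_rows <- list()
  set.seed(seed)
  for (li in seq_along(levels)) {
    lev <- levels[li]
    mk2 <- lapply(spec$markers, function(m) {
      neg <- min(m$modes)
      modes <- neg + (m$modes - neg) * lev^sep_exponent
      sds <- ifelse(m$modes > neg, m$sds * lev^sd_exponent, m$sds)
      sim_marker(m$name, stats::setNames(modes, names(m$modes)),
                 stats::setNames(sds, names(m$sds)), m$expected_peaks)
    })
    w <- base_prop
    # undetected positive cells read as background: shift their weight to
    # the population with the lowest overall signal
    detect <- min(1, lev^detect_exponent)
    if (detect < 1) {
      total_mode <- vapply(names(w), function(p) sum(
        vapply(spec$markers, function(m) m$modes[[p]], numeric(1))),
        numeric(1))
      bg <- names(which.min(total_mode))
      pos_pops <- setdiff(names(w)[total_mode > min(total_mode)], bg)
      lost <- sum(w[pos_pops]) * (1 - detect)
      w[pos_pops] <- w[pos_pops] * detect
      w[bg] <- w[bg] + lost
    }
    if (!is.null(min_detectable) && lev <= min_detectable) {
      # positive cells fail to stain: every population collapses to background
      mk2 <- lapply(mk2, function(m) {
        m$modes[] <- min(m$modes)
        m$expected_peaks <- 1L
        m
      })
    }
    pop <- sample(names(w), n_cells, replace = TRUE, prob = w)
    y <- vapply(mk2, function(m)
      stats::rnorm(n_cells, m$modes[pop], m$sds[pop]), numeric(n_cells))
    cnt <- round(sinh(y) * spec$cofactor)
    cnt[cnt < 0] <- 0
    all_counts <- rbind(all_counts, cnt)
    all_batch <- c(all_batch, rep(lev_names[li], n_cells))
    all_pop <- c(all_pop, pop)
    for (m in mk2) {
      truth <- mixture_landmarks(m$modes, m$sds, w)
      lm_rows[[length(lm_rows) + 1]] <- rbind(
        data.frame(marker = m$name, batch = lev_names[li], type = "peak",
                   location = truth$peaks),
        if (length(truth$valleys) > 0)
          data.frame(marker = m$name, batch = lev_names[li], type = "valley",
                     location = truth$valleys))
    }
  }
  colnames(all_counts) <- names(spec$markers)
  rownames(all_counts) <- paste0(all_batch, "_c", seq_along(all_batch))
  ds <- adt_dataset(all_counts, batch = all_batch)
  ds$batch <- factor(ds$batch, levels = lev_names)  # keep titration order
  truth <- structure(list(landmarks = do.call(rbind, lm_rows),
                          population = all_pop, components = NULL),
                     class = "sim_truth")
  list(dataset = ds, truth = truth,
       levels = stats::setNames(levels, lev_names))
}
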