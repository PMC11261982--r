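# Shared fixtures built in code. Deterministic "quantile" samples (equally
# spaced probability points pushed through component quantile functions) give
# smooth, seed-free densities where sampling noise would cloud an oracle.

quantile_mixture <- function(n, means, sds, weights) {
  weights <- weights / sum(weights)
  unlist(lapply(seq_along(means), function(k) {
    nk <- max(2, round(n * weights[k]))
    stats::qnorm(stats::ppoints(nk), means[k], sds[k])
  }))
}

# analytic density_curve for tests that need an exact curve, not a KDE
analytic_curve <- function(grid, means, sds, weights) {
  weights <- weights / sum(weights)
  d <- rowSums(vapply(seq_along(means), function(k)
    weights[k] * stats::dnorm(grid, means[k], sds[k]), numeric(length(grid))))
  d <- d / sum(diff(grid) * (head(d, -1) + tail(d, -1)) / 2)
  structure(list(grid = grid, density = d, bandwidth_used = NA_real_,
                 n_cells = NA_integer_), class = "density_curve")
}

# 3-population B / CD4 T / CD8 T world with >= 6 SD peak separation,
# exercised by the gating tests
gating_sim_spec <- function() {
  props <- rbind(batch1 = c(B = 0.25, CD4T = 0.45, CD8T = 0.30),
                 batch2 = c(B = 0.30, CD4T = 0.40, CD8T = 0.30),
                 batch3 = c(B = 0.20, CD4T = 0.50, CD8T = 0.30))
  markers <- list(
    sim_marker("CD3", c(B = 1.4, CD4T = 3.5, CD8T = 3.5),
               c(B = 0.25, CD4T = 0.30, CD8T = 0.30)),
    sim_marker("CD4", c(B = 1.3, CD4T = 3.7, CD8T = 1.3),
               c(B = 0.22, CD4T = 0.30, CD8T = 0.22)),
    sim_marker("CD19", c(B = 3.3, CD4T = 1.3, CD8T = 1.3),
               c(B = 0.30, CD4T = 0.25, CD8T = 0.25)))
  sim_spec(props, markers,
           batch_shift = c(batch1 = 0, batch2 = 0.6, batch3 = -0.4),
           batch_scale = c(batch1 = 1, batch2 = 1.05, batch3 = 0.95))
}

pbmc_gating_rules <- function() {
  gating_rules(data.frame(
    cell_type = c("B", "T", "T", "CD4T", "CD8T"),
    parent = c(NA, NA, NA, "T", "T"),
    marker = c("CD19", "CD3", "CD19", "CD4", "CD4"),
    relation = c("above_valley", "above_valley", "below_valley",
                 "above_valley", "below_valley"),
    valley = 1L, stringsAsFactors = FALSE))
}

# one-marker bimodal world used by the titration tests
titration_sim_spec <- function() {
  props <- rbind(s1 = c(neg = 0.55, pos = 0.45))
  markers <- list(sim_marker("CD86", c(neg = 1.4, pos = 3.4),
                             c(neg = 0.25, pos = 0.35)))
  sim_spec(props, markers)
}

# max |post-normalization peak - target| over all peak slots of all batches
max_peak_target_dev <- function(norm) {
  post <- norm$landmarks_post
  worst <- 0
  for (mk in names(norm$targets)) {
    tg <- norm$targets[[mk]]
    p <- post[post$marker == mk & post$landmark_type != "valley", ]
    key <- ifelse(p$landmark_type == "neg_peak", "neg_peak",
                  paste0("pos_peak_", p$index))
    dev <- abs(p$location - tg[key])
    worst <- max(worst, dev, na.rm = TRUE)
  }
  worst
}

# rank preservation check: per marker x batch, average ranks identical
ranks_preserved <- function(norm) {
  ds <- norm$dataset
  for (mk in colnames(norm$values)) {
    raw <- arcsinh_transform(ds$counts[, mk], norm$config$arcsinh_cofactor)
    for (b in levels(ds$batch)) {
      sel <- ds$batch == b
      if (all(is.na(raw[sel]))) next
      if (!identical(rank(raw[sel], ties.method = "average"),
                     rank(norm$values[sel, mk], ties.method = "average")))
        return(FALSE)
    }
  }
  TRUE
}
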