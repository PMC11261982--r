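make_ls <- function(peaks, valleys = NULL) {
  landmark_set(data.frame(location = peaks, height = 1),
               if (is.null(valleys)) empty_df() else
                 data.frame(location = valleys, height = 0.1))
}
empty_df <- function() data.frame(location = numeric(0), height = numeric(0))

test_that("landmark slots harmonize across batches of unequal peak counts", {
  lms <- list(
    b1 = make_ls(c(1, 3.5), 2.2),          # bimodal
    b2 = make_ls(c(0.9, 2.3, 3.6), c(1.6, 3.0)))  # trimodal
  hm <- harmonize_landmark_counts(lms)
  expect_equal(hm$slot_names, c("neg_peak", "valley_1", "pos_peak_1",
                                "valley_2", "pos_peak_2"))
  # bimodal batch: rightmost peak in the rightmost slot, middle slots NA
  expect_equal(unname(hm$locations["b1", ]), c(1, NA, NA, 2.2, 3.5))
  expect_equal(unname(hm$locations["b2", ]), c(0.9, 1.6, 2.3, 3.0, 3.6))

  # all bimodal: 3 slots, no NA
  hm2 <- harmonize_landmark_counts(list(b1 = make_ls(c(1, 3), 2),
                                        b2 = make_ls(c(1.2, 3.2), 2.1)))
  expect_equal(ncol(hm2$locations), 3L)
  expect_false(anyNA(hm2$locations))

  # positive-only batch: sole peak fills pos_peak_1, neg slot stays NA
  hm3 <- harmonize_landmark_counts(
    list(b1 = make_ls(c(1, 3), 2), b2 = make_ls(3.1, 2.4)),
    positive_only = c(b1 = FALSE, b2 = TRUE))
  expect_equal(unname(hm3$locations["b2", ]), c(NA, 2.4, 3.1))
  # without the prior the sole peak is the negative peak
  hm4 <- harmonize_landmark_counts(
    list(b1 = make_ls(c(1, 3), 2), b2 = make_ls(1.1, 1.8)))
  expect_equal(unname(hm4$locations["b2", ]), c(1.1, 1.8, NA))
})

test_that("targets are per-slot means excluding outliers, or user-given", {
  loc <- rbind(b1 = c(1.0, 2.0, 3.0), b2 = c(2.0, 2.4, 3.4))
  colnames(loc) <- c("neg_peak", "valley_1", "pos_peak_1")
  tg <- compute_targets(loc)
  expect_equal(unname(tg$targets), c(1.5, 2.2, 3.2))
  expect_equal(tg$source, "mean-of-batches")
  # user targets returned verbatim
  tg_u <- compute_targets(loc, user_targets = c(0.5, 1.5, 3.0))
  expect_equal(unname(tg_u$targets), c(0.5, 1.5, 3.0))
  expect_error(compute_targets(loc, user_targets = c(2, 1.5, 3)),
               "increasing")
  # outlier-flagged values are excluded from the mean
  loc3 <- rbind(loc, b3 = c(1.2, 2.2, 9.0))
  out <- matrix(FALSE, 3, 3); out[3, 3] <- TRUE
  tg_o <- compute_targets(loc3, out)
  expect_equal(unname(tg_o$targets[3]), mean(c(3.0, 3.4)))
})

test_that("warps pin landmarks, fix endpoints and invert exactly", {
  # already aligned: identity within 1e-8 everywhere
  w_id <- fit_warp(c(1.5, 3), c(1.5, 3), 0, 6)
  g <- seq(0, 6, length.out = 1001)
  expect_lt(max(abs(predict(w_id, g) - g)), 1e-8)

  # single landmark: h(2) = 3, inverse recovers 2, strictly increasing
  w <- fit_warp(3, 2, 0, 6)
  expect_equal(predict(w, 2), 3, tolerance = 1e-10)
  expect_equal(predict(w, 3, inverse = TRUE), 2, tolerance = 1e-8)
  hv <- predict(w, g)
  expect_true(all(diff(hv) > 0))
  expect_identical(predict(w, 0), 0)
  expect_identical(predict(w, 6), 6)
  # piecewise-linear monotone oracle through the same knots
  pl <- approx(c(0, 2, 6), c(0, 3, 6), xout = g)$y
  expect_lt(max(abs(hv - pl)), 0.02)

  expect_error(fit_warp(c(3, 2), c(1, 2), 0, 6), "increasing")
  expect_error(fit_warp(7, 2, 0, 6), "inside")
})

test_that("normalize_values applies the inverse warp and preserves ranks", {
  w_id <- fit_warp(numeric(0), numeric(0), 0, 6)
  x <- c(0, 0.5, 2, 2, 5.9)
  expect_equal(normalize_values(x, w_id), x)
  w <- fit_warp(3, 2, 0, 6)
  expect_equal(normalize_values(3, w), 2, tolerance = 1e-8)
  set.seed(4)
  v <- runif(500, 0, 6)
  out <- normalize_values(v, w)
  expect_identical(order(v), order(out))
  expect_identical(rank(c(v, v)), rank(c(out, out)))  # ties preserved
})

test_that("run_normalization aligns peaks of shifted batches", {
  # batch 2 is exactly batch 1 shifted by +0.3 on the arcsinh scale, so after
  # normalization the re-detected peaks must coincide to within the grid
  y1 <- quantile_mixture(3000, c(1.4, 3.4), c(0.25, 0.35), c(0.6, 0.4))
  cnt <- matrix(round(sinh(c(y1, y1 + 0.3)) * 5), ncol = 1,
                dimnames = list(NULL, "CD8"))
  cnt[cnt < 0] <- 0
  ds <- adt_dataset(cnt, batch = rep(c("b1", "b2"), each = length(y1)))
  norm <- run_normalization(ds, adt_config(peak_count_prior = c(CD8 = 2)))
  post <- norm$landmarks_post
  grid_step <- (norm$warps$CD8$b1$t_end - norm$warps$CD8$b1$t_start) /
    (adt_config()$grid_size - 1)
  for (type in c("neg_peak", "pos_peak")) {
    locs <- post$location[post$landmark_type == type]
    expect_equal(length(locs), 2L)
    expect_lte(abs(diff(locs)), 2 * grid_step)
  }
  expect_true(ranks_preserved(norm))
})

test_that("a single batch is normalized to its own landmarks", {
  spec <- default_sim_spec(n_batches = 1)
  sim <- simulate_dataset(spec, n_cells = 1500, seed = 17)
  norm <- run_normalization(sim$dataset, config_for_spec(spec))
  # mean of one batch is the batch itself: warps stay near identity
  for (mk in names(norm$warps)) {
    w <- norm$warps[[mk]][[1]]
    g <- seq(w$t_start, w$t_end, length.out = 500)
    expect_lt(max(abs(predict(w, g) - g)), 1e-8)
  }
  expect_equal(sum(is.na(norm$values)), 0L)
})

test_that("fixed targets integrate separate runs without joint processing", {
  spec <- default_sim_spec()
  cfg <- config_for_spec(spec)
  sim1 <- simulate_dataset(spec, n_cells = 2000, seed = 51)
  sim2 <- simulate_dataset(spec, n_cells = 2000, seed = 52)
  ref <- run_normalization(sim1$dataset, cfg)
  tg <- lapply(ref$targets, function(v) unname(v[!is.na(v)]))
  n1 <- run_normalization(sim1$dataset, cfg, target_landmarks = tg)
  n2 <- run_normalization(sim2$dataset, cfg, target_landmarks = tg)
  for (mk in names(tg)) {
    expect_equal(unname(n1$targets[[mk]][!is.na(n1$targets[[mk]])]), tg[[mk]])
    expect_equal(unname(n2$targets[[mk]][!is.na(n2$targets[[mk]])]), tg[[mk]])
  }
  # both runs land their peaks on the shared targets; re-detection around
  # single-pinned populations carries up to ~0.1 of warp-kink bias (vignette)
  expect_lt(max_peak_target_dev(n1), 0.15)
  expect_lt(max_peak_target_dev(n2), 0.15)
})

test_that("markers missing in a batch are skipped, not zeroed", {
  spec <- default_sim_spec()
  sim <- simulate_dataset(spec, n_cells = 800, seed = 19)
  ds <- sim$dataset
  ds$counts[ds$batch == "batch2", "CD19"] <- NA  # CD19 not profiled in batch2
  norm <- run_normalization(ds, config_for_spec(spec))
  expect_true(all(is.na(norm$values[ds$batch == "batch2", "CD19"])))
  expect_false(anyNA(norm$values[ds$batch != "batch2", "CD19"]))
  expect_null(norm$warps$CD19$batch2)
  expect_length(norm$warps$CD19, 2L)
  avail <- marker_availability(ds)
  expect_false(avail["batch2", "CD19"])
  expect_true(all(avail[, "CD3"]))
})

test_that("normalization is approximately idempotent", {
  # well-pinned bimodal world; single-pin markers under large shifts carry a
  # larger re-detection bias at the warp kink (see the methods vignette)
  spec <- sim_spec(rbind(b1 = c(neg = 0.6, pos = 0.4),
                         b2 = c(neg = 0.6, pos = 0.4)),
                   list(sim_marker("CD8", c(neg = 1.4, pos = 3.4),
                                   c(neg = 0.25, pos = 0.35))),
                   batch_shift = c(b1 = 0, b2 = 0.8))
  cfg <- config_for_spec(spec)
  for (seed in c(7, 23)) {
    sim <- simulate_dataset(spec, n_cells = 4000, seed = seed)
    n1 <- run_normalization(sim$dataset, cfg)
    # feed the normalized values back as (non-integer) counts
    cnt2 <- sinh(n1$values) * cfg$arcsinh_cofactor
    ds2 <- adt_dataset(cnt2, batch = n1$dataset$batch)
    n2 <- run_normalization(ds2, cfg)
    for (w in n2$warps$CD8) {
      g <- seq(w$t_start, w$t_end, length.out = 400)
      expect_lt(max(abs(predict(w, g) - g)), 0.05)
    }
  }
})

test_that("landmark overrides replace detected locations", {
  spec <- default_sim_spec()
  sim <- simulate_dataset(spec, n_cells = 1000, seed = 29)
  cfg <- config_for_spec(spec)
  base <- run_normalization(sim$dataset, cfg)
  pre <- base$landmarks_pre
  row <- pre[pre$marker == "CD3" & pre$batch == "batch1" &
             pre$landmark_type == "pos_peak", ][1, ]
  ov <- data.frame(marker = "CD3", batch = "batch1",
                   landmark_type = "pos_peak", index = row$index,
                   location = row$location + 0.3)
  norm <- run_normalization(sim$dataset, cfg, landmark_override = ov)
  pre2 <- norm$landmarks_pre
  moved <- pre2[pre2$marker == "CD3" & pre2$batch == "batch1" &
                pre2$landmark_type == "pos_peak", ][1, ]
  expect_equal(moved$location, row$location + 0.3)
  expect_equal(moved$provenance, "override")
})
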