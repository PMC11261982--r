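# build a peak_summary directly (bypassing detection) for formula tests
mk_summary <- function(modes, heights, sds, aucs, valley_h,
                       valley_loc = NULL, auc_tail = 0, sd_all = 1) {
  structure(list(
    peaks = data.frame(mode = modes, height = heights, sd = sds, auc = aucs),
    valleys = data.frame(
      location = if (is.null(valley_loc))
        (modes[-1] + modes[-length(modes)]) / 2 else valley_loc,
      height = valley_h),
    auc_right_tail = auc_tail, sd_all = sd_all,
    n_peaks = length(modes)), class = "peak_summary")
}

test_that("peak summaries recompute from cells and conserve area", {
  set.seed(41)
  y <- c(rnorm(1200, 1.4, 0.25), rnorm(800, 3.4, 0.35))
  grid <- seq(0, 5, length.out = 512)
  det <- detect_landmarks(y, grid, adt_config())
  sm <- summarize_peaks(det$curve, det$landmarks, y)
  expect_equal(sm$n_peaks, 2L)
  v <- det$landmarks$valleys$location[1]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  # SDs match a direct split of the cells at the valley
  expect_equal(sm$peaks$sd[1], pop_sd(y[y < v]), tolerance = 1e-12)
  expect_equal(sm$peaks$sd[2], pop_sd(y[y >= v]), tolerance = 1e-12)
  # the two peak intervals tile the support: AUCs sum to ~1
  expect_equal(sum(sm$peaks$auc), 1, tolerance = 0.01)
  expect_equal(sm$auc_right_tail, sm$peaks$auc[2], tolerance = 1e-12)
  # a single peak spanning everything has AUC ~ 1
  y1 <- rnorm(1000, 1.5, 0.3)
  det1 <- detect_landmarks(y1, grid, adt_config(), peak_count_prior = 1)
  sm1 <- summarize_peaks(det1$curve, det1$landmarks, y1)
  expect_gt(sm1$peaks$auc[1], 0.9)
})

test_that("stain index follows its formula", {
  sm <- mk_summary(c(1, 4), c(1, 0.5), c(0.3, 0.3), c(0.5, 0.5), 0.05)
  expect_equal(stain_index(sm), 5)
  # zero numerator
  sm0 <- mk_summary(c(2, 2 + 1e-15), c(1, 1), c(0.3, 0.3), c(0.5, 0.5), 0)
  expect_equal(stain_index(sm0), 0, tolerance = 1e-10)
  # doubling SD(neg) halves the index
  sm2 <- mk_summary(c(1, 4), c(1, 0.5), c(0.6, 0.3), c(0.5, 0.5), 0.05)
  expect_equal(stain_index(sm2), stain_index(sm) / 2)
  expect_error(stain_index(mk_summary(c(1, 4), c(1, 1), c(0, 0.3),
                                      c(0.5, 0.5), 0)), "SD")
})

test_that("stain quality scores match independent formula evaluation", {
  # printed 2-peak case
  sm <- mk_summary(c(1, 4), c(1, 0.5), c(0.3, 0.3), c(0.4, 0.5), 0.05)
  expect_equal(stain_quality_score(sm), 5 * 1.45 * 1.5, tolerance = 1e-12)
  expect_equal(stain_quality_score(sm), 10.875)
  # independent oracle over randomized summaries, all three cases
  set.seed(43)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    modes <- sort(runif(n, 0.5, 5))
    heights <- runif(n, 0.2, 1.2)
    sds <- runif(n, 0.1, 0.6)
    aucs <- runif(n, 0.05, 0.5)
    vh <- runif(max(n - 1, 1), 0.01, 0.15)
    vloc <- if (n == 1) modes + runif(1, 0.3, 1)
    tail_auc <- runif(1, 0, 0.4)
    sd_all <- runif(1, 0.3, 1.2)
    sm_i <- mk_summary(modes, heights, sds, aucs, vh, vloc, tail_auc, sd_all)
    oracle <- if (n >= 3) {
      (modes[n] - modes[1]) / sum(sds) *
        (heights[n] - vh[n - 1] + 1) * (sum(aucs[-1]) + 1)
    } else if (n == 2) {
      (modes[2] - modes[1]) / (sds[1] + sds[2]) *
        (heights[2] - vh[1] + 1) * (aucs[2] + 1)
    } else {
      (vloc - modes) / sd_all * (0 - vh[1] + 1) * (tail_auc + 1)
    }
    expect_equal(stain_quality_score(sm_i), oracle, tolerance = 1e-9)
  }
})

test_that("scores are monotone in separation and spread", {
  base <- function(sep, sds) {
    sm <- mk_summary(c(1, 1 + sep), c(1, 0.5), sds, c(0.4, 0.5), 0.05)
    stain_quality_score(sm)
  }
  seps <- seq(0.5, 3, by = 0.5)
  expect_true(all(diff(vapply(seps, base, numeric(1),
                              sds = c(0.3, 0.3))) > 0))
  spreads <- seq(0.2, 0.8, by = 0.1)
  expect_true(all(diff(vapply(spreads, function(s) base(2, c(s, s)),
                              numeric(1))) < 0))
})

test_that("score ordering holds on the constructed density family", {
  grid <- seq(0, 6, length.out = 512)
  cfg <- adt_config()
  score_of <- function(y, prior = NULL) {
    det <- detect_landmarks(y, grid, cfg, peak_count_prior = prior)
    sm <- summarize_peaks(det$curve, det$landmarks, y)
    list(score = stain_quality_score(sm), n_peaks = sm$n_peaks)
  }
  n <- 3000
  two_peaks <- quantile_mixture(n, c(1.4, 3.4), c(0.25, 0.35), c(0.55, 0.45))
  shoulder <- quantile_mixture(n, c(1.4, 2.1), c(0.25, 0.55), c(0.7, 0.3))
  heavy_tail <- c(quantile_mixture(round(0.85 * n), 1.4, 0.25, 1),
                  1.6 + stats::qexp(stats::ppoints(round(0.15 * n)), 1.2))
  no_tail <- quantile_mixture(n, 1.4, 0.25, 1)
  s2 <- score_of(two_peaks)
  s_sh <- score_of(shoulder, prior = 1)
  s_ht <- score_of(heavy_tail, prior = 1)
  s_nt <- score_of(no_tail, prior = 1)
  expect_equal(s2$n_peaks, 2L)
  expect_equal(s_sh$n_peaks, 1L)
  expect_equal(s_ht$n_peaks, 1L)
  expect_equal(s_nt$n_peaks, 1L)
  expect_gt(s2$score, s_sh$score)
  expect_gt(s_sh$score, s_ht$score)
  expect_gt(s_ht$score, s_nt$score)
})

test_that("scores are stable under 50% subsampling", {
  set.seed(47)
  y <- c(rnorm(2400, 1.4, 0.25), rnorm(1600, 3.4, 0.35))
  grid <- seq(0, 5.5, length.out = 512)
  cfg <- adt_config()
  sc <- function(v) {
    det <- detect_landmarks(v, grid, cfg)
    stain_quality_score(summarize_peaks(det$curve, det$landmarks, v))
  }
  full <- sc(y)
  half <- sc(sample(y, length(y) / 2))
  expect_lt(abs(half - full) / full, 0.05)
})

test_that("quality_report covers all batches and flags below threshold", {
  spec <- default_sim_spec()
  sim <- simulate_dataset(spec, n_cells = 1200, seed = 61)
  cfg <- config_for_spec(spec)
  qr <- quality_report(sim$dataset, cfg)
  expect_equal(nrow(qr$table), 4 * 3)  # one row per marker x batch
  expect_setequal(unique(qr$table$marker), marker_names(sim$dataset))
  # IgG1 (isotype control, unimodal) must score below the bimodal markers
  expect_lt(mean(qr$table$score[qr$table$marker == "IgG1"]),
            mean(qr$table$score[qr$table$marker == "CD3"]))
  # the flag set is monotone in the threshold
  f5 <- qr$table$score < 5
  f8 <- qr$table$score < 8
  expect_true(all(f8[f5]))
  cfg8 <- config_for_spec(spec, quality_threshold = 8)
  qr8 <- quality_report(sim$dataset, cfg8)
  expect_true(all(qr8$table$flagged[qr$table$flagged]))
})
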