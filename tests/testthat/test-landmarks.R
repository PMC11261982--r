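test_that("peaks are found at analytic modes with deterministic tie-breaks", {
  grid <- seq(0, 6, length.out = 601)
  cv <- analytic_curve(grid, c(1, 4), c(0.2, 0.3), c(0.5, 0.5))
  pk <- detect_peaks(cv)
  # oracle: brute-force local argmax over the analytic grid
  d <- cv$density
  oracle <- which(d > c(-Inf, d[-601]) & d >= c(d[-1], -Inf))
  expect_equal(pk$index, oracle[d[oracle] >= 0.01 * max(d)])
  step <- grid[2] - grid[1]
  expect_lt(abs(pk$location[1] - 1), step + 1e-9)
  expect_lt(abs(pk$location[2] - 4), step + 1e-9)

  # monotone decreasing curve: boundary mode at the left edge only
  mono <- structure(list(grid = grid, density = rev(sort(dexp(grid))),
                         bandwidth_used = 1, n_cells = 10L),
                    class = "density_curve")
  pk_m <- detect_peaks(mono)
  expect_equal(nrow(pk_m), 1L)
  expect_equal(pk_m$index, 1L)

  # plateau of equal maximal values: leftmost grid point wins
  dens <- dnorm(grid, 3, 0.5)
  dens[grid >= 2.8 & grid <= 3.2] <- max(dens)
  plat <- structure(list(grid = grid, density = dens, bandwidth_used = 1,
                         n_cells = 10L), class = "density_curve")
  pk_p <- detect_peaks(plat)
  expect_equal(nrow(pk_p), 1L)
  expect_equal(pk_p$location, min(grid[grid >= 2.8 & grid <= 3.2]))
})

test_that("valleys sit at inter-peak minima or derive from the slope", {
  grid <- seq(0, 6, length.out = 601)
  cv <- analytic_curve(grid, c(1, 4), c(0.2, 0.3), c(0.5, 0.5))
  pk <- detect_peaks(cv)
  vl <- detect_valleys(cv, pk)
  # brute-force min between the two modes
  span <- which(grid > pk$location[1] & grid < pk$location[2])
  expect_equal(vl$index, span[which.min(cv$density[span])])
  expect_gt(vl$location, 1); expect_lt(vl$location, 4)

  # three peaks -> exactly two interleaved valleys
  cv3 <- analytic_curve(grid, c(1, 2.5, 4), c(0.2, 0.2, 0.25), c(1, 1, 1))
  pk3 <- detect_peaks(cv3)
  expect_equal(nrow(pk3), 3L)
  vl3 <- detect_valleys(cv3, pk3)
  expect_equal(nrow(vl3), 2L)
  ord <- order(c(pk3$location, vl3$location))
  expect_equal(rep(c("P", "V"), c(3, 2))[ord], c("P", "V", "P", "V", "P"))

  # single peak: slope-derived valley lies right of the peak
  cv1 <- analytic_curve(grid, 1.2, 0.4, 1)
  pk1 <- detect_peaks(cv1)
  expect_equal(nrow(pk1), 1L)
  vl1 <- detect_valleys(cv1, pk1)
  expect_equal(vl1$provenance, "slope-derived")
  expect_gt(vl1$location, pk1$location)
})

test_that("near-zero peak merging keeps the tallest candidate", {
  ls <- landmark_set(
    data.frame(location = c(0.1, 0.4, 3.0), height = c(0.8, 1.2, 1.0)),
    data.frame(location = c(0.25, 1.5), height = c(0.5, 0.1)))
  out <- merge_low_peaks(ls, neg_candidate_thres = 0.5)
  expect_equal(out$peaks$location, c(0.4, 3.0))
  expect_equal(out$valleys$location, 1.5)
  expect_equal(out$peaks$provenance[1], "merged")
  # no peaks below threshold: identity
  expect_identical(merge_low_peaks(ls, 0.05)$peaks$location, ls$peaks$location)
  # all peaks below threshold: single peak, no valleys
  all_low <- merge_low_peaks(ls, 10)
  expect_equal(nrow(all_low$peaks), 1L)
  expect_equal(all_low$peaks$location, 0.4)
  expect_equal(nrow(all_low$valleys), 0L)
})

test_that("spurious empty-droplet peaks are dropped, sole peaks never", {
  ls <- landmark_set(
    data.frame(location = c(0.05, 0.9), height = c(0.1, 1.0)),
    data.frame(location = 0.4, height = 0.05))
  out <- drop_spurious_zero_peak(ls, neg_candidate_thres = 0.5)
  expect_equal(out$peaks$location, 0.9)
  expect_equal(nrow(out$valleys), 0L)
  # leftmost peak that is the tallest is not "minor": kept
  tall <- landmark_set(
    data.frame(location = c(0.05, 0.9), height = c(1.0, 0.4)),
    data.frame(location = 0.4, height = 0.05))
  expect_equal(nrow(drop_spurious_zero_peak(tall, 0.5)$peaks), 2L)
  # a sole peak is never deleted
  solo <- landmark_set(data.frame(location = 0.05, height = 0.1))
  expect_equal(nrow(drop_spurious_zero_peak(solo, 0.5)$peaks), 1L)
})

test_that("MAD outlier flagging matches a brute-force oracle", {
  flags <- flag_outlier_positive_peaks(c(0.9, 1.0, 1.1, 5.0), 3)
  expect_equal(flags, c(FALSE, FALSE, FALSE, TRUE))
  # hand computation with the 1.4826 consistency constant
  x <- c(0.9, 1.0, 1.1, 5.0)
  s <- 1.4826 * median(abs(x - median(x)))
  expect_equal(s, 0.14826, tolerance = 1e-9)
  expect_gt(abs(5 - median(x)) / s, 26)
  expect_equal(flag_outlier_positive_peaks(rep(2, 5)), rep(FALSE, 5))
  expect_equal(flag_outlier_positive_peaks(c(1, 9)), c(FALSE, FALSE))
  # property: agreement with an independent oracle on random vectors
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(sample(3:12, 1), 2, 0.5)
    if (runif(1) < 0.5) v[1] <- v[1] + 10
    med <- median(v); sc <- 1.4826 * median(abs(v - med))
    oracle <- if (sc > 0) abs(v - med) / sc > 3 else abs(v - med) > 0
    expect_identical(flag_outlier_positive_peaks(v, 3), oracle)
  }
})

test_that("EMD equals the area between CDFs", {
  grid <- seq(0, 2, length.out = 401)
  a <- analytic_curve(grid, 0.5, 0.1, 1)
  expect_equal(compute_emd_matrix(list(a = a, b = a))["a", "b"], 0)
  # near point masses at 0 and 1 are distance ~1 apart
  pm <- function(at) {
    d <- numeric(401); i <- which.min(abs(grid - at))
    d[i] <- 1 / (grid[2] - grid[1])
    structure(list(grid = grid, density = d, bandwidth_used = 1,
                   n_cells = 1L), class = "density_curve")
  }
  emd <- compute_emd_matrix(list(zero = pm(0), one = pm(1)))
  expect_equal(emd["zero", "one"], 1, tolerance = 2 * (grid[2] - grid[1]))
  # symmetry + zero diagonal on random discrete curves
  set.seed(8)
  curves <- lapply(1:4, function(i) {
    d <- runif(401); d <- d / sum(diff(grid) * (head(d, -1) + tail(d, -1)) / 2)
    structure(list(grid = grid, density = d, bandwidth_used = 1,
                   n_cells = 10L), class = "density_curve")
  })
  names(curves) <- paste0("b", 1:4)
  m <- compute_emd_matrix(curves)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 4), paste0("b", 1:4)))
  bad <- curves
  bad[[1]]$grid <- bad[[1]]$grid + 1
  expect_error(compute_emd_matrix(bad), "grid")
})

test_that("outlier valleys are imputed from EMD-nearest batches", {
  vm <- matrix(c(2.0, 2.1, 2.05, 6.0), ncol = 1,
               dimnames = list(paste0("b", 1:4), "valley_1"))
  emd <- matrix(c(0, 1, 2, 4,
                  1, 0, 1, 5,
                  2, 1, 0, 6,
                  4, 5, 6, 0), 4, 4, byrow = TRUE,
                dimnames = list(paste0("b", 1:4), paste0("b", 1:4)))
  out <- impute_outlier_valleys(vm, emd, 3, k_neighbors = 2)
  # b4 flagged; its two nearest clean neighbors are b1 (4) and b2 (5)
  expect_equal(out$locations["b4", 1], mean(c(2.0, 2.1)))
  expect_true(out$imputed["b4", 1])
  expect_equal(out$locations[1:3, 1], vm[1:3, 1])
  # nothing flagged: identity
  vm2 <- vm; vm2[4, 1] <- 2.02
  out2 <- impute_outlier_valleys(vm2, emd, 3, 2)
  expect_equal(out2$locations, vm2)
  expect_false(any(out2$imputed))
  # two batches: insufficient support, no imputation
  out3 <- impute_outlier_valleys(vm[1:2, , drop = FALSE],
                                 emd[1:2, 1:2], 3, 2)
  expect_equal(out3$locations, vm[1:2, , drop = FALSE])
})

test_that("the single-positive-peak prior relabels and mirrors the valley", {
  grid <- seq(0, 6, length.out = 601)
  cv <- analytic_curve(grid, 3.2, 0.4, 1)
  pk <- detect_peaks(cv)
  ls <- landmark_set(pk, detect_valleys(cv, pk))
  out <- apply_positive_peak_prior(ls, TRUE, cv)
  expect_equal(out$peaks$label, "positive")
  expect_lt(out$valleys$location, out$peaks$location)  # mirrored to the left
  # without the prior a single peak is background
  def <- apply_positive_peak_prior(ls, FALSE, cv)
  expect_equal(def$peaks$label, "negative")
  # two peaks with the prior: warning, rightmost treated positive
  cv2 <- analytic_curve(grid, c(1, 4), c(0.2, 0.3), c(0.5, 0.5))
  pk2 <- detect_peaks(cv2)
  ls2 <- landmark_set(pk2, detect_valleys(cv2, pk2))
  expect_warning(out2 <- apply_positive_peak_prior(ls2, TRUE, cv2),
                 "rightmost")
  expect_equal(out2$peaks$label, c("negative", "positive"))
})

test_that("interleaving survives randomized cleanup sequences", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    locs <- sort(runif(2 * k - 1, 0, 6))
    pk <- data.frame(location = locs[seq(1, 2 * k - 1, 2)],
                     height = runif(k, 0.1, 1.5))
    vl <- data.frame(location = locs[seq(2, 2 * k - 2, 2)],
                     height = runif(k - 1, 0.01, 0.09))
    ls <- landmark_set(pk, vl)
    ls <- drop_spurious_zero_peak(ls, runif(1, 0, 3), runif(1, 0.2, 0.8))
    ls <- merge_low_peaks(ls, runif(1, 0, 4))
    locs2 <- c(ls$peaks$location, ls$valleys$location)
    type <- rep(c("P", "V"), c(nrow(ls$peaks), nrow(ls$valleys)))
    type <- type[order(locs2)]
    expect_false(any(type[-1] == type[-length(type)]))
    expect_gte(nrow(ls$peaks), 1L)
  }
})
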