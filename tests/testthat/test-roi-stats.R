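# Independent textbook Welch formula used as the oracle.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = pt(t, df, lower.tail = FALSE))
}

# Volume filled with given values at given linear indices of an atlas ROI.
fill_roi <- function(atlas, assignments, background = 0) {
  vol <- array(background, dim(atlas$labels))
  for (nm in names(assignments)) {
    idx <- roi_voxel_indices(atlas, nm, include_children = FALSE)
    vol[idx] <- assignments[[nm]]
  }
  vol
}

test_that("erosion by a spherical element matches brute-force set logic", {
  cube <- array(FALSE, c(7, 7, 7))
  cube[2:6, 2:6, 2:6] <- TRUE # solid 5^3 cube
  er <- erode_mask(cube, 1, c(1, 1, 1))
  # brute force: voxel survives iff all voxels within radius 1 are in mask
  oracle <- array(FALSE, c(7, 7, 7))
  for (x in 1:7) for (y in 1:7) for (z in 1:7) {
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (sqrt(dx^2 + dy^2 + dz^2) > 1) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1 | p > 7) || !cube[p[1], p[2], p[3]]) ok <- FALSE
    }
    oracle[x, y, z] <- ok
  }
  expect_identical(er, oracle)
  expect_equal(sum(er), 27) # 3^3 interior survives

  # radius 0 is the identity
  expect_identical(erode_mask(cube, 0), cube)

  # single voxel vanishes with a warning
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_warning(er1 <- erode_mask(single, 1), "empty")
  expect_false(any(er1))
})

test_that("eroding touching masks separates them", {
  # two touching slabs: after 1-voxel erosion each recedes by 1, leaving a
  # gap of at least 2 voxels (the intent of pulling adjacent nuclei apart)
  a <- array(FALSE, c(10, 5, 5)); a[1:5, , ] <- TRUE
  b <- array(FALSE, c(10, 5, 5)); b[6:10, , ] <- TRUE
  ea <- erode_mask(a, 1); eb <- erode_mask(b, 1)
  expect_false(any(ea & eb))
  xa <- max(which(apply(ea, 1, any)))
  xb <- min(which(apply(eb, 1, any)))
  expect_gte(xb - xa, 2)
})

test_that("probability-map thresholding reports mask and percentile", {
  pm <- array(0, c(5, 2, 1))
  pm[cbind(1:5, 1, 1)] <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  pm[cbind(1:5, 2, 1)] <- c(0.06, 0.07, 0.08, 0.09, 0.10)
  res <- threshold_probability_map(pm, 0.03)
  expect_equal(sum(res$mask), 7) # strictly above 0.03
  expect_equal(res$percentile, 30) # 3 of 10 nonzero values <= threshold

  uni <- array(0.5, c(3, 3, 3))
  expect_equal(sum(threshold_probability_map(uni, 0.03)$mask), 27)
  expect_equal(sum(threshold_probability_map(uni, 1.0)$mask), 0)
  expect_error(threshold_probability_map(array(0, c(2, 2, 2)), 0.5), "support")
  expect_error(threshold_probability_map(array(2, c(2, 2, 2)), 0.5), "\\[0, 1\\]")
})

test_that("roi_values extracts labeled voxels and accounts for the partition", {
  at <- nested_atlas()
  vol <- array(0, dim(at$labels))
  idx <- roi_voxel_indices(at, "roi")
  vol[idx] <- seq_along(idx)
  expect_equal(sort(roi_values(vol, at, "roi")), as.numeric(seq_along(idx)))

  # ROI fully outside the map support -> error
  nanvol <- array(NaN, dim(at$labels))
  expect_error(roi_values(nanvol, at, "roi"), "support")

  # partition accounting: ROI voxels + background = all voxels
  n_roi <- length(roi_voxel_indices(at, "region")) # includes child "roi"
  n_bg <- sum(at$labels == 0)
  expect_equal(n_roi + n_bg, length(at$labels))
})

test_that("ROI-vs-region Welch test matches the textbook formula", {
  at <- nested_atlas()
  idx_roi <- roi_voxel_indices(at, "roi", include_children = FALSE)
  idx_reg <- roi_voxel_indices(at, "region", include_children = FALSE)

  # degenerate zero-variance ROI from the printed toy values
  vol <- array(NaN, dim(at$labels))
  vol[idx_roi] <- 2 # ROI: all 2s (7 voxels)
  vol[idx_reg] <- rep(c(2, 0), length.out = length(idx_reg))
  res <- roi_vs_region_ttest(vol, at, "roi", "region")
  orc <- welch_oracle(vol[idx_roi], vol[sort(c(idx_roi, idx_reg))])
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_equal(res$df, orc$df, tolerance = 1e-10)

  # ROI and region means exactly equal (small integers): t = 0, p = 0.5
  vol2 <- array(NaN, dim(at$labels))
  mean2 <- function(n) {
    v <- rep(c(1, 3), length.out = n)
    if (n %% 2 == 1) v[n] <- 2
    v
  }
  vol2[idx_roi] <- mean2(length(idx_roi))
  vol2[idx_reg] <- mean2(length(idx_reg))
  res2 <- roi_vs_region_ttest(vol2, at, "roi", "region")
  expect_equal(res2$t, 0, tolerance = 1e-12)
  expect_equal(res2$p, 0.5, tolerance = 1e-12)

  # ROI not contained in region -> error
  at2 <- generate_toy_atlas(c(9, 5, 5), list(
    list(name = "a", center = c(3, 3, 3), radius = 1),
    list(name = "b", center = c(7, 3, 3), radius = 1)
  ))
  volx <- array(1, dim(at2$labels))
  expect_error(roi_vs_region_ttest(volx, at2, "a", "b"), "subset")
})

test_that("one-sided Welch null rejection rate is calibrated", {
  at <- nested_atlas()
  idx_roi <- roi_voxel_indices(at, "roi", include_children = FALSE)
  idx_reg <- roi_voxel_indices(at, "region", include_children = FALSE)
  set.seed(41)
  reps <- 2000
  rej_disjoint <- 0
  rej_included <- 0
  vol <- array(NaN, dim(at$labels))
  for (i in seq_len(reps)) {
    vol[c(idx_roi, idx_reg)] <- rnorm(length(idx_roi) + length(idx_reg))
    if (roi_vs_region_ttest(vol, at, "roi", "region",
                            exclude_roi = TRUE)$p < 0.05) {
      rej_disjoint <- rej_disjoint + 1
    }
    if (roi_vs_region_ttest(vol, at, "roi", "region")$p < 0.05) {
      rej_included <- rej_included + 1
    }
  }
  expect_lt(abs(rej_disjoint / reps - 0.05), 0.02)
  # with the ROI included in the region the samples overlap, which shrinks
  # the mean difference's variance: the default convention is conservative
  expect_lte(rej_included, rej_disjoint)
})

test_that("RFT correction bounds, limits and monotonicity", {
  p_raw <- 0.01
  t <- qt(1 - p_raw, df = 20)
  # zero-resel limit: corrected -> raw
  expect_equal(rft_correct(p_raw, t, 20, 1e-9, 10), p_raw, tolerance = 1e-6)
  # never below raw, monotone non-decreasing in resels
  vols <- 10^seq(0, 4, length.out = 20)
  pc <- vapply(vols, function(v) rft_correct(p_raw, t, 20, v, 2), numeric(1))
  expect_true(all(pc >= p_raw))
  expect_true(all(diff(pc) >= 0))
  expect_true(all(pc <= 1))
  expect_error(rft_correct(0.01, 2, -1, 10, 2), "df")
  expect_error(rft_correct(0.01, 2, 10, 10, 0), "fwhm")
})

test_that("summarize_rois builds the full table and flags effects", {
  at <- nested_atlas()
  pairs <- data.frame(roi = "roi", region = "region")
  set.seed(42)
  idx_roi <- roi_voxel_indices(at, "roi", include_children = FALSE)
  idx_reg <- roi_voxel_indices(at, "region", include_children = FALSE)

  # strong embedded effect -> significant at 0.05 after correction
  vol <- array(NaN, dim(at$labels))
  vol[idx_reg] <- rnorm(length(idx_reg), 0, 0.1)
  vol[idx_roi] <- rnorm(length(idx_roi), 1, 0.1)
  tab <- summarize_rois(vol, at, pairs, fwhm = 2)
  expect_equal(nrow(tab), 1)
  expect_true(tab$significant_at_0.05)
  expect_gte(tab$p_corrected, tab$p_raw)

  # all-zero map: nothing significant (degenerate tests give NA rows)
  vz <- array(0, dim(at$labels))
  tz <- suppressWarnings(summarize_rois(vz, at, pairs))
  expect_false(any(tz$significant_at_0.05))
  expect_false(any(tz$significant_at_0.001))

  # row count equals requested pairs; unknown names abort
  p2 <- data.frame(roi = c("roi", "roi"), region = c("region", "region"))
  expect_equal(nrow(suppressWarnings(summarize_rois(vol, at, p2))), 2)
  expect_error(summarize_rois(vol, at, data.frame(roi = "nope",
                                                  region = "region")),
               "unknown ROI name 'nope'")
})

test_that("atlas upsampling preserves labels at source centers", {
  at <- nested_atlas()
  up <- upsample_atlas(at, 2L)
  expect_equal(dim(up$labels), (dim(at$labels) - 1L) * 2L + 1L)
  expect_equal(up$voxel_size, at$voxel_size / 2)
  co <- which(at$labels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    expect_equal(up$labels[2 * co[r, 1] - 1, 2 * co[r, 2] - 1,
                           2 * co[r, 3] - 1],
                 at$labels[co[r, 1], co[r, 2], co[r, 3]])
  }
})
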