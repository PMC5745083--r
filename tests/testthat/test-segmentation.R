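# Unit tests for each stage of the counting chain, with generator ground
# truth as the oracle where one exists.

make_disk <- function(n = 101, r = 15, amp = 100) {
  ctr <- (n - 1) / 2
  d2 <- outer(seq_len(n) - 1 - ctr, seq_len(n) - 1 - ctr,
              function(y, x) y^2 + x^2)
  amp * (d2 <= r^2)
}

make_gaussian <- function(n = 61, sigma = 4, amp = 100,
                          cy = (n - 1) / 2, cx = (n - 1) / 2) {
  g <- outer(seq_len(n) - 1, seq_len(n) - 1, function(y, x) {
    exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
  })
  amp * g
}

test_that("homomorphic denoising flattens illumination, preserves flats", {
  const <- matrix(7, 40, 50)
  out <- homomorphic_denoise(const, 0.05, 1)
  expect_lt(diff(range(out)), 1e-8)
  # cutoff 0, sigma 0: exact identity
  img <- make_gaussian()
  expect_equal(homomorphic_denoise(img, 0, 0), img)
  # known multiplicative gradient: background CV strictly reduced
  field <- outer(seq_len(80) / 80, seq_len(80) / 80, function(u, v) {
    1 + 0.5 * (u - 0.5) + 0.3 * (v - 0.5)
  })
  biased <- 50 * field
  cv <- function(m) sd(m) / mean(m)
  flat <- homomorphic_denoise(biased, 0.03, 1)
  expect_lt(cv(flat), cv(biased) / 2)
  expect_error(homomorphic_denoise(matrix(c(1, NA), 2, 2)), "non-finite")
})

test_that("Canny finds a disk boundary enclosing roughly its area", {
  expect_error(detect_boundaries(make_disk(), 0.5, 0.2), "canny_low")
  blank <- matrix(0, 30, 30)
  expect_false(any(detect_boundaries(blank)))
  disk <- homomorphic_denoise(make_disk(n = 121, r = 25), 0, 1.5)
  edges <- detect_boundaries(disk, 0.08, 0.2)
  expect_true(any(edges))
  regions <- rough_segment(edges)
  expect_equal(length(regions), 1L)
  area <- nrow(regions[[1L]]$pixels)
  expect_lt(abs(area - pi * 25^2) / (pi * 25^2), 0.10)
})

test_that("convex-hull rough segmentation fills open contours", {
  # a C-shaped open contour: its hull covers the concavity
  edges <- matrix(FALSE, 40, 40)
  theta <- seq(pi / 3, 5 * pi / 3, length.out = 120)
  edges[cbind(round(20 + 10 * sin(theta)), round(20 + 10 * cos(theta)))] <- TRUE
  regions <- rough_segment(edges)
  expect_equal(length(regions), 1L)
  px <- regions[[1L]]$pixels
  # center of the C (inside the concavity) is inside the hull
  expect_true(any(px[, 1L] == 19L & px[, 2L] == 19L))
  expect_gt(nrow(px), sum(edges))
})

test_that("active contours shrink an oversized hull toward the spot", {
  spot <- make_gaussian(n = 41, sigma = 4, amp = 100) + 1
  box <- as.matrix(expand.grid(5:35, 5:35))
  reg <- list(list(pixels = box))
  expect_identical(refine_contours(reg, spot, 0L), reg)
  refined <- refine_contours(reg, spot, 10L)[[1L]]
  true_area <- sum(spot - 1 > 50) # FWHM-ish disk
  expect_lt(abs(nrow(refined$pixels) - true_area),
            abs(nrow(box) - true_area))
  # refinement never escapes the bounded dilation of its input
  expect_true(all(refined$pixels[, 1L] >= 3 & refined$pixels[, 1L] <= 37))
})

test_that("watershed splits touching spots and partitions the mask", {
  n <- 60
  two <- make_gaussian(n, 5, 100, cy = 29, cx = 20) +
    make_gaussian(n, 5, 100, cy = 29, cx = 40)
  img <- retina_image(two, matrix(0, n, n))
  mask_px <- which(two > 5, arr.ind = TRUE) - 1L
  regions <- list(list(pixels = mask_px))
  markers <- matrix(0L, n, n)
  markers[30, 21] <- 1L
  markers[30, 41] <- 2L
  lab <- watershed_partition(img, regions, markers = markers)
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), c(1L, 2L))
  expect_equal(lab[30, 21], 1L)
  expect_equal(lab[30, 41], 2L)
  # every masked pixel got exactly one label (partition property)
  expect_true(all(lab[mask_px + 1L] > 0))
  # single seed: single region
  markers1 <- matrix(0L, n, n)
  markers1[30, 21] <- 1L
  lab1 <- watershed_partition(img, regions, markers = markers1)
  expect_setequal(setdiff(unique(as.vector(lab1)), 0L), 1L)
  expect_warning(watershed_partition(img, list()), "no seed")
})

test_that("region filtering enforces area and center-distance rules", {
  lab <- matrix(0L, 50, 50)
  lab[25:26, 25:28] <- 1L       # area 8 at center
  lab[1:2, 1:2] <- 2L           # area 4, at the corner
  lab[40:49, 5:14] <- 3L        # area 100
  kept <- filter_regions(lab, min_area = 8, max_area = 500,
                         max_center_distance = 0.95)
  expect_true(all(kept[lab == 1L] == 1L))   # centroid at center: retained
  expect_true(all(kept[lab == 2L] == 0L))   # too small AND at the corner
  kept2 <- filter_regions(lab, min_area = 5, max_area = 99,
                          max_center_distance = 1)
  expect_true(all(kept2[lab == 3L] == 0L))  # above max_area
  # relaxing all bounds retains every region; filtering never adds any
  all_kept <- filter_regions(lab, 0, Inf, 1)
  expect_identical(all_kept, lab)
  expect_lte(length(setdiff(unique(as.vector(kept)), 0L)),
             length(setdiff(unique(as.vector(lab)), 0L)))
})

test_that("classification matches a brute-force per-pixel oracle", {
  set.seed(31)
  rh3 <- matrix(runif(900, 0, 100), 30, 30)
  rh4 <- matrix(runif(900, 0, 100), 30, 30)
  img <- retina_image(rh3, rh4)
  lab <- matrix(0L, 30, 30)
  lab[3:8, 3:8] <- 1L
  lab[15:20, 10:18] <- 2L
  regions <- classify_regions(lab, img, 99, 0.05)
  for (id in 1:2) {
    idx <- which(lab == id)
    expect_equal(regions$mean_rh3[regions$label == id], mean(rh3[idx]))
    expect_equal(regions$mean_rh4[regions$label == id], mean(rh4[idx]))
  }
  # region 1 bright only in rh4, region 2 bright only in rh3
  rh4b <- matrix(1, 30, 30); rh4b[3:8, 3:8] <- 80
  rh3b <- matrix(1, 30, 30); rh3b[15:20, 10:18] <- 70
  calls <- classify_regions(lab, retina_image(rh3b, rh4b), 99, 0.05)$call
  expect_equal(calls, c("RH4", "RH3"))
  # identical channels: every region is an exact tie -> AMBIGUOUS
  img3 <- retina_image(rh3, rh3)
  expect_true(all(classify_regions(lab, img3, 99, 0.05)$call == "AMBIGUOUS"))
  expect_error(classify_regions(lab, retina_image(matrix(0, 30, 30),
                                                  rh4b), 99, 0.05), "rh3")
})

test_that("end-to-end counting is deterministic and recovers ground truth", {
  gen <- generate_retina_image(sim_config(seed = 5, on_fraction = 0.65))
  a <- count_mosaic(gen$image)
  b <- count_mosaic(gen$image)
  expect_identical(a[c("n_rh3", "n_rh4", "n_ambiguous", "pct_on")],
                   b[c("n_rh3", "n_rh4", "n_ambiguous", "pct_on")])
  expect_lt(abs(a$pct_on - 100 * gen$truth$on_fraction_true), 3)
  expect_true(a$scorable)
  # all-OFF retina: %ON is exactly zero
  off <- generate_retina_image(sim_config(seed = 6, on_fraction = 0,
                                          n_rows = 11, n_cols = 10))
  mc <- count_mosaic(off$image)
  expect_equal(mc$pct_on, 0)
  expect_true(mc$n_rh3 + mc$n_rh4 >= 100) # scoring floor met by 110 spots
})

test_that("ROI means agree with a direct pixel-sum oracle", {
  const <- matrix(42, 30, 30)
  expect_equal(roi_mean_intensity(const, rbind(c(10, 10), c(20, 5)), 3),
               c(42, 42))
  spot <- make_gaussian(41, 4, 100) + 10
  v <- roi_mean_intensity(spot, rbind(c(20, 20)), 4)
  expect_gt(v, 10)
  expect_lt(v, 110)
  # two-spot ROI beats one-spot ROI at equal background
  two <- make_gaussian(61, 3, 100, cy = 30, cx = 25) +
    make_gaussian(61, 3, 100, cy = 30, cx = 35) + 5
  one_roi <- roi_mean_intensity(two, rbind(c(30, 25)), 3)
  big_roi <- roi_mean_intensity(two, rbind(c(30, 30)), 9)
  # oracle: direct masked mean
  d2 <- outer(0:60 - 30, 0:60 - 30, function(y, x) y^2 + x^2)
  expect_equal(big_roi, mean(two[d2 <= 81]))
  expect_error(roi_mean_intensity(const, rbind(c(500, 500)), 3), "outside")
  expect_error(roi_mean_intensity(const, rbind(c(10, 10)), 0), "radius")
})
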