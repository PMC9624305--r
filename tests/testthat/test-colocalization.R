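# Stiffness-actin overlap statistics.

toy_map <- function(stiff_px, size = 10) {
  m <- matrix(0.5, size, size)
  m[seq_len(stiff_px)] <- 2
  elasticity_map(m, 1)
}

test_that("identical, disjoint, and partial masks give 100, 0, and 80 percent", {
  m <- toy_map(10)
  act_same <- matrix(0, 10, 10); act_same[1:10] <- 1
  r <- overlap_fraction(m, act_same, actin_rule = "fraction", fraction = 0.5)
  expect_equal(r$overlap_percent, 100)
  act_disj <- matrix(0, 10, 10); act_disj[51:60] <- 1
  expect_equal(overlap_fraction(m, act_disj, actin_rule = "fraction",
                                fraction = 0.5)$overlap_percent, 0)
  # 10 stiff pixels, 8 inside the actin mask -> 80.0%
  act8 <- matrix(0, 10, 10); act8[1:8] <- 1; act8[51:60] <- 1
  r8 <- overlap_fraction(m, act8, actin_rule = "fraction", fraction = 0.5)
  expect_equal(r8$overlap_percent, 80)
  expect_equal(r8$joint_count, 8)
  expect_lte(r8$joint_count, min(r8$stiff_pixel_count, r8$actin_pixel_count))
})

test_that("overlap is invariant under identical crops of both grids", {
  p <- make_stiffness_actin_pair(seed = 3, size = 20)
  full <- overlap_fraction(p$map, p$actin)
  crop <- function(m) m[3:18, 3:18]
  cropped <- overlap_fraction(
    elasticity_map(crop(p$map$moduli_kpa), 1, crop(p$map$qc_mask)),
    crop(p$actin),
    actin_rule = "fraction", fraction = 0.5
  )
  full_f <- overlap_fraction(p$map, p$actin, actin_rule = "fraction",
                             fraction = 0.5)
  expect_equal(cropped$overlap_percent, full_f$overlap_percent)
})

test_that("raising the stiffness threshold never lets joint exceed stiff", {
  p <- make_stiffness_actin_pair(seed = 5)
  for (thr in c(0.8, 1, 1.5)) {
    r <- overlap_fraction(p$map, p$actin, e_threshold = thr)
    expect_lte(r$joint_count, r$stiff_pixel_count)
    expect_lte(r$overlap_percent, 100)
  }
  uniform_soft <- elasticity_map(matrix(0.3, 8, 8), 1)
  expect_error(overlap_fraction(uniform_soft, matrix(1, 8, 8)), "no stiff")
  expect_error(overlap_fraction(toy_map(5), matrix(0, 4, 4)), "resampled")
})

test_that("the calibrated jitter harness lands in the high-70s to mid-80s", {
  ov <- sapply(1:20, function(s) {
    p <- make_stiffness_actin_pair(seed = s)
    overlap_fraction(p$map, p$actin)$overlap_percent
  })
  # planted ideal-disk overlap is 81.9%; pixelation of the 16 x 16 grid
  # spreads individual draws by a few percent around it
  expect_gt(mean(ov), 78)
  expect_lt(mean(ov), 85)
  expect_true(all(ov > 74 & ov < 89))
})

test_that("Otsu thresholding separates a bimodal actin image like the truth mask", {
  p <- make_stiffness_actin_pair(seed = 7)
  r <- overlap_fraction(p$map, p$actin)  # otsu rule
  actin_mask <- p$actin >= r$intensity_threshold_value
  expect_gt(mean(actin_mask == p$truth$actin_mask), 0.97)
})
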