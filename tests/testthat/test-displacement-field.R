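# Bead detection, linking, outlier filtering, and grid interpolation.

test_that("a noiseless Gaussian spot is localized to better than 0.05 px", {
  img <- gaussian_spot_image(60, 60, 10.3, 20.7)
  det <- detect_beads(img, pixel_size = 1)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - (10.3 - 1)), 0.05)
  expect_lt(abs(det$y_um - (20.7 - 1)), 0.05)
})

test_that("flat images yield no detections and close pairs are suppressed", {
  expect_equal(nrow(detect_beads(matrix(7, 32, 32), 1)), 0)
  two <- gaussian_spot_image(40, 40, 20.2, 20.0) +
    gaussian_spot_image(40, 40, 22.2, 20.0, amp = 800)
  det <- detect_beads(two, pixel_size = 1, min_separation = 4)
  expect_equal(nrow(det), 1)
  expect_error(detect_beads(matrix(0, 8, 8), 1), "16 x 16")
})

test_that("detection count matches the planted count within 2% at SNR 10", {
  d0 <- displacement_field(matrix(0, 4, 4), matrix(0, 4, 4), 20)
  pr <- render_bead_pair(d0, bead_density = 0.15, seed = 9)
  det <- detect_beads(pr$reference, pr$pixel_size)
  expect_lt(abs(nrow(det) - nrow(pr$truth)) / nrow(pr$truth), 0.02)
})

test_that("matching links identical and rigidly shifted bead sets", {
  set.seed(1)
  pos <- data.frame(x_um = runif(60, 0, 50), y_um = runif(60, 0, 50))
  same <- match_beads(pos, pos, max_displacement = 1)
  expect_equal(nrow(same), 60)
  expect_equal(max(abs(c(same$ux_um, same$uy_um))), 0)
  shifted <- data.frame(x_um = pos$x_um + 0.3, y_um = pos$y_um - 0.2)
  mm <- match_beads(pos, shifted, max_displacement = 1)
  expect_equal(unname(colMeans(mm[, c("ux_um", "uy_um")])), c(0.3, -0.2),
               tolerance = 1e-12)
  # one bead displaced beyond the search radius drops out, others unaffected
  far <- shifted
  far$x_um[1] <- far$x_um[1] + 30
  mm2 <- match_beads(pos, far, max_displacement = 1)
  expect_equal(nrow(mm2), 59)
  expect_error(match_beads(pos, shifted, max_displacement = -1), "> 0")
})

test_that("rigid sub-pixel shifts are recovered to < 0.05 px at SNR 10", {
  px <- 0.25
  errs <- sapply(seq(0.1, 1.0, by = 0.1), function(shift) {
    tru <- displacement_field(matrix(shift * px, 2, 2),
                              matrix(-shift * px / 2, 2, 2), 50)
    pair <- render_bead_pair(tru, bead_density = 0.02, pixel_size = px,
                             photon_noise = TRUE, seed = round(shift * 100))
    ref <- detect_beads(pair$reference, px)
    lod <- detect_beads(pair$loaded, px)
    sp <- match_beads(ref, lod, max_displacement = 0.6)
    est <- c(mean(sp$ux_um), mean(sp$uy_um)) / px
    sqrt(sum((est - c(shift, -shift / 2))^2))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("the outlier filter removes gross mismatches and keeps smooth fields", {
  set.seed(3)
  n <- 80
  x <- runif(n, 0, 40); y <- runif(n, 0, 40)
  sp <- sparse_df(x, y, 0.01 * x, -0.005 * y + 0.002 * x)
  sp$ux_um[5] <- sp$ux_um[5] + 1.5  # gross mismatch
  out <- filter_vector_outliers(sp)
  expect_false("5" %in% rownames(out))
  expect_lte(attr(out, "n_rejected"), 3)  # the outlier plus at most stragglers
})

test_that("thin-plate gridding reproduces constant and affine fields exactly", {
  set.seed(4)
  x <- runif(40, 0, 30); y <- runif(40, 0, 30)
  const <- interpolate_to_grid(sparse_df(x, y, rep(0.4, 40), rep(-0.1, 40)),
                               grid_spacing = 2, extent = c(0, 30, 0, 30))
  expect_equal(max(abs(const$ux - 0.4)), 0, tolerance = 1e-8)
  expect_equal(max(abs(const$uy + 0.1)), 0, tolerance = 1e-8)
  lin <- interpolate_to_grid(sparse_df(x, y, 0.01 * x, 0.02 * y),
                             grid_spacing = 2, extent = c(0, 30, 0, 30))
  g <- expand.grid(y = seq(0, 30, 2), x = seq(0, 30, 2))
  expect_equal(as.vector(lin$ux), 0.01 * g$x, tolerance = 1e-8)
  expect_equal(as.vector(lin$uy), 0.02 * g$y, tolerance = 1e-8)
  expect_error(interpolate_to_grid(sparse_df(1:5, 2 * (1:5), 0, 0), 1),
               "collinear")
  expect_error(interpolate_to_grid(sparse_df(1:2, c(1, 3), 0, 0), 1),
               "at least 3")
})

test_that("gridded field approximates a forward-model field at default density", {
  sc <- make_scene(seed = 6, photon_noise = FALSE)
  tb <- sc$bead_pair$truth
  di <- interpolate_to_grid(sparse_df(tb$x_um, tb$y_um, tb$ux_um, tb$uy_um),
                            grid_spacing = 2, extent = c(0, 62, 0, 62))
  tru <- sc$truth_displacement
  err <- sqrt(mean((di$ux - tru$ux)^2 + (di$uy - tru$uy)^2)) /
    sqrt(mean(tru$ux^2 + tru$uy^2))
  expect_lt(err, 0.05)
  # end-to-end correlation including detection and linking
  rec <- recover_scene(sc)
  expect_gt(cor(as.vector(rec$displacement$ux), as.vector(tru$ux)), 0.95)
  expect_gt(cor(as.vector(rec$displacement$uy), as.vector(tru$uy)), 0.95)
})

test_that("drift correction removes a rigid offset using out-of-cell beads", {
  set.seed(8)
  x <- runif(120, 0, 60); y <- runif(120, 0, 60)
  sp <- sparse_df(x, y, rep(0.12, 120), rep(-0.07, 120))
  maskm <- matrix(FALSE, 31, 31)
  maskm[12:20, 12:20] <- TRUE
  mk <- cell_mask(maskm, 2)
  out <- correct_drift(sp, mk)
  expect_equal(max(abs(out$ux_um)), 0, tolerance = 1e-12)
  expect_equal(attr(out, "drift_um"), c(0.12, -0.07))
  expect_identical(correct_drift(sp, NULL), sp)
})
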