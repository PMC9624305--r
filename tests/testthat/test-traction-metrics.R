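# Force integration, contact areas, time series, stress-modulus pairing.

test_that("force integration is the definitional stress x area product", {
  # uniform 50 Pa over 150 um^2 -> 7.5 nN
  maskm <- matrix(FALSE, 20, 20)
  maskm[1:10, 1:15] <- TRUE  # 150 px
  mk <- cell_mask(maskm, grid_spacing = 1)
  tr <- traction_field(matrix(50, 20, 20), matrix(0, 20, 20), 1)
  s <- integrate_force(tr, mk)
  expect_equal(s$total_force_nn, 7.5)
  expect_equal(s$mean_stress_pa, 50)
  expect_equal(s$peak_stress_pa, 50)
  expect_equal(s$net_force_nn, c(7.5, 0))
  expect_equal(s$contact_area_um2, 150)
})

test_that("opposite patches cancel vectorially but not in magnitude", {
  tx <- matrix(0, 16, 16)
  tx[4:6, 4:6] <- 40
  tx[10:12, 10:12] <- -40
  tr <- traction_field(tx, matrix(0, 16, 16), 1)
  mk <- cell_mask(matrix(TRUE, 16, 16), 1)
  s <- integrate_force(tr, mk)
  expect_equal(s$net_force_nn, c(0, 0), tolerance = 1e-12)
  expect_gt(s$total_force_nn, 0)
  z <- integrate_force(traction_field(matrix(0, 16, 16),
                                      matrix(0, 16, 16), 1), mk)
  expect_equal(z$total_force_nn, 0)
  expect_equal(z$mean_stress_pa, 0)
})

test_that("unit conversion: 1 Pa over 10^6 um^2 is exactly 1 uN", {
  expect_identical(pa_um2_to_nn, 1e-3)
  mk <- cell_mask(matrix(TRUE, 1000, 1000), grid_spacing = 1)
  tr <- traction_field(matrix(1, 1000, 1000), matrix(0, 1000, 1000), 1)
  expect_equal(integrate_force(tr, mk)$total_force_nn, 1e3)
})

test_that("contact area counts pixels times pixel area", {
  m <- matrix(FALSE, 16, 16); m[1:10, 1:10] <- TRUE
  expect_equal(contact_area(cell_mask(m, 1)), 100)
  expect_equal(contact_area(cell_mask(matrix(TRUE, 16, 16), 1)), 256)
  expect_equal(contact_area(cell_mask(m, 0.5)), 0.25 * 100)
  expect_error(contact_area(cell_mask(matrix(FALSE, 4, 4), 1)), "empty")
})

test_that("force is additive over disjoint masks and monotone in area", {
  set.seed(5)
  tx <- matrix(abs(rnorm(256, 20, 5)), 16, 16)
  tr <- traction_field(tx, matrix(0, 16, 16), 1)
  m1 <- matrix(FALSE, 16, 16); m1[1:8, ] <- TRUE
  m2 <- matrix(FALSE, 16, 16); m2[9:16, ] <- TRUE
  f1 <- integrate_force(tr, cell_mask(m1, 1))$total_force_nn
  f2 <- integrate_force(tr, cell_mask(m2, 1))$total_force_nn
  fu <- integrate_force(tr, cell_mask(m1 | m2, 1))$total_force_nn
  expect_equal(fu, f1 + f2)
  # constant stress: force strictly increasing in contact area
  trc <- traction_field(matrix(30, 16, 16), matrix(0, 16, 16), 1)
  areas <- c(20, 60, 120, 200)
  forces <- sapply(areas, function(a) {
    m <- matrix(FALSE, 16, 16); m[seq_len(a)] <- TRUE
    integrate_force(trc, cell_mask(m, 1))$total_force_nn
  })
  expect_true(all(diff(forces) > 0))
  expect_error(integrate_force(tr, cell_mask(matrix(FALSE, 16, 16), 1)),
               "empty")
  expect_error(integrate_force(tr, cell_mask(matrix(TRUE, 4, 4), 1)),
               "shape")
})

make_summary <- function(stress, t, label = "c") {
  mk <- cell_mask(matrix(TRUE, 4, 4), 1, label = label)
  tr <- traction_field(matrix(stress, 4, 4), matrix(0, 4, 4), 1)
  integrate_force(tr, mk, time_min = t)
}

test_that("time-series summaries report trace statistics and classification", {
  const <- lapply(seq(0, 120, 10), function(t) make_summary(30, t))
  ts1 <- summarize_time_series(const)
  expect_equal(ts1$stats$mean, 30)
  expect_equal(ts1$stats$sem, 0)
  expect_equal(ts1$classification, "quiescent-like")
  # alternating 28/70 Pa trace spans the reported growing-neuron range
  alt <- lapply(seq_along(seq(0, 120, 10)), function(i) {
    make_summary(if (i %% 2) 28 else 70, (i - 1) * 10)
  })
  ts2 <- summarize_time_series(alt)
  expect_equal(ts2$stats$min, 28)
  expect_equal(ts2$stats$max, 70)
  expect_equal(ts2$classification, "growing-like")
  single <- summarize_time_series(list(make_summary(42, 0)))
  expect_equal(single$stats$mean, 42)
  expect_equal(single$stats$sem, 0)
  expect_false(single$stats$sem_defined)
  expect_error(summarize_time_series(rev(alt)), "increasing")
})

test_that("stress-modulus pairing joins by label and keeps planted trends", {
  s <- make_summary(50, 0, label = "cellA")
  m <- elasticity_map(matrix(1, 8, 8), 1)
  tab <- pair_stress_modulus(list(s), list(cellA = m))
  expect_equal(tab$mean_stress_Pa, 50)
  expect_equal(tab$mean_modulus_kPa, 1)
  expect_equal(tab$cell, "cellA")
  expect_error(pair_stress_modulus(list(s), list(other = m)), "cellA")
  expect_equal(nrow(pair_stress_modulus(list(), list())), 0)
  # planted positive stiffness-stress coupling survives the join (n = 10)
  co <- make_cohort(cohort_spec(n_cells = 10, seed = 2), render = "none")
  sums <- lapply(co$cells, function(cl) make_summary(cl$mean_stress_pa, 0,
                                                     label = cl$label))
  maps <- setNames(
    lapply(co$cells, function(cl) elasticity_map(matrix(cl$modulus_kpa, 4, 4), 1)),
    sapply(co$cells, function(cl) cl$label)
  )
  tab2 <- pair_stress_modulus(sums, maps)
  expect_gt(cor(tab2$mean_stress_Pa, tab2$mean_modulus_kPa,
                method = "spearman"), 0.9)
})
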