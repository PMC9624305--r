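# Ground-truth generators: determinism, construction invariants,
# parameterization.

test_that("traction patterns respect site count, stress range, and balance", {
  z <- make_traction_pattern(n_sites = 0, seed = 1)
  expect_equal(max(abs(z$tx)), 0)
  tr <- make_traction_pattern(n_sites = 6, stress_range = c(30, 70),
                              balanced = TRUE, seed = 2)
  peaks <- attr(tr, "site_peaks")
  expect_true(all(peaks >= 30 & peaks <= 70))
  peak <- max(field_magnitude(tr))
  expect_lt(sqrt(mean(tr$tx)^2 + mean(tr$ty)^2), 1e-12 * peak)
  expect_error(make_traction_pattern(site_radius = -1), "> 0")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(make_scene(seed = 42), make_scene(seed = 42))
  expect_identical(simulate_force_curve(470, noise_frac = 0.05, seed = 3),
                   simulate_force_curve(470, noise_frac = 0.05, seed = 3))
  s1 <- cohort_spec(n_cells = 3, seed = 9)
  expect_identical(make_cohort(s1, render = "none"),
                   make_cohort(s1, render = "none"))
})

test_that("scene truth displacement is the forward model of its traction", {
  sc <- make_scene(seed = 13)
  expect_identical(sc$truth_displacement,
                   forward_displacement(sc$truth_traction, sc$substrate))
  # mean-stress rescaling hits its target exactly
  sc50 <- make_scene(seed = 13, mean_stress_pa = 50)
  expect_equal(sc50$truth_summary$mean_stress_pa, 50, tolerance = 1e-9)
})

test_that("bead rendering plants the advertised density with a hard core", {
  d0 <- displacement_field(matrix(0, 6, 6), matrix(0, 6, 6), 20)  # 100 um
  pr <- render_bead_pair(d0, bead_density = 0.02, margin = 0, seed = 21)
  # 0.02/um^2 over 100x100 um: 200 +/- Poisson fluctuation
  expect_lt(abs(nrow(pr$truth) - 200), 4 * sqrt(200))
  dmat <- as.matrix(dist(pr$truth[, c("x_um", "y_um")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 1)
})

test_that("zero displacement gives identical frames; rigid shift moves every bead", {
  d0 <- displacement_field(matrix(0, 4, 4), matrix(0, 4, 4), 20)
  pr <- render_bead_pair(d0, seed = 5)
  expect_identical(pr$reference, pr$loaded)
  dsh <- displacement_field(matrix(0.4, 4, 4), matrix(-0.2, 4, 4), 20)
  prs <- render_bead_pair(dsh, seed = 5)
  expect_equal(max(abs(prs$truth$ux_um - 0.4)), 0, tolerance = 1e-9)
  expect_equal(max(abs(prs$truth$uy_um + 0.2)), 0, tolerance = 1e-9)
  expect_warning(render_bead_pair(d0, psf_sigma = 0.05, seed = 1),
                 "undersampled")
})

test_that("simulated force curves are flat before contact and exact after", {
  cv <- simulate_force_curve(470, contact_z = 2, noise_frac = 0)
  pre <- cv$z_piezo < 2
  expect_equal(max(abs(cv$deflection_force[pre])), 0)
  expect_lt(abs(fit_hertz_cone(cv)$young_modulus_pa - 470), 0.5)
  expect_error(simulate_force_curve(470, noise_frac = -0.1), ">= 0")
})

test_that("cohorts encode growth dynamics, coupling, and the time grid", {
  qspec <- cohort_spec(n_cells = 8, growth_fraction = 0, seed = 4)
  qco <- make_cohort(qspec, render = "none")
  for (cl in qco$cells) {
    expect_false(cl$growing)
    expect_equal(nrow(cl$trace), 13)  # 0-120 min every 10 min
    expect_lt(diff(range(cl$trace$stress_pa)), 15)  # constant within noise
  }
  gspec <- cohort_spec(n_cells = 8, growth_fraction = 1, seed = 4)
  gco <- make_cohort(gspec, render = "none")
  ranges <- sapply(gco$cells, function(cl) diff(range(cl$trace$stress_pa)))
  expect_true(all(ranges > 15))  # high/low alternation
  # modulus coupling: E = base + slope * mean stress (+ small jitter)
  ms <- sapply(gco$cells, `[[`, "mean_stress_pa")
  ek <- sapply(gco$cells, `[[`, "modulus_kpa")
  expect_lt(max(abs(ek - (0.4 + 0.025 * ms))), 0.25)
  # rendered scene inherits the cell's area and stress
  rco <- make_cohort(cohort_spec(n_cells = 2, seed = 6), render = "first")
  sc <- rco$cells[[1]]$scenes[[1]]
  expect_s3_class(sc, "synthetic_scene")
  expect_equal(sc$truth_summary$mean_stress_pa,
               rco$cells[[1]]$trace$stress_pa[1], tolerance = 1e-9)
})
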