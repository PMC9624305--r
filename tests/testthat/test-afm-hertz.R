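# Hertz conical-tip fitting: contact detection, modulus recovery, maps.

test_that("noise-free curves return the generating modulus and contact point", {
  for (e in c(470, 1000)) {
    cv <- simulate_force_curve(young_modulus_pa = e, contact_z = 2,
                               noise_frac = 0)
    fit <- fit_hertz_cone(cv)
    expect_true(fit$converged)
    expect_lt(abs(fit$young_modulus_pa / e - 1), 1e-3)
    expect_lt(abs(fit$contact_point_um - 2), 0.005)
  }
})

test_that("the fitted modulus carries the tan(alpha) degeneracy", {
  cv <- simulate_force_curve(1000, noise_frac = 0)
  f30 <- fit_hertz_cone(cv)
  # same force data declared as coming from a steeper tip: E scales down by
  # the tangent ratio
  cv2 <- force_curve(cv$z_piezo, cv$deflection_force, cv$spring_constant,
                     half_angle = atan(2 * tan(30 * pi / 180)) * 180 / pi)
  f2 <- fit_hertz_cone(cv2)
  expect_equal(f2$young_modulus_pa * 2, f30$young_modulus_pa,
               tolerance = 1e-6)
})

test_that("moduli across 0.4-2.3 kPa are recovered with small bias and CV", {
  for (e in c(400, 1000, 2300)) {
    est <- sapply(1:40, function(s) {
      fit_hertz_cone(simulate_force_curve(e, noise_frac = 0.02,
                                          seed = s))$young_modulus_pa
    })
    expect_lt(abs(mean(est) / e - 1), 0.02)
    expect_lt(sd(est) / mean(est), 0.05)
  }
})

test_that("soft and stiff cantilevers recover the same modulus", {
  soft <- sapply(1:25, function(s) {
    fit_hertz_cone(simulate_force_curve(1000, spring_constant = 0.03,
                                        noise_frac = 0.02,
                                        seed = s))$young_modulus_pa
  })
  stiff <- sapply(1:25, function(s) {
    fit_hertz_cone(simulate_force_curve(1000, spring_constant = 2.8,
                                        noise_frac = 0.02,
                                        seed = s + 400))$young_modulus_pa
  })
  expect_lt(abs(mean(soft) / mean(stiff) - 1), 0.05)
})

test_that("contact detection is robust to force noise", {
  errs <- sapply(1:40, function(s) {
    cp <- find_contact_point(simulate_force_curve(470, contact_z = 2,
                                                  noise_frac = 0.05,
                                                  seed = s))
    abs(cp$contact_point_um - 2)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("a tip that never touches raises a not-in-contact error", {
  z <- seq(0, 2, length.out = 100)
  flat <- force_curve(z, rep(0, 100), 0.03, 30)
  expect_error(find_contact_point(flat), class = "not_in_contact")
})

test_that("relative fit error grows with injected noise", {
  mean_err <- sapply(c(0.01, 0.05, 0.10), function(nf) {
    mean(sapply(1:20, function(s) {
      fit_hertz_cone(simulate_force_curve(1000, noise_frac = nf,
                                          seed = s))$relative_fit_error
    }))
  })
  expect_true(all(diff(mean_err) > 0))
})

test_that("elasticity maps recover uniform and structured modulus fields", {
  # uniform 450 Pa substrate-like volume
  fv <- simulate_force_volume(matrix(450, 16, 16), noise_frac = 0.02,
                              seed = 5)
  m <- build_elasticity_map(fv)
  expect_true(all(m$qc_mask))
  expect_lt(abs(m$stats$mean_kpa * 1000 - 450), 10)
  expect_false(m$unreliable)
  # planted stiff 4x4 block segments exactly at a 1 kPa threshold
  truth <- matrix(500, 8, 8)
  truth[3:6, 3:6] <- 2000
  fv2 <- simulate_force_volume(truth, noise_frac = 0.02, seed = 11)
  m2 <- build_elasticity_map(fv2)
  expect_identical(m2$moduli_kpa >= 1, truth >= 1000)
})

test_that("a volume of flat curves yields an unreliable, fully masked map", {
  z <- seq(0, 2, length.out = 60)
  flat <- force_curve(z, rep(0, 60), 0.03, 30)
  fv <- force_volume(rep(list(flat), 16), 4, 4, 1)
  expect_warning(m <- build_elasticity_map(fv), "unreliable")
  expect_false(any(m$qc_mask))
  expect_true(m$unreliable)
})

test_that("force-curve constructor enforces its invariants", {
  expect_error(force_curve(1:10, 1:10), "20 samples")
  expect_error(force_curve(c(1:19, 19), rnorm(20)), "increasing")
  expect_error(force_curve(1:20, rnorm(20), spring_constant = -1), "> 0")
})
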