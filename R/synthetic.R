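# Synthetic ground-truth generators: traction scenes, bead image pairs,
# AFM force curves and volumes, multi-timepoint cohorts.
#
# Every generator is deterministic under its `seed` argument.  The defaults
# emulate the reference experimental conditions: a 470 Pa polyacrylamide
# substrate (Poisson ratio 0.5), focal-adhesion traction patches with peak
# stresses of a few tens of Pa, 200 nm beads imaged as diffraction-limited
# Gaussian spots at ~0.02 in-focus beads/um^2, conical-tip force curves for
# cell moduli of 0.4-2.3 kPa, and 10-minute sampling over 2 h.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Synthetic focal-adhesion traction pattern
#'
#' Generates a traction field made of Gaussian stress patches ("adhesion
#' sites") whose force vectors point toward the common site centroid -- the
#' centripetal morphology of a contractile cell anchored at peripheral
#' adhesions.  Peak magnitudes are drawn uniformly from `stress_range`.
#'
#' @param n_sites Number of adhesion sites (>= 0; 0 gives a zero field).
#' @param stress_range Range (Pa) for the per-site peak stress magnitude.
#' @param site_radius Patch radius in um; the Gaussian profile uses
#'   `sigma = site_radius / 2`.
#' @param field_extent Side length of the square field, um.
#' @param grid_spacing Node spacing, um.
#' @param balanced Project the mean traction to zero so the pattern carries
#'   no net force (default TRUE).
#' @param site_positions Optional `n_sites x 2` matrix of site centres (um);
#'   default: evenly spaced (jittered) angles on a ring of radius 0.3 x
#'   `field_extent` around the field centre.
#' @param seed RNG seed.
#'
#' @return A [traction_field()] on an `n x n` grid,
#'   `n = field_extent / grid_spacing`.
#' @export
make_traction_pattern <- function(n_sites = 6, stress_range = c(30, 70),
                                  site_radius = 4, field_extent = 64,
                                  grid_spacing = 2, balanced = TRUE,
                                  site_positions = NULL, seed = NULL) {
  stopifnot(n_sites >= 0, length(stress_range) == 2,
            stress_range[1] <= stress_range[2])
  stopifnot_scalar(site_radius, "site_radius", positive = TRUE)
  stopifnot_scalar(field_extent, "field_extent", positive = TRUE)
  stopifnot_scalar(grid_spacing, "grid_spacing", positive = TRUE)
  sites <- with_seed(seed, {
    draw_sites(n_sites, stress_range, field_extent, site_positions)
  })
  out <- traction_from_sites(sites, site_radius, field_extent, grid_spacing,
                             balanced)
  attr(out, "site_positions") <- sites$positions
  attr(out, "site_peaks") <- sites$peaks
  out
}

# draw site geometry and peak magnitudes (consumes RNG)
draw_sites <- function(n_sites, stress_range, field_extent, site_positions) {
  if (n_sites == 0) {
    return(list(positions = matrix(numeric(0), 0, 2), peaks = numeric(0),
                dirs = matrix(numeric(0), 0, 2)))
  }
  ctr <- rep(field_extent / 2, 2)
  if (is.null(site_positions)) {
    ang <- seq(0, 2 * pi, length.out = n_sites + 1)[-1] +
      stats::runif(n_sites, -0.3, 0.3)
    rad <- 0.3 * field_extent * stats::runif(n_sites, 0.8, 1.1)
    site_positions <- cbind(ctr[1] + rad * cos(ang),
                            ctr[2] + rad * sin(ang))
  }
  stopifnot(nrow(site_positions) == n_sites)
  centroid <- colMeans(site_positions)
  dirs <- t(apply(site_positions, 1, function(p) {
    d <- centroid - p
    len <- sqrt(sum(d^2))
    if (len > 0) d / len else c(1, 0)
  }))
  list(positions = site_positions,
       peaks = stats::runif(n_sites, stress_range[1], stress_range[2]),
       dirs = matrix(dirs, ncol = 2))
}

# evaluate the analytic Gaussian-patch pattern on a grid of given spacing
traction_from_sites <- function(sites, site_radius, field_extent,
                                grid_spacing, balanced) {
  n <- round(field_extent / grid_spacing)
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  if (nrow(sites$positions) > 0) {
    g <- grid_coords(n, n, grid_spacing)
    sig <- site_radius / 2
    for (q in seq_len(nrow(sites$positions))) {
      prof <- exp(-((g$x - sites$positions[q, 1])^2 +
                    (g$y - sites$positions[q, 2])^2) / (2 * sig^2))
      tx <- tx + sites$peaks[q] * sites$dirs[q, 1] * prof
      ty <- ty + sites$peaks[q] * sites$dirs[q, 2] * prof
    }
  }
  if (balanced) {
    tx <- tx - mean(tx)
    ty <- ty - mean(ty)
  }
  traction_field(tx, ty, grid_spacing)
}

#' Render a reference/loaded fluorescent bead image pair
#'
#' Plants beads at uniform random positions (with a hard-core minimum
#' separation, since sub-resolution bead pairs merge optically and are not
#' individually trackable), images each as a Gaussian spot of width
#' `psf_sigma` (diffraction-limited point spread function) on a constant
#' background, and produces the loaded image by displacing every bead by the
#' displacement field sampled (bilinearly) at its position.  Per-pixel
#' Poisson counting noise emulates photon shot noise; the spot amplitude and
#' background defaults give a peak signal-to-noise ratio `a / sqrt(a + b)`
#' of about 10.
#'
#' The default density, 0.15 beads/um^2, represents the resolvable, tracked
#' subset of the physically much denser bead population (5 percent v/v of
#' 200 nm beads is ~12 beads/um^3, far beyond what a diffraction-limited
#' image can separate).
#'
#' @param displacement A [displacement_field()] covering the imaged region.
#' @param bead_density Areal density of resolvable in-focus beads,
#'   beads/um^2.
#' @param pixel_size Image pixel size, um/px.
#' @param psf_sigma Spot Gaussian width, um; a value below 0.5 px triggers
#'   an undersampling warning.
#' @param peak_intensity Mean spot peak amplitude, counts (per-bead
#'   brightness varies uniformly by +/- 30 percent).
#' @param background Background level, counts.
#' @param photon_noise Apply Poisson noise (default TRUE).
#' @param margin Keep bead centres this far from the field edge, um.
#' @param min_bead_separation Hard-core distance between planted beads, um.
#' @param seed RNG seed.
#'
#' @return An object of class `bead_image_pair`: `reference`, `loaded`
#'   (count matrices), `pixel_size`, and `truth` -- the planted bead table
#'   (`x_um`, `y_um`, `ux_um`, `uy_um`) for oracle tests.
#' @export
render_bead_pair <- function(displacement, bead_density = 0.15,
                             pixel_size = 0.25, psf_sigma = 0.325,
                             peak_intensity = 160, background = 100,
                             photon_noise = TRUE, margin = 2,
                             min_bead_separation = 1, seed = NULL) {
  stopifnot(inherits(displacement, "displacement_field"))
  stopifnot_scalar(bead_density, "bead_density", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (psf_sigma < 0.5 * pixel_size) {
    warning("psf_sigma below 0.5 px: spots are undersampled", call. = FALSE)
  }
  h <- displacement$grid_spacing
  ext_x <- (ncol(displacement$ux) - 1) * h
  ext_y <- (nrow(displacement$ux) - 1) * h
  nx <- round(ext_x / pixel_size) + 1
  ny <- round(ext_y / pixel_size) + 1
  with_seed(seed, {
    nb <- stats::rpois(1, bead_density * ext_x * ext_y)
    pos <- hardcore_positions(nb, margin, ext_x - margin, margin,
                              ext_y - margin, min_bead_separation)
    px <- pos[, 1]; py <- pos[, 2]
    nb <- nrow(pos)
    amp <- peak_intensity * stats::runif(nb, 0.7, 1.3)
    ux <- bilinear_at(displacement$ux, h, displacement$origin, px, py)
    uy <- bilinear_at(displacement$uy, h, displacement$origin, px, py)
    ref <- render_spots(nx, ny, px / pixel_size + 1, py / pixel_size + 1,
                        amp, psf_sigma / pixel_size, background)
    load <- render_spots(nx, ny, (px + ux) / pixel_size + 1,
                         (py + uy) / pixel_size + 1,
                         amp, psf_sigma / pixel_size, background)
    if (photon_noise) {
      # both frames share one noise sub-stream: identical expected images
      # (e.g. zero displacement) then yield bit-identical realizations
      noise_seed <- if (is.null(seed)) {
        stats::runif(1)  # advance; draw below is then seedless but shared
        NULL
      } else {
        seed + 1L
      }
      ref <- with_seed(noise_seed,
        matrix(as.numeric(stats::rpois(length(ref), ref)), ny, nx))
      load <- with_seed(noise_seed,
        matrix(as.numeric(stats::rpois(length(load), load)), ny, nx))
    }
    structure(
      list(reference = ref, loaded = load, pixel_size = pixel_size,
           truth = data.frame(x_um = px, y_um = py, ux_um = ux, uy_um = uy)),
      class = "bead_image_pair"
    )
  })
}

# sequential dart-throwing with a hard-core exclusion radius; keeps the
# requested count whenever the packing allows it
hardcore_positions <- function(n, x0, x1, y0, y1, dmin) {
  px <- numeric(0); py <- numeric(0)
  attempts <- 0L
  max_attempts <- 200L * max(n, 1L)
  while (length(px) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- stats::runif(1, x0, x1)
    cy <- stats::runif(1, y0, y1)
    if (length(px) == 0 || all((px - cx)^2 + (py - cy)^2 >= dmin^2)) {
      px <- c(px, cx); py <- c(py, cy)
    }
  }
  cbind(px, py)
}

# additive Gaussian spots at sub-pixel positions (1-based px coordinates)
render_spots <- function(nx, ny, x_px, y_px, amp, sig_px, background) {
  img <- matrix(background, ny, nx)
  r <- ceiling(4 * sig_px)
  for (q in seq_along(x_px)) {
    j0 <- max(1, floor(x_px[q]) - r); j1 <- min(nx, floor(x_px[q]) + r + 1)
    i0 <- max(1, floor(y_px[q]) - r); i1 <- min(ny, floor(y_px[q]) + r + 1)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1 - x_px[q])^2) / (2 * sig_px^2))
    gy <- exp(-((i0:i1 - y_px[q])^2) / (2 * sig_px^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[q] * outer(gy, gx)
  }
  img
}

#' Simulate an AFM approach force curve for a conical tip
#'
#' Forward model of a force-distance measurement on an elastic sample:
#' zero-force baseline until the tip meets the surface at `contact_z_um`,
#' then the Sneddon cone response `F = (2/pi) tan(alpha) E delta^2 / (1 -
#' nu^2)` with the indentation self-consistently reduced by cantilever
#' bending (`z` travel splits into indentation plus deflection `F/k`).
#' Multiplicative Gaussian noise of relative amplitude `noise_frac` is
#' applied, plus a small additive floor (`noise_frac` x peak force / 20) so
#' the pre-contact baseline carries realistic detector noise.
#'
#' @param young_modulus_pa Sample modulus, Pa (> 0).
#' @param contact_z_um Contact position along the approach, um.
#' @param half_angle Cone half-angle, degrees.
#' @param poisson Sample Poisson ratio.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param noise_frac Relative force noise (>= 0).
#' @param z_max_um End of the approach ramp, um; default indents about
#'   0.55 um past contact.
#' @param n_samples Samples along the ramp (default 400).
#' @param seed RNG seed.
#'
#' @return A [force_curve()].
#' @export
simulate_force_curve <- function(young_modulus_pa = 470, contact_z_um = 2,
                                 half_angle = 30, poisson = 0.5,
                                 spring_constant = 0.03, noise_frac = 0,
                                 z_max_um = contact_z_um + 0.56,
                                 n_samples = 400, seed = NULL) {
  stopifnot_scalar(young_modulus_pa, "young_modulus_pa", positive = TRUE)
  stopifnot_scalar(noise_frac, "noise_frac", nonneg = TRUE)
  z <- seq(0, z_max_um, length.out = n_samples)
  cc <- hertz_cone_coeff(young_modulus_pa, half_angle, poisson)
  k <- spring_constant * n_per_m_to_nn_per_um
  s <- pmax(z - contact_z_um, 0)
  # solve F = cc * (s - F/k)^2 for the physical (smaller) root
  f <- 2 * cc * s^2 / ((2 * cc * s / k + 1) + sqrt(4 * cc * s / k + 1))
  with_seed(seed, {
    if (noise_frac > 0) {
      f <- f * (1 + noise_frac * stats::rnorm(n_samples)) +
        (noise_frac * max(f) / 20) * stats::rnorm(n_samples)
    }
    force_curve(z, f, spring_constant, half_angle)
  })
}

#' Simulate a force-volume grid over a modulus map
#'
#' One simulated force curve per pixel of a ground-truth modulus map, for
#' testing [build_elasticity_map()] end to end.
#'
#' @param moduli_pa Matrix of true moduli in Pa.
#' @param grid_spacing Lateral pixel spacing, um.
#' @param noise_frac Per-curve relative force noise.
#' @param seed RNG seed; per-curve seeds are derived deterministically.
#' @param ... Passed to [simulate_force_curve()].
#'
#' @return A [force_volume()] with `attr(, "truth_pa")` the input map.
#' @export
simulate_force_volume <- function(moduli_pa, grid_spacing = 1,
                                  noise_frac = 0.02, seed = NULL, ...) {
  stopifnot(is.matrix(moduli_pa))
  n <- nrow(moduli_pa); m <- ncol(moduli_pa)
  curves <- vector("list", n * m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      idx <- (i - 1) * m + j
      sd_i <- if (is.null(seed)) NULL else (seed + 7919L * idx) %% 2147483647L
      curves[[idx]] <- simulate_force_curve(
        young_modulus_pa = moduli_pa[i, j], noise_frac = noise_frac,
        seed = sd_i, ...
      )
    }
  }
  fv <- force_volume(curves, n, m, grid_spacing)
  attr(fv, "truth_pa") <- moduli_pa
  fv
}

#' Generate a complete synthetic traction scene
#'
#' Builds the full ground-truth chain for one cell at one time point: a
#' centripetal adhesion-site traction pattern inside a circular contact
#' mask, the forward Boussinesq displacement field (computed with
#' [forward_displacement()], the same code path the inverse solver is tested
#' against), a rendered bead image pair, and an actin-like fluorescence
#' image with intensity concentrated at the adhesion sites.
#'
#' The scene's analysis-grid truth displacement is exactly
#' `forward_displacement(truth_traction)`.  The bead renderer, however,
#' samples a displacement field computed on a `supersample`-times finer grid
#' from the same analytic traction pattern: beads sit between analysis
#' nodes, and the substrate they ride on deforms continuously, not as a
#' bilinear interpolant of the coarse grid.
#'
#' @param seed RNG seed (drives every random choice in the scene).
#' @param field_extent,grid_spacing Field geometry, um.
#' @param substrate A [substrate_properties()] object.
#' @param cell_area_um2 Contact area of the circular cell mask, um^2.
#' @param n_sites,stress_range,site_radius Passed to
#'   [make_traction_pattern()]; sites are placed on the cell periphery.
#' @param mean_stress_pa Optional target for the mean traction magnitude
#'   over the cell mask, Pa; the pattern is rescaled linearly to match.
#' @param pixel_size,bead_density,psf_sigma,photon_noise Passed to
#'   [render_bead_pair()].
#' @param supersample Refinement factor of the rendering grid (default 4).
#'
#' @return An object of class `synthetic_scene` with elements
#'   `truth_traction`, `truth_displacement`, `bead_pair`, `cell_mask`,
#'   `actin_image`, `truth_summary` (the [integrate_force()] of the truth),
#'   `substrate`, `seed`.
#' @export
make_scene <- function(seed = 1, field_extent = 64, grid_spacing = 2,
                       substrate = substrate_properties(470, 0.5),
                       cell_area_um2 = 160, n_sites = 6,
                       stress_range = c(30, 70), site_radius = 5,
                       mean_stress_pa = NULL, pixel_size = 0.25,
                       bead_density = 0.15, psf_sigma = 0.325,
                       photon_noise = TRUE, supersample = 4) {
  n <- round(field_extent / grid_spacing)
  ctr <- field_extent / 2
  r_cell <- sqrt(cell_area_um2 / pi)
  sites <- with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = n_sites + 1)[-1] +
      stats::runif(n_sites, -0.25, 0.25)
    rad <- r_cell * stats::runif(n_sites, 0.55, 0.8)
    pos <- cbind(ctr + rad * cos(ang), ctr + rad * sin(ang))
    draw_sites(n_sites, stress_range, field_extent, pos)
  })
  traction <- traction_from_sites(sites, site_radius, field_extent,
                                  grid_spacing, balanced = TRUE)
  g <- grid_coords(n, n, grid_spacing)
  maskm <- (g$x - ctr)^2 + (g$y - ctr)^2 <= r_cell^2
  mask <- cell_mask(maskm, grid_spacing, label = paste0("scene", seed))
  scale <- 1
  if (!is.null(mean_stress_pa)) {
    mag <- field_magnitude(traction)
    scale <- mean_stress_pa / mean(mag[maskm])
    traction <- traction_field(traction$tx * scale, traction$ty * scale,
                               grid_spacing)
  }
  displacement <- forward_displacement(traction, substrate)
  # continuous-world displacement for the renderer: same analytic pattern on
  # a finer grid
  fine <- traction_from_sites(sites, site_radius, field_extent,
                              grid_spacing / supersample, balanced = TRUE)
  fine <- traction_field(fine$tx * scale, fine$ty * scale,
                         grid_spacing / supersample)
  displacement_fine <- forward_displacement(fine, substrate)
  pair <- render_bead_pair(
    displacement_fine, bead_density = bead_density, pixel_size = pixel_size,
    psf_sigma = psf_sigma, photon_noise = photon_noise, seed = seed + 202
  )
  actin <- with_seed(seed + 303, {
    base <- 50 + 150 * exp(-((g$x - ctr)^2 + (g$y - ctr)^2) / (2 * (r_cell / 1.5)^2))
    for (q in seq_len(nrow(sites$positions))) {
      base <- base + 400 * exp(-((g$x - sites$positions[q, 1])^2 +
                                 (g$y - sites$positions[q, 2])^2) /
                                (2 * (site_radius / 2)^2))
    }
    matrix(stats::rpois(length(base), base), n, n)
  })
  structure(
    list(
      truth_traction = traction,
      truth_displacement = displacement,
      bead_pair = pair,
      cell_mask = mask,
      actin_image = actin,
      truth_summary = integrate_force(traction, mask),
      substrate = substrate,
      field_extent = field_extent,
      seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' Cohort specification for multi-cell, multi-timepoint simulations
#'
#' Captures the study conditions emulated by [make_cohort()]: cohort size,
#' instantaneous stress range of growing cells, contact-area range, the
#' linear stiffness-stress coupling, the acquisition time grid, and noise
#' settings.
#'
#' @param n_cells Number of cells (default 30).
#' @param stress_range Instantaneous mean-stress range (Pa) spanned by the
#'   high/low phases of growing cells (default 28-70 Pa).
#' @param area_range Contact-area range, um^2 (default 100-250).
#' @param modulus_coupling `c(base_kpa, slope_kpa_per_pa)`: true cell
#'   modulus = base + slope x time-averaged stress (default 0.4 kPa +
#'   0.025 kPa/Pa, spanning roughly 0.4-2.3 kPa over the stress range).
#' @param timepoints Acquisition times in minutes (default 0-120 every 10).
#' @param growth_fraction Fraction of cells with actively growing axons.
#' @param substrate A [substrate_properties()] object.
#' @param bead_density Beads per um^2 for rendered scenes.
#' @param noise List: `photon` (bead-image shot noise) and `force_frac`
#'   (AFM force noise).
#' @param seed Cohort seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 30, stress_range = c(28, 70),
                        area_range = c(100, 250),
                        modulus_coupling = c(base_kpa = 0.4,
                                             slope_kpa_per_pa = 0.025),
                        timepoints = seq(0, 120, by = 10),
                        growth_fraction = 0.5,
                        substrate = substrate_properties(470, 0.5),
                        bead_density = 0.15,
                        noise = list(photon = TRUE, force_frac = 0.02),
                        seed = 1) {
  stopifnot(n_cells >= 1, stress_range[1] <= stress_range[2],
            area_range[1] <= area_range[2],
            growth_fraction >= 0, growth_fraction <= 1,
            all(diff(timepoints) > 0))
  structure(
    list(n_cells = n_cells, stress_range = stress_range,
         area_range = area_range, modulus_coupling = modulus_coupling,
         timepoints = timepoints, growth_fraction = growth_fraction,
         substrate = substrate, bead_density = bead_density,
         noise = noise, seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of cells with known mechanics
#'
#' Per cell: a contact area drawn from `area_range`; a stress trace over
#' `timepoints` -- growing cells alternate between a high and a low stress
#' phase (~30 min dwell, levels drawn from the upper and lower parts of
#' `stress_range`), quiescent cells hold a constant low stress; a true
#' modulus coupled linearly to the time-averaged stress; and, when
#' requested, fully rendered bead-image scenes and a simulated AFM force
#' volume.  All ground truth is returned so every pipeline stage can be
#' scored.
#'
#' @param spec A [cohort_spec()].
#' @param render Which scenes to render: `"none"`, `"first"` (first
#'   timepoint), `"all"` (every timepoint), or `"mean"` -- one
#'   representative scene per cell at its time-averaged stress, the planted
#'   `force = mean stress x area` relation behind force-versus-area
#'   analyses.
#' @param afm Simulate a 16 x 16 force volume per cell (default FALSE).
#'
#' @return A list with `spec` and `cells`; each cell is a list with
#'   `label`, `growing`, `area_um2`, `trace` (data.frame `time_min`,
#'   `stress_pa`), `mean_stress_pa`, `true_force_nn`, `modulus_kpa`,
#'   `scenes` (named list or empty), `force_volume` (or NULL).
#' @export
make_cohort <- function(spec = cohort_spec(),
                        render = c("none", "first", "all", "mean"),
                        afm = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  render <- match.arg(render)
  nt <- length(spec$timepoints)
  lo <- spec$stress_range[1]; hi <- spec$stress_range[2]
  cells <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_cells), function(ic) {
      growing <- stats::runif(1) < spec$growth_fraction
      area <- stats::runif(1, spec$area_range[1], spec$area_range[2])
      if (growing) {
        high <- stats::runif(1, lo + 0.65 * (hi - lo), hi)
        low <- stats::runif(1, lo, lo + 0.3 * (hi - lo))
        dwell <- 3  # timepoints per phase (~30 min)
        phase0 <- sample(0:(2 * dwell - 1), 1)
        state <- ((seq_len(nt) - 1 + phase0) %/% dwell) %% 2
        trace <- ifelse(state == 0, high, low) + stats::rnorm(nt, 0, 2)
      } else {
        level <- stats::runif(1, 8, 30)
        trace <- level + stats::rnorm(nt, 0, 2)
      }
      trace <- pmax(trace, 1)
      mean_stress <- mean(trace)
      modulus <- spec$modulus_coupling[[1]] +
        spec$modulus_coupling[[2]] * mean_stress + stats::rnorm(1, 0, 0.05)
      list(
        label = sprintf("cell%02d", ic),
        growing = growing,
        area_um2 = area,
        trace = data.frame(time_min = spec$timepoints, stress_pa = trace),
        mean_stress_pa = mean_stress,
        true_force_nn = mean_stress * area * pa_um2_to_nn,
        modulus_kpa = max(modulus, 0.1),
        scene_seed = spec$seed + 1000L * ic
      )
    })
  })
  which_t <- switch(render, none = integer(0), first = 1L,
                    all = seq_len(nt), mean = NA_integer_)
  for (ic in seq_along(cells)) {
    cl <- cells[[ic]]
    scenes <- list()
    for (it in which_t) {
      if (is.na(it)) {
        scenes[["mean"]] <- make_scene(
          seed = cl$scene_seed,
          substrate = spec$substrate,
          cell_area_um2 = cl$area_um2,
          mean_stress_pa = cl$mean_stress_pa,
          bead_density = spec$bead_density,
          photon_noise = isTRUE(spec$noise$photon)
        )
      } else {
        scenes[[as.character(spec$timepoints[it])]] <- make_scene(
          seed = cl$scene_seed + it,
          substrate = spec$substrate,
          cell_area_um2 = cl$area_um2,
          mean_stress_pa = cl$trace$stress_pa[it],
          bead_density = spec$bead_density,
          photon_noise = isTRUE(spec$noise$photon)
        )
      }
    }
    cells[[ic]]$scenes <- scenes
    cells[[ic]]$force_volume <- if (afm) {
      simulate_force_volume(
        matrix(cl$modulus_kpa * 1000, 16, 16), grid_spacing = 1,
        noise_frac = spec$noise$force_frac, seed = cl$scene_seed + 500L
      )
    } else NULL
  }
  list(spec = spec, cells = cells)
}

#' Synthetic stiffness-map / actin-image pair
#'
#' Demonstration harness for the stiffness-actin overlap statistic: the
#' stiff region of the elasticity map is a disk, and the actin-rich region
#' is the same disk displaced by a small calibrated jitter, mimicking the
#' imperfect but strong colocalization of cytoskeletal actin with stiff
#' soma regions.  With the default geometry (disk radius 4.2 px on a 16 x 16
#' map, jitter 1.2 px: planted overlap 81.9 percent for ideal disks) the
#' realized pixel-level overlap lies in the high-70s to mid-80s percent
#' range, the spread coming from pixelation of the disk boundary.
#'
#' @param seed RNG seed.
#' @param size Map side length in pixels (default 16).
#' @param stiff_kpa,soft_kpa Moduli inside/outside the stiff disk.
#' @param disk_radius_px Stiff-disk radius, px.
#' @param jitter_px Range of the actin-disk displacement, px (degenerate
#'   default: exactly 1.2 px, random direction).
#'
#' @return A list with `map` (an `elasticity_map`), `actin` (intensity
#'   matrix), and `truth` (planted masks and jitter).
#' @export
make_stiffness_actin_pair <- function(seed = 1, size = 16, stiff_kpa = 1.8,
                                      soft_kpa = 0.6, disk_radius_px = 4.2,
                                      jitter_px = c(1.2, 1.2)) {
  with_seed(seed, {
    ctr <- (size + 1) / 2 + stats::runif(2, -0.5, 0.5)
    jit <- stats::runif(1, jitter_px[1], jitter_px[2])
    th <- stats::runif(1, 0, 2 * pi)
    actin_ctr <- ctr + jit * c(cos(th), sin(th))
    jj <- matrix(seq_len(size), size, size, byrow = TRUE)
    ii <- matrix(seq_len(size), size, size)
    stiff <- (jj - ctr[1])^2 + (ii - ctr[2])^2 <= disk_radius_px^2
    actin_mask <- (jj - actin_ctr[1])^2 + (ii - actin_ctr[2])^2 <=
      disk_radius_px^2
    moduli <- matrix(soft_kpa, size, size) +
      matrix(stats::rnorm(size^2, 0, 0.03), size, size)
    moduli[stiff] <- stiff_kpa + stats::rnorm(sum(stiff), 0, 0.08)
    actin <- matrix(60, size, size)
    actin[actin_mask] <- 240
    actin <- actin + matrix(stats::rnorm(size^2, 0, 8), size, size)
    list(
      map = elasticity_map(moduli, grid_spacing = 1),
      actin = actin,
      truth = list(stiff_mask = stiff, actin_mask = actin_mask,
                   jitter_px = jit)
    )
  })
}
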