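# End-to-end recovery and the staged file-based pipeline with manifest.

#' Recover the traction field of a synthetic scene end to end
#'
#' Runs the full measurement chain on a rendered scene: detect beads in both
#' images, link them, optionally remove stage drift, interpolate the sparse
#' displacements onto the scene grid, invert by FTTC, and integrate over the
#' cell mask.  Used to score the pipeline against the scene's ground truth.
#'
#' @param scene A [make_scene()] result.
#' @param regularization Tikhonov parameter passed to [fttc_invert()].
#' @param drift_correct Apply [correct_drift()] using the scene's cell mask
#'   (default FALSE; the simulator adds no drift).
#' @param min_separation,intensity_threshold Passed to [detect_beads()].
#'
#' @return A list with `sparse`, `displacement`, `traction`, `summary`
#'   (recovered), and `truth_summary` from the scene.
#' @export
recover_scene <- function(scene, regularization = 0, drift_correct = FALSE,
                          min_separation = NULL, intensity_threshold = 0.2) {
  stopifnot(inherits(scene, "synthetic_scene"))
  pair <- scene$bead_pair
  ps <- pair$pixel_size
  if (is.null(min_separation)) min_separation <- 4 * ps
  ref <- detect_beads(pair$reference, ps, min_separation, intensity_threshold)
  lod <- detect_beads(pair$loaded, ps, min_separation, intensity_threshold)
  sparse <- match_beads_predictive(ref, lod)
  if (drift_correct) sparse <- correct_drift(sparse, scene$cell_mask)
  h <- scene$truth_traction$grid_spacing
  n <- nrow(scene$truth_traction$tx)
  m <- ncol(scene$truth_traction$tx)
  disp <- interpolate_to_grid(
    sparse, h, extent = c(0, (m - 1) * h, 0, (n - 1) * h)
  )
  # accept the extrapolated boundary nodes for the inversion
  disp_full <- displacement_field(disp$ux, disp$uy, h, disp$origin)
  traction <- fttc_invert(disp_full, scene$substrate, regularization)
  list(
    sparse = sparse,
    displacement = disp,
    traction = traction,
    summary = integrate_force(traction, scene$cell_mask),
    truth_summary = scene$truth_summary
  )
}

#' Default pipeline configuration
#'
#' The defaults reproduce the reference demonstration conditions: a 470 Pa,
#' Poisson-0.5 substrate, a 64 um field on a 2 um traction grid, 0.25 um
#' image pixels, unregularized inversion, a 30-degree conical AFM tip with
#' 20 percent fit-error quality control on 16 x 16 x 1 um elasticity maps,
#' a 1 kPa stiffness threshold for overlap statistics, and 10-minute
#' sampling.
#'
#' @return A nested list; see [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    substrate = list(young_modulus_pa = 470, poisson_ratio = 0.5),
    field_extent_um = 64,
    grid_spacing_um = 2,
    pixel_size_um = 0.25,
    regularization = 0,
    scene = list(cell_area_um2 = 160, mean_stress_pa = 50,
                 bead_density_per_um2 = 0.15, photon_noise = TRUE),
    tracking = list(min_separation_um = 1.0, intensity_threshold = 0.2),
    hertz = list(half_angle_deg = 30, poisson_cell = 0.5,
                 qc_threshold = 0.2, map_size = 16, map_spacing_um = 1),
    overlap = list(e_threshold_kpa = 1, actin_rule = "otsu"),
    timepoints_min = seq(0, 120, by = 10)
  )
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' Configurations round-trip losslessly; unspecified entries fall back to
#' [default_run_config()].
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param config Configuration list to write.
#' @return `read_run_config()` returns the merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the staged file-based pipeline
#'
#' Executes the requested stages in order, each reading only the declared
#' artifacts of its upstream stage from `out_dir` and writing its own:
#'
#' * `simulate` -- synthetic scene: truth fields, bead image TIFFs, mask and
#'   actin CSVs;
#' * `track` -- sparse displacements CSV and gridded displacement field from
#'   the bead images;
#' * `invert` -- FTTC traction field from the gridded displacement;
#' * `metrics` -- per-cell summary CSV and JSON digest from the traction
#'   field and mask.
#'
#' A manifest (`manifest.json`) records the configuration, its MD5 hash,
#' the package version, and each stage's outputs with MD5 checksums, making
#' every output regenerable and the run auditable for determinism: re-running
#' with the same configuration reproduces identical artifact checksums.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   accepted by [read_run_config()].
#' @param stages Ordered subset of
#'   `c("simulate", "track", "invert", "metrics")`.
#' @param out_dir Artifact directory.
#'
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "track", "invert", "metrics"),
                         out_dir = "pipeline_out") {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  substrate <- substrate_properties(config$substrate$young_modulus_pa,
                                    config$substrate$poisson_ratio)
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("neurotfm")),
    config = config,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list()
  )
  need <- function(path, stage, producer) {
    if (!file.exists(path)) {
      stop(sprintf("stage '%s' requires '%s' (produced by stage '%s')",
                   stage, path, producer), call. = FALSE)
    }
    path
  }
  p <- function(...) file.path(out_dir, ...)

  for (stage in stages) {
    outputs <- switch(
      stage,
      simulate = {
        scene <- make_scene(
          seed = config$seed,
          field_extent = config$field_extent_um,
          grid_spacing = config$grid_spacing_um,
          substrate = substrate,
          cell_area_um2 = config$scene$cell_area_um2,
          mean_stress_pa = config$scene$mean_stress_pa,
          pixel_size = config$pixel_size_um,
          bead_density = config$scene$bead_density_per_um2,
          photon_noise = isTRUE(config$scene$photon_noise)
        )
        write_field(scene$truth_traction, p("truth_traction"), substrate)
        write_field(scene$truth_displacement, p("truth_displacement"))
        write_bead_pair(scene$bead_pair, p("beads"))
        utils::write.table(scene$cell_mask$mask * 1L, p("cell_mask.csv"),
                           sep = ",", row.names = FALSE, col.names = FALSE)
        utils::write.table(scene$actin_image, p("actin.csv"), sep = ",",
                           row.names = FALSE, col.names = FALSE)
        c("truth_traction.csv", "truth_traction.tif", "truth_traction.json",
          "truth_displacement.csv", "truth_displacement.tif",
          "truth_displacement.json", "beads_reference.tif",
          "beads_loaded.tif", "beads.json", "beads_truth.csv",
          "cell_mask.csv", "actin.csv")
      },
      track = {
        need(p("beads.json"), "track", "simulate")
        pair <- read_bead_pair(p("beads"))
        ref <- detect_beads(pair$reference, pair$pixel_size,
                            config$tracking$min_separation_um,
                            config$tracking$intensity_threshold)
        lod <- detect_beads(pair$loaded, pair$pixel_size,
                            config$tracking$min_separation_um,
                            config$tracking$intensity_threshold)
        sparse <- match_beads_predictive(ref, lod)
        write_sparse_displacements(sparse, p("sparse_displacements.csv"))
        h <- config$grid_spacing_um
        n <- round(config$field_extent_um / h)
        disp <- interpolate_to_grid(
          sparse, h, extent = c(0, (n - 1) * h, 0, (n - 1) * h)
        )
        write_field(displacement_field(disp$ux, disp$uy, h, disp$origin),
                    p("displacement"))
        c("sparse_displacements.csv", "displacement.csv", "displacement.tif",
          "displacement.json")
      },
      invert = {
        need(p("displacement.json"), "invert", "track")
        disp <- read_field(p("displacement"))
        tr <- fttc_invert(disp, substrate, config$regularization)
        write_field(tr, p("traction"), substrate)
        c("traction.csv", "traction.tif", "traction.json")
      },
      metrics = {
        need(p("traction.json"), "metrics", "invert")
        need(p("cell_mask.csv"), "metrics", "simulate")
        tr <- read_field(p("traction"))
        maskm <- as.matrix(utils::read.table(p("cell_mask.csv"), sep = ",")) == 1
        dimnames(maskm) <- NULL
        mask <- cell_mask(maskm, config$grid_spacing_um, label = "cell01")
        s <- integrate_force(tr, mask)
        utils::write.csv(summary_table(list(s)), p("summary.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(cell = s$label, mean_stress_pa = s$mean_stress_pa,
               peak_stress_pa = s$peak_stress_pa,
               total_force_nn = s$total_force_nn,
               net_force_nn = s$net_force_nn,
               contact_area_um2 = s$contact_area_um2),
          p("summary.json"), auto_unbox = TRUE, digits = NA
        )
        c("summary.csv", "summary.json")
      }
    )
    manifest$stages[[stage]] <- list(
      outputs = outputs,
      md5 = unname(tools::md5sum(file.path(out_dir, outputs)))
    )
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
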