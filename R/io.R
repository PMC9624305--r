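# Plain-text and TIFF serialization.
#
# Vector fields travel as long-format CSV plus a JSON sidecar holding the
# grid metadata (spacing, origin, substrate, regularization), and optionally
# as multi-page 32-bit TIFF.  TIFF pages are affinely rescaled to [0, 1]
# (the range the tiff package stores losslessly at float precision) with the
# offset/scale recorded in the sidecar.

#' Write a gridded field to CSV (+ JSON sidecar, optional TIFF)
#'
#' @param field A [traction_field()] or [displacement_field()].
#' @param prefix Output path prefix; writes `<prefix>.csv`,
#'   `<prefix>.json`, and (if `tiff = TRUE`) `<prefix>.tif` with one page
#'   per component.
#' @param substrate Optional [substrate_properties()] recorded in the
#'   sidecar.
#' @param tiff Also write the multi-page 32-bit TIFF (default TRUE).
#' @return `prefix`, invisibly.
#' @export
write_field <- function(field, prefix, substrate = NULL, tiff = TRUE) {
  is_tr <- inherits(field, "traction_field")
  stopifnot(is_tr || inherits(field, "displacement_field"))
  utils::write.csv(as.data.frame(field), paste0(prefix, ".csv"),
                   row.names = FALSE)
  comps <- if (is_tr) list(field$tx, field$ty) else list(field$ux, field$uy)
  meta <- list(
    type = if (is_tr) "traction" else "displacement",
    units = if (is_tr) "Pa" else "um",
    grid_spacing_um = field$grid_spacing,
    origin_um = field$origin,
    shape = dim(comps[[1]])
  )
  if (is_tr) meta$regularization <- field$regularization_used
  if (!is.null(substrate)) {
    meta$substrate <- list(young_modulus_pa = substrate$young_modulus,
                           poisson_ratio = substrate$poisson_ratio)
  }
  if (tiff) {
    meta$tiff_pages <- write_tiff_float(comps, paste0(prefix, ".tif"))
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a gridded field written by [write_field()]
#'
#' @param prefix Path prefix used at write time.
#' @param from `"csv"` (default) or `"tiff"`.
#' @return The reconstructed field object.
#' @export
read_field <- function(prefix, from = c("csv", "tiff")) {
  from <- match.arg(from)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$shape[1]; m <- meta$shape[2]
  if (from == "csv") {
    df <- utils::read.csv(paste0(prefix, ".csv"))
    cols <- if (meta$type == "traction") c("tx_Pa", "ty_Pa")
            else c("ux_um", "uy_um")
    a <- matrix(df[[cols[1]]], n, m)
    b <- matrix(df[[cols[2]]], n, m)
  } else {
    pages <- read_tiff_float(paste0(prefix, ".tif"), meta$tiff_pages)
    a <- pages[[1]]; b <- pages[[2]]
  }
  if (meta$type == "traction") {
    traction_field(a, b, meta$grid_spacing_um, meta$origin_um,
                   regularization_used = meta$regularization %||% 0)
  } else {
    displacement_field(a, b, meta$grid_spacing_um, meta$origin_um)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiff_float <- function(mats, path) {
  pages <- lapply(mats, function(m) {
    off <- min(m); scale <- max(m) - off
    if (scale == 0) scale <- 1
    list(offset = off, scale = scale)
  })
  norm <- Map(function(m, p) (m - p$offset) / p$scale, mats, pages)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  pages
}

read_tiff_float <- function(path, pages_meta) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.data.frame(pages_meta)) {
    pages_meta <- split(pages_meta, seq_len(nrow(pages_meta)))
  }
  Map(function(m, p) m * p$scale + p$offset, pages, pages_meta)
}

#' Write a bead image pair as 16-bit TIFFs
#'
#' Writes `<prefix>_reference.tif` and `<prefix>_loaded.tif` (16-bit
#' grayscale, common linear count scale recorded in `<prefix>.json`) plus
#' the ground-truth bead table `<prefix>_truth.csv` when present.
#'
#' @param pair A `bead_image_pair`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bead_pair <- function(pair, prefix) {
  stopifnot(inherits(pair, "bead_image_pair"))
  top <- max(pair$reference, pair$loaded, 1)
  tiff::writeTIFF(pair$reference / top, paste0(prefix, "_reference.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(pair$loaded / top, paste0(prefix, "_loaded.tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = pair$pixel_size, count_scale = top),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(pair$truth)) {
    utils::write.csv(pair$truth, paste0(prefix, "_truth.csv"),
                     row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a bead image pair written by [write_bead_pair()]
#' @param prefix Path prefix used at write time.
#' @return A `bead_image_pair` (quantized to the stored 16-bit scale).
#' @export
read_bead_pair <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ref <- tiff::readTIFF(paste0(prefix, "_reference.tif")) * meta$count_scale
  lod <- tiff::readTIFF(paste0(prefix, "_loaded.tif")) * meta$count_scale
  truth_path <- paste0(prefix, "_truth.csv")
  structure(
    list(reference = ref, loaded = lod, pixel_size = meta$pixel_size_um,
         truth = if (file.exists(truth_path)) utils::read.csv(truth_path)),
    class = "bead_image_pair"
  )
}

#' Write / read sparse bead displacements as CSV
#' @param sparse A `sparse_displacements` data.frame.
#' @param path CSV path.
#' @return `path` invisibly; `read_sparse_displacements()` returns the
#'   data.frame.
#' @export
write_sparse_displacements <- function(sparse, path) {
  utils::write.csv(as.data.frame(sparse), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sparse_displacements
#' @export
read_sparse_displacements <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("sparse_displacements", "data.frame")
  out
}

#' Write / read an AFM force curve as CSV with a JSON sidecar
#'
#' The CSV has columns `z_um`, `force_nN`; the sidecar stores the cantilever
#' spring constant and tip half-angle.
#'
#' @param curve A [force_curve()].
#' @param path CSV path (sidecar at `<path>.json`).
#' @param spring_constant,half_angle Used by the reader when no sidecar
#'   exists.
#' @return `path` invisibly; the reader returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(
    data.frame(z_um = curve$z_piezo, force_nN = curve$deflection_force),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(spring_constant_n_per_m = curve$spring_constant,
         half_angle_deg = curve$half_angle),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path, spring_constant = 0.03, half_angle = 30) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    spring_constant <- meta$spring_constant_n_per_m
    half_angle <- meta$half_angle_deg
  }
  force_curve(df$z_um, df$force_nN, spring_constant, half_angle)
}

#' Write / read a force volume as a directory of curve CSVs + JSON manifest
#'
#' @param fv A [force_volume()].
#' @param dir Output directory (created if missing); the manifest is
#'   `<dir>/force_volume.json`.
#' @return `dir` invisibly; the reader returns a [force_volume()].
#' @export
write_force_volume <- function(fv, dir) {
  stopifnot(inherits(fv, "force_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(fv$curves))
  for (q in seq_along(fv$curves)) {
    files[q] <- sprintf("curve_%04d.csv", q)
    write_force_curve(fv$curves[[q]], file.path(dir, files[q]))
  }
  jsonlite::write_json(
    list(nrow = fv$nrow, ncol = fv$ncol, grid_spacing_um = fv$grid_spacing,
         order = "row-major", files = files),
    file.path(dir, "force_volume.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_force_volume
#' @export
read_force_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "force_volume.json"),
                              simplifyVector = TRUE)
  curves <- lapply(meta$files, function(f) read_force_curve(file.path(dir, f)))
  force_volume(curves, meta$nrow, meta$ncol, meta$grid_spacing_um)
}

#' Write an elasticity map as CSV grid (+ TIFF, + JSON)
#'
#' @param map An `elasticity_map`.
#' @param prefix Path prefix for `<prefix>.csv` (modulus grid, kPa, NA for
#'   unfitted pixels), `<prefix>_qc.csv`, `<prefix>.tif`, `<prefix>.json`.
#' @return `prefix` invisibly; the reader returns an `elasticity_map`.
#' @export
write_elasticity_map <- function(map, prefix) {
  stopifnot(inherits(map, "elasticity_map"))
  utils::write.table(map$moduli_kpa, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map$qc_mask * 1L, paste0(prefix, "_qc.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  filled <- map$moduli_kpa
  filled[is.na(filled)] <- 0
  pages <- write_tiff_float(list(filled), paste0(prefix, ".tif"))
  jsonlite::write_json(
    list(grid_spacing_um = map$grid_spacing, units = "kPa",
         shape = dim(map$moduli_kpa), stats = map$stats,
         unreliable = map$unreliable, tiff_pages = pages),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_elasticity_map
#' @export
read_elasticity_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  moduli <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(moduli) <- NULL
  qc <- as.matrix(utils::read.table(paste0(prefix, "_qc.csv"), sep = ",")) == 1
  dimnames(qc) <- NULL
  elasticity_map(moduli, meta$grid_spacing_um, qc)
}
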