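# Volumetric images, NIfTI I/O and SUV calibration.
#
# Internal geometry convention: world coordinates are LPS millimetres (DICOM
# patient space), voxel indices are 0-based in the mapping formula, and the
# voxel value sits at the voxel center:
#   world = origin + orientation %*% (index * spacing)
# NIfTI stores RAS+ affines, so the first two affine rows are negated on read
# and write.

VALID_MODALITIES <- c("CT_HU", "PET_BQML", "PET_SUV")

#' Construct an in-memory 3-D image volume
#'
#' The common currency of all imaging operations: a 3-D voxel array with its
#' grid geometry and a modality tag (`CT_HU` Hounsfield units, `PET_BQML`
#' activity concentration in Bq/mL, or `PET_SUV` standardized uptake values).
#'
#' @param voxels 3-D numeric array.
#' @param spacing Voxel edge lengths in mm, length 3, strictly positive.
#' @param origin World (LPS, mm) position of the center of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction matrix (world-from-index).
#' @param modality One of `"CT_HU"`, `"PET_BQML"`, `"PET_SUV"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         orientation = diag(3), modality = "PET_SUV") {
  if (length(dim(voxels)) != 3L)
    stop_gq("voxel data must be a 3-D array (got %d dims)",
            length(dim(voxels)), class = "gq_dimensionality_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_gq("spacing must be 3 strictly positive values", class = "gq_geometry_error")
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop_gq("orientation matrix is not orthonormal", class = "gq_geometry_error")
  modality <- match.arg(modality, VALID_MODALITIES)
  if (modality == "CT_HU") {
    rng <- range(voxels)
    if (rng[1L] < -1024 - 1e-6 || rng[2L] > 4000 + 1e-6)
      stop_gq("CT_HU voxels outside plausible range [-1024, 4000]: [%g, %g]",
              rng[1L], rng[2L], class = "gq_modality_error")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  cat(sprintf("  origin (%s) mm, value range [%.4g, %.4g]\n",
              paste(signif(x$origin, 5), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# 4x4 world-from-index affine in LPS (index 0-based, mm)
volume_affine <- function(vol) {
  A <- vol$orientation %*% diag(vol$spacing)
  rbind(cbind(A, vol$origin), c(0, 0, 0, 1))
}

# world coordinates (n x 3, LPS mm) of 1-based subscripts
index_to_world <- function(vol, sub) {
  idx0 <- sweep(sub - 1, 2L, vol$spacing, `*`)
  sweep(idx0 %*% t(vol$orientation), 2L, vol$origin, `+`)
}

# continuous 0-based index coordinates of world points (n x 3)
world_to_index <- function(vol, pts) {
  rel <- sweep(pts, 2L, vol$origin, `-`) %*% vol$orientation  # R^-1 = t(R)
  sweep(rel, 2L, vol$spacing, `/`)
}

#' Read a NIfTI volume from disk
#'
#' Populates grid geometry from the NIfTI header (sform/qform, converted from
#' RAS+ to the package's internal LPS convention); voxel values are read
#' unchanged.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality Modality tag to attach (`"CT_HU"`, `"PET_BQML"`, `"PET_SUV"`).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality) {
  if (!file.exists(path))
    stop_gq("file not found: %s", path, class = "gq_io_error")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop_gq("expected a 3-D volume, got %d dims", length(dim(arr)),
            class = "gq_dimensionality_error")
  aff_ras <- structure(RNifti::xform(img), dim = c(4L, 4L))
  aff_lps <- diag(c(-1, -1, 1, 1)) %*% aff_ras
  A <- aff_lps[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  image_volume(arr, spacing = spacing, origin = aff_lps[1:3, 4L],
               orientation = sweep(A, 2L, spacing, `/`), modality = modality)
}

#' Write an image volume as NIfTI-1
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  aff_ras <- diag(c(-1, -1, 1, 1)) %*% volume_affine(vol)
  RNifti::qform(img) <- structure(aff_ras, code = 2L)
  RNifti::sform(img) <- structure(aff_ras, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' SUV calibration parameters
#'
#' Converts PET activity concentration to body-weight standardized uptake
#' values. Times may be `POSIXct` timestamps or numeric minutes.
#'
#' @param injected_dose_mbq Injected activity at injection time, MBq.
#' @param injection_time,scan_time Timestamps (`POSIXct`) or numeric minutes.
#' @param body_weight_kg Body weight, kg.
#' @param half_life_min Tracer half-life in minutes (default 110, 18F).
#' @return An object of class `suv_calibration`.
#' @export
suv_calibration <- function(injected_dose_mbq, injection_time, scan_time,
                            body_weight_kg, half_life_min = 110) {
  check_scalar_pos(injected_dose_mbq, "injected_dose_mbq")
  check_scalar_pos(body_weight_kg, "body_weight_kg")
  check_scalar_pos(half_life_min, "half_life_min")
  if (minutes_between(injection_time, scan_time) < 0)
    stop_gq("scan_time precedes injection_time", class = "gq_calibration_error")
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 injection_time = injection_time, scan_time = scan_time,
                 body_weight_kg = body_weight_kg,
                 half_life_min = half_life_min),
            class = "suv_calibration")
}

minutes_between <- function(from, to) {
  if (inherits(from, "POSIXt") && inherits(to, "POSIXt"))
    as.numeric(difftime(to, from, units = "mins"))
  else as.numeric(to) - as.numeric(from)
}

#' Decay-corrected injected dose
#'
#' Physical decay of the injected activity: `dose * 2^(-dt / half_life)`,
#' with `dt` the injection-to-`at_time` interval in minutes.
#'
#' @param cal An [suv_calibration()].
#' @param at_time Target time (same representation as the calibration times);
#'   defaults to the scan time.
#' @return Remaining activity in MBq.
#' @export
decay_corrected_dose <- function(cal, at_time = cal$scan_time) {
  stopifnot(inherits(cal, "suv_calibration"))
  dt <- minutes_between(cal$injection_time, at_time)
  if (dt < 0)
    stop_gq("at_time precedes injection_time", class = "gq_calibration_error")
  cal$injected_dose_mbq * 2^(-dt / cal$half_life_min)
}

#' Convert PET activity concentration to SUV
#'
#' Body-weight SUV with dose decay-corrected to scan start and the standard
#' 1 g/mL tissue density convention:
#' `SUV = C [Bq/mL] / (decayed dose [Bq] / body weight [g])`.
#'
#' @param pet An [image_volume()] with modality `PET_BQML`.
#' @param cal An [suv_calibration()].
#' @return An [image_volume()] with modality `PET_SUV`, same geometry.
#' @export
to_suv <- function(pet, cal) {
  stopifnot(inherits(pet, "image_volume"), inherits(cal, "suv_calibration"))
  if (pet$modality != "PET_BQML")
    stop_gq("to_suv expects PET_BQML input, got %s", pet$modality,
            class = "gq_modality_error")
  factor_bq_per_ml <- suv_scale_factor(cal)
  out <- pet
  out$voxels <- pet$voxels / factor_bq_per_ml
  out$modality <- "PET_SUV"
  out
}

# Bq/mL corresponding to SUV = 1 under this calibration
suv_scale_factor <- function(cal) {
  decay_corrected_dose(cal, cal$scan_time) * 1e6 / (cal$body_weight_kg * 1000)
}
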