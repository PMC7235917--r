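# Digital phantom generator: synthetic PET/CT pairs with exactly known
# ground truth. The default anatomy emulates the lumbar situation the method
# targets: an elliptical body, a posterior vertebral bone column, bilateral
# erector-spinae muscle cylinders above bilateral graft hot regions adjacent
# to the bone. PET is formed by rasterizing a piecewise-constant true SUV
# map, blurring with an isotropic Gaussian PSF, adding pseudo-Poisson noise
# and scaling to activity concentration (Bq/mL) under a known calibration.

#' Describe one homogeneous phantom tissue region
#'
#' @param label Region name (free text, unique within a spec).
#' @param shape `"cylinder"` (center/axis/radius/height), `"sphere"`
#'   (center/radius) or `"box"` (lo/hi corners), all in world mm.
#' @param hu CT value assigned to the region (Hounsfield units).
#' @param suv True uptake assigned to the region (SUV units).
#' @param ... Shape parameters: `center`, `axis`, `radius_mm`, `height_mm`,
#'   `lo`, `hi` as required by `shape`.
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(label, shape = c("cylinder", "sphere", "box"),
                           hu, suv, ...) {
  shape <- match.arg(shape)
  structure(c(list(label = label, shape = shape, hu = hu, suv = suv),
              list(...)),
            class = "phantom_region")
}

rasterize_region <- function(region, grid) {
  dm <- dim(grid$voxels)
  sub <- as.matrix(expand.grid(i = seq_len(dm[1L]), j = seq_len(dm[2L]),
                               k = seq_len(dm[3L])))
  w <- index_to_world(grid, sub)
  inside <- switch(
    region$shape,
    cylinder = {
      ax <- region$axis %||% c(0, 0, 1)
      ax <- ax / sqrt(sum(ax^2))
      d <- sweep(w, 2L, region$center, `-`)
      along <- d %*% ax
      abs(along) <= region$height_mm / 2 + 1e-9 &
        rowSums(d^2) - along^2 <= region$radius_mm^2 + 1e-9
    },
    sphere = {
      d <- sweep(w, 2L, region$center, `-`)
      rowSums(d^2) <= region$radius_mm^2 + 1e-9
    },
    box = {
      w[, 1L] >= region$lo[1L] & w[, 1L] <= region$hi[1L] &
        w[, 2L] >= region$lo[2L] & w[, 2L] <= region$hi[2L] &
        w[, 3L] >= region$lo[3L] & w[, 3L] <= region$hi[3L]
    })
  mask <- array(FALSE, dm)
  mask[sub_to_lin(sub[as.vector(inside), , drop = FALSE], dm)] <- TRUE
  mask
}

#' Phantom specification
#'
#' @param dim Grid dimensions (voxels), length 3.
#' @param spacing_mm Voxel spacing, mm.
#' @param air_hu,air_suv Values outside the body (default -1000 HU, 0 SUV).
#' @param body Body region (elliptic column): list with `center`
#'   (xy world mm), `semiaxes` (xy mm), `hu` (default 40), `suv`
#'   (default 0.5). The body spans the full z extent.
#' @param regions List of [phantom_region()]s; when regions overlap, the
#'   earlier-declared region takes precedence (overlaps are reported).
#' @param psf_fwhm_mm PET point-spread FWHM in mm (default 6).
#' @param noise_scale Pseudo-Poisson noise scale: Gaussian noise with
#'   variance `noise_scale x local mean SUV` added to the blurred SUV map
#'   (default 0, noise-free).
#' @param misalignment Optional [rigid_transform()] applied to the PET
#'   header geometry to emulate an unfused scan pair.
#' @param calibration [suv_calibration()] used to scale true SUV to Bq/mL.
#' @param seed Integer RNG seed for the noise draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(80L, 60L, 60L), spacing_mm = c(2, 2, 2),
                         air_hu = -1000, air_suv = 0,
                         body = list(center = c(79, 59), semiaxes = c(75, 55),
                                     hu = 40, suv = 0.5),
                         regions = list(), psf_fwhm_mm = 6, noise_scale = 0,
                         misalignment = NULL,
                         calibration = default_phantom_calibration(),
                         seed = 1L) {
  stopifnot(length(dim) == 3L, length(spacing_mm) == 3L)
  structure(list(dim = as.integer(dim), spacing_mm = as.numeric(spacing_mm),
                 air_hu = air_hu, air_suv = air_suv, body = body,
                 regions = regions, psf_fwhm_mm = psf_fwhm_mm,
                 noise_scale = noise_scale, misalignment = misalignment,
                 calibration = calibration, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default calibration for phantom scans
#'
#' A 70 kg patient injected with 2.2 MBq/kg (154 MBq) and scanned after a
#' 90-min uptake period; 18F half-life 110 min.
#' @return An [suv_calibration()].
#' @export
default_phantom_calibration <- function() {
  suv_calibration(injected_dose_mbq = 154, injection_time = 0, scan_time = 90,
                  body_weight_kg = 70, half_life_min = 110)
}

#' The default bilateral-graft phantom anatomy
#'
#' An elliptical body column (40 HU, SUV 0.5) containing a central posterior
#' bone column (700 HU, SUV 3), bilateral 20 cm3 erector-spinae muscle
#' cylinders (50 HU, true SUV 1) cranial to bilateral spherical graft hot
#' regions (400 HU, true SUV 5, 4 cm3 each) flanking the bone.
#'
#' @param graft_suv True graft SUV (default 5).
#' @param graft_volume_ml True volume of each graft region, mL (default 4).
#' @param muscle_suv True muscle SUV (default 1).
#' @param psf_fwhm_mm,noise_scale,seed,misalignment Passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(graft_suv = 5, graft_volume_ml = 4,
                                 muscle_suv = 1, psf_fwhm_mm = 6,
                                 noise_scale = 0, seed = 1L,
                                 misalignment = NULL) {
  graft_r <- (3 * graft_volume_ml * 1000 / (4 * pi))^(1 / 3)
  mid_x <- 79
  regions <- list(
    phantom_region("bone", "box", hu = 700, suv = 3,
                   lo = c(mid_x - 10, 65, 0), hi = c(mid_x + 10, 85, 118)),
    phantom_region("muscle_L", "cylinder", hu = 50, suv = muscle_suv,
                   center = c(mid_x + 30, 78, 85), axis = c(0, 0, 1),
                   radius_mm = 10, height_mm = 63.662),
    phantom_region("muscle_R", "cylinder", hu = 50, suv = muscle_suv,
                   center = c(mid_x - 30, 78, 85), axis = c(0, 0, 1),
                   radius_mm = 10, height_mm = 63.662),
    phantom_region("graft_L", "sphere", hu = 400, suv = graft_suv,
                   center = c(mid_x + 32, 75, 30), radius_mm = graft_r),
    phantom_region("graft_R", "sphere", hu = 400, suv = graft_suv,
                   center = c(mid_x - 32, 75, 30), radius_mm = graft_r))
  phantom_spec(regions = regions, psf_fwhm_mm = psf_fwhm_mm,
               noise_scale = noise_scale, seed = seed,
               misalignment = misalignment)
}

#' Generate a synthetic PET/CT pair with known ground truth
#'
#' Rasterizes the piecewise-constant HU and true-SUV maps (region precedence
#' by declaration order), blurs the SUV map with the PSF, adds seeded
#' pseudo-Poisson noise, scales to activity concentration under the spec's
#' calibration, and (optionally) perturbs the PET header geometry by the
#' misalignment transform. The CT is returned noise-free and unblurred.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `pet` (`PET_BQML` [image_volume()]), `ct` (`CT_HU`),
#'   `truth` (per-region data frame with true SUV, HU and exact rasterized
#'   volume), `region_masks` (named list of logical arrays on the CT grid),
#'   `suv_truth` (unblurred true SUV map), `calibration`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- image_volume(array(0, spec$dim), spec$spacing_mm,
                       modality = "PET_SUV")
  dm <- spec$dim
  vox_ml <- prod(spec$spacing_mm) / 1000
  hu <- array(spec$air_hu, dm)
  suv <- array(spec$air_suv, dm)
  # body: elliptic column over the full z extent
  sub_xy <- as.matrix(expand.grid(i = seq_len(dm[1L]), j = seq_len(dm[2L])))
  wxy <- cbind((sub_xy[, 1L] - 1) * spec$spacing_mm[1L],
               (sub_xy[, 2L] - 1) * spec$spacing_mm[2L])
  inside_body <- ((wxy[, 1L] - spec$body$center[1L]) / spec$body$semiaxes[1L])^2 +
    ((wxy[, 2L] - spec$body$center[2L]) / spec$body$semiaxes[2L])^2 <= 1
  body_slice <- array(FALSE, dm[1:2])
  body_slice[sub_xy[inside_body, , drop = FALSE]] <- TRUE
  body_mask <- array(rep(body_slice, dm[3L]), dm)
  hu[body_mask] <- spec$body$hu %||% 40
  suv[body_mask] <- spec$body$suv %||% 0.5
  assigned <- array(FALSE, dm)
  region_masks <- list()
  truth <- data.frame(label = character(0), hu = numeric(0),
                      true_suv = numeric(0), n_voxels = integer(0),
                      volume_ml = numeric(0))
  for (rg in spec$regions) {
    m <- rasterize_region(rg, grid)
    overlap <- sum(m & assigned)
    if (overlap > 0L)
      message(sprintf("phantom region '%s': %d voxel(s) already claimed by %s",
                      rg$label, overlap, "an earlier region (kept earlier)"))
    m <- m & !assigned
    assigned <- assigned | m
    hu[m] <- rg$hu
    suv[m] <- rg$suv
    region_masks[[rg$label]] <- m
    truth <- rbind(truth, data.frame(label = rg$label, hu = rg$hu,
                                     true_suv = rg$suv, n_voxels = sum(m),
                                     volume_ml = sum(m) * vox_ml))
  }
  pet_suv <- gaussian_blur(suv, spec$psf_fwhm_mm, spec$spacing_mm)
  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    pet_suv <- pet_suv +
      rnorm(length(pet_suv), sd = sqrt(spec$noise_scale * pmax(pet_suv, 0)))
  }
  scale_bqml <- suv_scale_factor(spec$calibration)
  pet <- image_volume(pet_suv * scale_bqml, spec$spacing_mm,
                      modality = "PET_BQML")
  if (!is.null(spec$misalignment)) {
    M <- spec$misalignment
    pet$orientation <- M$R %*% pet$orientation
    pet$origin <- as.numeric(apply_rigid(M, pet$origin))
  }
  ct <- image_volume(hu, spec$spacing_mm, modality = "CT_HU")
  list(pet = pet, ct = ct, truth = truth, region_masks = region_masks,
       suv_truth = suv, calibration = spec$calibration, spec = spec)
}
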