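# The quantification method: HU-windowed muscle masking, muscle SUVpeak as a
# patient-specific fixed lower threshold, graft threshold segmentation with
# minimum-component filtering, SUVtotal and partial-volume-corrected
# cSUVtotal.

#' Hounsfield-unit window
#'
#' The muscle reference window defaults to 0-250 HU, chosen to exclude fat
#' (approx. -100 HU) below and bone (> 250 HU) above.
#'
#' @param lo,hi Window bounds in HU, `lo < hi`.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(lo = 0, hi = 250) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop_gq("hu_window requires lo < hi", class = "gq_argument_error")
  structure(list(lo = lo, hi = hi), class = "hu_window")
}

#' Restrict a VOI mask to a CT attenuation window
#'
#' Keeps the voxels of `voi_mask` whose CT value lies in `[lo, hi]`
#' (inclusive). Applied to the muscle VOIs with the 0-250 HU window, this
#' minimizes inclusion of bone and fat in the background sample.
#'
#' @param ct_on_grid [image_volume()] with modality `CT_HU`, already on the
#'   reference grid.
#' @param voi_mask Logical 3-D array on the same grid.
#' @param window An [hu_window()].
#' @return Logical mask; all-`FALSE` with a warning if nothing survives.
#' @export
hu_mask <- function(ct_on_grid, voi_mask, window = hu_window()) {
  stopifnot(inherits(ct_on_grid, "image_volume"), inherits(window, "hu_window"))
  if (ct_on_grid$modality != "CT_HU")
    stop_gq("hu_mask expects a CT_HU volume, got %s", ct_on_grid$modality,
            class = "gq_modality_error")
  if (!identical(dim(ct_on_grid$voxels), dim(voi_mask)))
    stop_gq("CT and VOI mask dimensions differ", class = "gq_geometry_error")
  out <- voi_mask & ct_on_grid$voxels >= window$lo & ct_on_grid$voxels <= window$hi
  if (!any(out))
    warning("HU window [", window$lo, ", ", window$hi,
            "] left an empty mask; downstream SUVpeak is undefined")
  out
}

#' SUVpeak: mean uptake in the hottest 1 cm3 sphere
#'
#' Scans spheres of volume `sphere_volume_ml` centered on every voxel center
#' inside the mask; each sphere is clipped to the mask and must retain at
#' least `min_coverage` of its voxels. Returns the maximum sphere-mean SUV.
#' Ties are broken toward the lowest linear center index, making the result
#' deterministic.
#'
#' @param suv [image_volume()] with modality `PET_SUV`.
#' @param mask Logical 3-D array on the same grid.
#' @param sphere_volume_ml Sphere volume in mL (default 1.0).
#' @param min_coverage Minimum fraction of sphere voxels that must lie inside
#'   the mask for a center to qualify (default 0.5).
#' @return The SUVpeak (scalar), with attributes `center_lin` (linear index
#'   of the winning center) and `n_sphere_voxels`.
#' @export
suv_peak <- function(suv, mask, sphere_volume_ml = 1.0, min_coverage = 0.5) {
  stopifnot(inherits(suv, "image_volume"))
  if (suv$modality != "PET_SUV")
    stop_gq("suv_peak expects a PET_SUV volume, got %s", suv$modality,
            class = "gq_modality_error")
  dm <- dim(suv$voxels)
  if (!identical(dm, dim(mask)))
    stop_gq("SUV and mask dimensions differ", class = "gq_geometry_error")
  vox_ml <- prod(suv$spacing) / 1000
  centers <- which(mask)  # ascending linear index = deterministic tie-break
  if (length(centers) * vox_ml < sphere_volume_ml)
    stop_gq("mask volume %.3f mL is below the %.3f mL sphere",
            length(centers) * vox_ml, sphere_volume_ml,
            class = "gq_insufficient_volume_error")
  r_mm <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)
  off <- sphere_offsets(r_mm, suv$spacing)
  k <- nrow(off)
  need <- min_coverage * k
  vals <- suv$voxels
  best <- -Inf
  best_center <- NA_integer_
  chunk <- max(1L, floor(2e6 / k))
  for (start in seq(1L, length(centers), by = chunk)) {
    cc <- centers[start:min(start + chunk - 1L, length(centers))]
    sub <- lin_to_sub(cc, dm)
    n <- length(cc)
    s1 <- outer(sub[, 1L], off[, 1L], `+`)
    s2 <- outer(sub[, 2L], off[, 2L], `+`)
    s3 <- outer(sub[, 3L], off[, 3L], `+`)
    inside <- s1 >= 1L & s1 <= dm[1L] & s2 >= 1L & s2 <= dm[2L] &
      s3 >= 1L & s3 <= dm[3L]
    lin <- matrix(1L, n, k)
    lin[inside] <- (s1[inside] - 1L) + dm[1L] *
      ((s2[inside] - 1L) + dm[2L] * (s3[inside] - 1L)) + 1L
    valid <- inside & matrix(mask[lin], n, k)
    nvalid <- rowSums(valid)
    v <- matrix(vals[lin], n, k)
    v[!valid] <- 0
    means <- rowSums(v) / nvalid
    means[nvalid < need] <- -Inf
    if (any(means > best)) {
      i <- which.max(means)
      best <- means[i]
      best_center <- cc[i]
    }
  }
  if (!is.finite(best))
    stop_gq("no sphere center reaches %.0f%% mask coverage",
            100 * min_coverage, class = "gq_insufficient_volume_error")
  structure(best, center_lin = best_center, n_sphere_voxels = k)
}

#' Combine left/right muscle SUVpeaks into the graft segmentation threshold
#'
#' The muscle SUVpeak of each side is the background reference; the fixed
#' lower threshold applied to both graft VOIs is their combination under
#' `rule`: `"mean"` (default), `"max"`, or `"per_side"` (each graft VOI uses
#' its own side's muscle peak).
#'
#' @param left,right Muscle SUVpeak values (scalars from [suv_peak()]).
#' @param rule `"mean"`, `"max"` or `"per_side"`.
#' @return A scalar threshold, or for `"per_side"` a named vector
#'   `c(L = left, R = right)`.
#' @export
graft_threshold <- function(left, right, rule = c("mean", "max", "per_side")) {
  rule <- match.arg(rule)
  left <- as.numeric(left); right <- as.numeric(right)
  if (length(left) != 1L || length(right) != 1L ||
      is.na(left) || is.na(right))
    stop_gq("both muscle SUVpeaks are required (rule = %s)", rule,
            class = "gq_threshold_error")
  switch(rule,
         mean = (left + right) / 2,
         max = max(left, right),
         per_side = c(L = left, R = right))
}

#' Fixed-threshold segmentation with minimum-component filtering
#'
#' Voxels inside `voi_mask` with SUV at or above `lower_threshold` are
#' segmented; connected components (26-neighborhood by default) smaller than
#' `min_component_ml` are discarded, suppressing single high-uptake voxels
#' and small separated voxel groups. Metrics are computed on the retained
#' mask.
#'
#' @param suv [image_volume()] with modality `PET_SUV`.
#' @param voi_mask Logical 3-D array on the same grid.
#' @param lower_threshold Fixed lower SUV threshold (> 0); comparison is
#'   inclusive (`>=`).
#' @param min_component_ml Minimum retained component volume in mL
#'   (default 1.0); components at exactly the minimum are retained unless
#'   `strict_min = TRUE`.
#' @param connectivity 26 or 6.
#' @param strict_min Drop components exactly at `min_component_ml`.
#' @param sphere_volume_ml Sphere volume used for the mask SUVpeak metric.
#' @return An object of class `segmentation_result` with fields `mask`,
#'   `components` (data frame: id, n_voxels, volume_ml), `volume_ml`,
#'   `suv_mean`, `suv_max`, `suv_peak`, `suv_total`, `c_suv_total` (`NA`
#'   until [pvc_correct()] is applied) and `threshold_used`. An empty
#'   post-filter mask yields a valid result with zero volume and zero
#'   `suv_total`.
#' @export
threshold_segment <- function(suv, voi_mask, lower_threshold,
                              min_component_ml = 1.0, connectivity = 26L,
                              strict_min = FALSE, sphere_volume_ml = 1.0) {
  stopifnot(inherits(suv, "image_volume"))
  if (suv$modality != "PET_SUV")
    stop_gq("threshold_segment expects PET_SUV, got %s", suv$modality,
            class = "gq_modality_error")
  if (!is.numeric(lower_threshold) || lower_threshold <= 0)
    stop_gq("lower_threshold must be > 0", class = "gq_threshold_error")
  dm <- dim(suv$voxels)
  if (!identical(dm, dim(voi_mask)))
    stop_gq("SUV and VOI mask dimensions differ", class = "gq_geometry_error")
  vox_ml <- prod(suv$spacing) / 1000
  raw <- voi_mask & suv$voxels >= lower_threshold
  labels <- label_components(raw, connectivity)
  nlab <- max(labels)
  keep_mask <- array(FALSE, dm)
  comps <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_ml = numeric(0))
  if (nlab > 0L) {
    counts <- tabulate(labels[labels > 0L], nbins = nlab)
    vols <- counts * vox_ml
    keep <- if (strict_min) vols > min_component_ml else
      vols >= min_component_ml - 1e-12
    kept_ids <- which(keep)
    if (length(kept_ids)) {
      keep_mask <- array(labels %in% kept_ids, dm)
      comps <- data.frame(id = seq_along(kept_ids),
                          n_voxels = counts[kept_ids],
                          volume_ml = vols[kept_ids])
    }
  }
  new_segmentation_result(keep_mask, comps, suv, lower_threshold,
                          sphere_volume_ml)
}

new_segmentation_result <- function(mask, components, suv, threshold,
                                    sphere_volume_ml = 1.0) {
  vox_ml <- prod(suv$spacing) / 1000
  n <- sum(mask)
  volume_ml <- n * vox_ml
  if (n == 0L) {
    res <- list(mask = mask, components = components, volume_ml = 0,
                suv_mean = NA_real_, suv_max = NA_real_, suv_peak = NA_real_,
                suv_total = 0, c_suv_total = NA_real_,
                threshold_used = threshold, voxel_volume_ml = vox_ml,
                spacing = suv$spacing, flags = "empty_mask")
    return(structure(res, class = "segmentation_result"))
  }
  vals <- suv$voxels[mask]
  peak <- if (volume_ml >= sphere_volume_ml) {
    tryCatch(as.numeric(suv_peak(suv, mask, sphere_volume_ml)),
             graftquant_error = function(e) NA_real_)
  } else NA_real_
  structure(list(mask = mask, components = components, volume_ml = volume_ml,
                 suv_mean = mean(vals), suv_max = max(vals), suv_peak = peak,
                 suv_total = mean(vals) * volume_ml, c_suv_total = NA_real_,
                 threshold_used = threshold, voxel_volume_ml = vox_ml,
                 spacing = suv$spacing, flags = character(0)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_result> %.2f mL in %d component(s), ",
                     "threshold %.3f\n"),
              x$volume_ml, nrow(x$components), x$threshold_used))
  cat(sprintf("  SUVmean %.3f  SUVmax %.3f  SUVpeak %.3f\n",
              x$suv_mean, x$suv_max, x$suv_peak))
  cat(sprintf("  SUVtotal %.2f  cSUVtotal %s\n", x$suv_total,
              ifelse(is.na(x$c_suv_total), "(not corrected)",
                     sprintf("%.2f", x$c_suv_total))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Partial volume correction of a segmented uptake total
#'
#' Local-background spill correction under a Gaussian PSF. The background
#' SUV `B` is estimated from a spherical shell around the segmented mask
#' (inner margin `shell_gap_mm`, thickness `shell_thickness_mm`, excluding
#' other segmented voxels); the in-mask recovery fraction `r` is the mean
#' value over the mask of the PSF-convolved mask indicator. The corrected
#' mean is `(observed mean - B (1 - r)) / r`, floored at the observed mean
#' so that a failed spill-in estimate can never reduce the total, and
#' `cSUVtotal = corrected mean x volume`. With FWHM tending to 0, `r` tends
#' to 1 and `cSUVtotal` reduces to `SUVtotal`.
#'
#' @param seg A [threshold_segment()] result with a non-empty mask.
#' @param suv The [image_volume()] the segmentation was computed on.
#' @param psf_fwhm_mm Assumed scanner PSF FWHM in mm (default 6).
#' @param shell_gap_mm,shell_thickness_mm Background shell geometry in mm;
#'   both default to the PSF FWHM and are floored at voxel scale so the
#'   shell always contains at least one ring of voxels.
#' @param exclude_mask Optional logical array of voxels (e.g. other segmented
#'   lesions) to exclude from the background shell.
#' @param r_floor If `r` falls below this floor (default 0.05) the correction
#'   is deemed unstable: `cSUVtotal` falls back to `SUVtotal` and the result
#'   is flagged `pvc_unstable`.
#' @return The `segmentation_result` updated with `c_suv_total`,
#'   `corrected_mean`, `pvc_background`, `pvc_recovery_r` and flags.
#' @export
pvc_correct <- function(seg, suv, psf_fwhm_mm = 6,
                        shell_gap_mm = psf_fwhm_mm,
                        shell_thickness_mm = psf_fwhm_mm,
                        exclude_mask = NULL, r_floor = 0.05) {
  stopifnot(inherits(seg, "segmentation_result"), inherits(suv, "image_volume"))
  if (psf_fwhm_mm < 0)
    stop_gq("psf_fwhm_mm must be >= 0", class = "gq_argument_error")
  if (seg$volume_ml == 0) {
    seg$c_suv_total <- 0
    return(seg)
  }
  mask <- seg$mask
  sp <- seg$spacing
  shell_gap_mm <- max(shell_gap_mm, min(sp))
  shell_thickness_mm <- max(shell_thickness_mm, 2 * max(sp))
  if (psf_fwhm_mm == 0) {
    seg$c_suv_total <- seg$suv_total
    seg$corrected_mean <- seg$suv_mean
    seg$pvc_recovery_r <- 1
    seg$pvc_background <- NA_real_
    return(seg)
  }
  ind <- gaussian_blur(array(as.numeric(mask), dim(mask)), psf_fwhm_mm, sp)
  r <- mean(ind[mask])
  if (r < r_floor) {
    warning(sprintf("PVC recovery fraction %.3g below floor %.2f; %s",
                    r, r_floor, "falling back to uncorrected total"))
    seg$c_suv_total <- seg$suv_total
    seg$pvc_recovery_r <- r
    seg$pvc_background <- NA_real_
    seg$flags <- union(seg$flags, "pvc_unstable")
    return(seg)
  }
  inner <- binary_dilate_mm(mask, shell_gap_mm, sp)
  outer_m <- binary_dilate_mm(mask, shell_gap_mm + shell_thickness_mm, sp)
  shell <- outer_m & !inner
  if (!is.null(exclude_mask)) shell <- shell & !exclude_mask
  if (!any(shell)) {
    warning("empty background shell; PVC falls back to uncorrected total")
    seg$c_suv_total <- seg$suv_total
    seg$flags <- union(seg$flags, "pvc_no_background")
    return(seg)
  }
  B <- mean(suv$voxels[shell])
  corrected <- (seg$suv_mean - B * (1 - r)) / r
  if (corrected < seg$suv_mean) {
    corrected <- seg$suv_mean
    seg$flags <- union(seg$flags, "pvc_clipped")
  }
  seg$corrected_mean <- corrected
  seg$pvc_background <- B
  seg$pvc_recovery_r <- r
  seg$c_suv_total <- corrected * seg$volume_ml
  seg
}

#' Sum graft uptake across levels and sides
#'
#' Per-patient total: sums `suv_total` and `c_suv_total` over all graft
#' segmentation results (all insertion levels, both sides).
#'
#' @param segs A list of [threshold_segment()] results (after
#'   [pvc_correct()] if `c_suv_total` is wanted).
#' @return A list with `suv_total` and `c_suv_total` (SUV.mL) and `n_vois`.
#' @export
patient_graft_uptake <- function(segs) {
  if (inherits(segs, "segmentation_result")) segs <- list(segs)
  if (length(segs) == 0L)
    stop_gq("at least one segmentation result is required",
            class = "gq_argument_error")
  stopifnot(all(vapply(segs, inherits, logical(1), "segmentation_result")))
  list(suv_total = sum(vapply(segs, `[[`, numeric(1), "suv_total")),
       c_suv_total = sum(vapply(segs, `[[`, numeric(1), "c_suv_total")),
       n_vois = length(segs))
}
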