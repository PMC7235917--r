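# Cylindrical VOIs, rasterization, mid-sagittal mirroring and grid resampling.

#' Cylindrical volume of interest
#'
#' An analytic cylinder in world space, rasterizable onto any image grid.
#' Muscle VOIs are placed in the erector spinae below rib 12 and above the
#' graft region (target volume 20 cm3); graft VOIs cover the bilateral graft
#' beds. The right-sided VOI is conventionally the mirror image of the left
#' ([mirror_voi()]), keeping dimensions identical.
#'
#' @param label One of `"muscle_L"`, `"muscle_R"`, `"graft_L"`, `"graft_R"`.
#' @param center Cylinder center in world mm (LPS), length 3.
#' @param axis Cylinder axis direction (normalized internally), length 3.
#' @param radius_mm,height_mm Cylinder radius and height in mm.
#' @param level Insertion level index (1 = most cranial operated level).
#' @return An object of class `cylinder_voi` with analytic `volume_ml`.
#' @export
cylinder_voi <- function(label, center, axis = c(0, 0, 1),
                         radius_mm, height_mm, level = 1L) {
  label <- match.arg(label, c("muscle_L", "muscle_R", "graft_L", "graft_R"))
  check_scalar_pos(radius_mm, "radius_mm")
  check_scalar_pos(height_mm, "height_mm")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop_gq("axis must be non-zero", class = "gq_argument_error")
  structure(list(label = label, center = as.numeric(center), axis = axis / nrm,
                 radius_mm = radius_mm, height_mm = height_mm,
                 level = as.integer(level),
                 volume_ml = pi * radius_mm^2 * height_mm / 1000),
            class = "cylinder_voi")
}

#' @export
print.cylinder_voi <- function(x, ...) {
  cat(sprintf("<cylinder_voi> %s level %d: r %.1f mm, h %.1f mm (%.1f mL)\n",
              x$label, x$level, x$radius_mm, x$height_mm, x$volume_ml))
  invisible(x)
}

#' Rasterize a cylindrical VOI onto an image grid
#'
#' A voxel belongs to the mask iff its center lies inside the cylinder
#' (center-inside rule, no partial-voxel weighting). The mask volume is the
#' voxel count times the voxel volume; it converges to the analytic
#' `pi r^2 h` as the grid is refined.
#'
#' @param voi A [cylinder_voi()].
#' @param grid An [image_volume()] supplying the target geometry.
#' @return A logical 3-D array matching `dim(grid)`. Attribute `volume_ml`
#'   holds the rasterized volume. An empty intersection yields an all-`FALSE`
#'   mask with a warning.
#' @export
rasterize_voi <- function(voi, grid) {
  stopifnot(inherits(voi, "cylinder_voi"), inherits(grid, "image_volume"))
  dm <- dim(grid$voxels)
  # bounding box in index space to avoid touching every voxel
  half_diag <- sqrt(voi$radius_mm^2 + (voi$height_mm / 2)^2)
  ctr_idx <- drop(world_to_index(grid, matrix(voi$center, 1L)))
  pad <- ceiling(half_diag / grid$spacing) + 1
  lo <- pmax(1L, floor(ctr_idx + 1 - pad))
  hi <- pmin(dm, ceiling(ctr_idx + 1 + pad))
  mask <- array(FALSE, dm)
  if (any(lo > hi)) {
    warning("VOI '", voi$label, "' does not intersect the grid; empty mask")
    attr(mask, "volume_ml") <- 0
    return(mask)
  }
  sub <- as.matrix(expand.grid(i = lo[1L]:hi[1L], j = lo[2L]:hi[2L],
                               k = lo[3L]:hi[3L]))
  w <- index_to_world(grid, sub)
  d <- sweep(w, 2L, voi$center, `-`)
  along <- d %*% voi$axis
  rad2 <- rowSums(d^2) - along^2
  inside <- abs(along) <= voi$height_mm / 2 + 1e-9 &
    rad2 <= voi$radius_mm^2 + 1e-9
  mask[sub_to_lin(sub[inside, , drop = FALSE], dm)] <- TRUE
  if (!any(mask))
    warning("VOI '", voi$label, "' does not intersect the grid; empty mask")
  attr(mask, "volume_ml") <- sum(mask) * voxel_volume_ml(grid)
  mask
}

#' Mirror a VOI across the mid-sagittal plane
#'
#' Reflects center and axis across the plane `x = sagittal_plane_x` and swaps
#' the `_L`/`_R` side in the label; radius and height are unchanged, so the
#' right-sided VOI keeps the dimensions of its left-sided counterpart.
#'
#' @param voi A [cylinder_voi()].
#' @param sagittal_plane_x World x (mm) of the mid-sagittal plane.
#' @return The mirrored [cylinder_voi()].
#' @export
mirror_voi <- function(voi, sagittal_plane_x) {
  stopifnot(inherits(voi, "cylinder_voi"))
  ctr <- voi$center
  ctr[1L] <- 2 * sagittal_plane_x - ctr[1L]
  ax <- voi$axis
  ax[1L] <- -ax[1L]
  lab <- if (grepl("_L$", voi$label)) sub("_L$", "_R", voi$label)
         else sub("_R$", "_L", voi$label)
  cylinder_voi(lab, ctr, ax, voi$radius_mm, voi$height_mm, voi$level)
}

#' Resample a moving image onto a reference grid
#'
#' Pulls voxel values of `moving` onto the voxel centers of `reference`
#' through a rigid transform mapping moving world space to reference world
#' space (e.g. the fused PET-to-CT transform). Out-of-field voxels receive
#' `fill` (default: -1000 HU for CT, 0 otherwise).
#'
#' @param moving [image_volume()] to resample.
#' @param transform `rigid_transform` mapping `moving` world coordinates into
#'   `reference` world coordinates (identity by default).
#' @param reference [image_volume()] supplying the output geometry.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill Fill value outside the moving field of view.
#' @return An [image_volume()] on the reference grid with `moving`'s modality.
#' @export
resample_to_grid <- function(moving, transform = rigid_transform(),
                             reference, interpolation = c("trilinear", "nearest"),
                             fill = if (moving$modality == "CT_HU") -1000 else 0) {
  stopifnot(inherits(moving, "image_volume"), inherits(reference, "image_volume"))
  interpolation <- match.arg(interpolation)
  dm_ref <- dim(reference$voxels)
  sub <- as.matrix(expand.grid(i = seq_len(dm_ref[1L]), j = seq_len(dm_ref[2L]),
                               k = seq_len(dm_ref[3L])))
  w_ref <- index_to_world(reference, sub)
  w_mov <- apply_rigid(invert_rigid(transform), w_ref)
  idx <- world_to_index(moving, w_mov)  # continuous 0-based
  dm <- dim(moving$voxels)
  vals <- rep(fill, nrow(idx))
  if (interpolation == "nearest") {
    ni <- round(idx) + 1
    ok <- ni[, 1L] >= 1 & ni[, 1L] <= dm[1L] & ni[, 2L] >= 1 &
      ni[, 2L] <= dm[2L] & ni[, 3L] >= 1 & ni[, 3L] <= dm[3L]
    vals[ok] <- moving$voxels[sub_to_lin(ni[ok, , drop = FALSE], dm)]
  } else {
    # in-field: within half a voxel of the sampled grid; values are clamped
    # to the grid hull so edge voxel centers resolve exactly
    ok <- idx[, 1L] > -0.5 & idx[, 1L] < dm[1L] - 0.5 &
      idx[, 2L] > -0.5 & idx[, 2L] < dm[2L] - 0.5 &
      idx[, 3L] > -0.5 & idx[, 3L] < dm[3L] - 0.5
    if (any(ok)) {
      cl <- pmin(pmax(idx[ok, , drop = FALSE], 0),
                 matrix(dm - 1, sum(ok), 3L, byrow = TRUE))
      base <- pmin(floor(cl), matrix(dm - 2L, sum(ok), 3L, byrow = TRUE))
      base <- pmax(base, 0)  # degenerate single-voxel axes
      frac <- cl - base
      b <- base + 1  # 1-based lower corner
      fx <- frac[, 1L]; fy <- frac[, 2L]; fz <- frac[, 3L]
      v <- moving$voxels
      acc <- numeric(sum(ok))
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wgt <- (if (dx == 1) fx else 1 - fx) *
               (if (dy == 1) fy else 1 - fy) *
               (if (dz == 1) fz else 1 - fz)
        corner <- cbind(pmin(b[, 1L] + dx, dm[1L]),
                        pmin(b[, 2L] + dy, dm[2L]),
                        pmin(b[, 3L] + dz, dm[3L]))
        acc <- acc + wgt * v[sub_to_lin(corner, dm)]
      }
      vals[ok] <- acc
    }
  }
  out <- reference
  out$voxels <- array(vals, dm_ref)
  out$modality <- moving$modality
  out
}

#' Center a graft VOI on the local uptake centroid
#'
#' Optional placement helper: within an axis-aligned world-space search box,
#' recenters the cylinder on the SUV-weighted centroid. This emulates the
#' observer's "best fit" toward the volume of high uptake, but placement
#' remains an input — the helper is never invoked implicitly.
#'
#' @param voi A [cylinder_voi()].
#' @param suv [image_volume()] with modality `PET_SUV`.
#' @param box_lo,box_hi World-space corners (mm) of the search box.
#' @return The recentered [cylinder_voi()].
#' @export
center_voi_on_uptake <- function(voi, suv, box_lo, box_hi) {
  stopifnot(inherits(voi, "cylinder_voi"), inherits(suv, "image_volume"))
  dm <- dim(suv$voxels)
  sub <- as.matrix(expand.grid(i = seq_len(dm[1L]), j = seq_len(dm[2L]),
                               k = seq_len(dm[3L])))
  w <- index_to_world(suv, sub)
  inside <- w[, 1L] >= box_lo[1L] & w[, 1L] <= box_hi[1L] &
    w[, 2L] >= box_lo[2L] & w[, 2L] <= box_hi[2L] &
    w[, 3L] >= box_lo[3L] & w[, 3L] <= box_hi[3L]
  if (!any(inside))
    stop_gq("search box does not intersect the image", class = "gq_geometry_error")
  wt <- pmax(suv$voxels[sub_to_lin(sub[inside, , drop = FALSE], dm)], 0)
  if (sum(wt) <= 0) return(voi)
  ctr <- colSums(w[inside, , drop = FALSE] * wt) / sum(wt)
  cylinder_voi(voi$label, ctr, voi$axis, voi$radius_mm, voi$height_mm, voi$level)
}
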