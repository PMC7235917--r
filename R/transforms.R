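# Rigid world-space transforms for PET/CT fusion.
#
# A transform maps world points p (LPS mm) as  p' = R (p - c) + c + t,
# with R a rotation built from intrinsic z-y-x Euler angles in degrees,
# c the rotation center and t a translation. This parameterisation keeps
# config files (rotations in the three planes + shifts) human-readable.

#' Rigid transform from Euler angles and translations
#'
#' @param rotations_deg Intrinsic z-y-x Euler angles in degrees, length 3
#'   (applied as Rz then Ry then Rx about the rotation center).
#' @param translations_mm Translation in mm, length 3.
#' @param center_mm Rotation center in world mm (default origin).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations_deg = c(0, 0, 0),
                            translations_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  r <- as.numeric(rotations_deg) * pi / 180
  cz <- cos(r[1L]); sz <- sin(r[1L])
  cy <- cos(r[2L]); sy <- sin(r[2L])
  cx <- cos(r[3L]); sx <- sin(r[3L])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  new_rigid(Rz %*% Ry %*% Rx, as.numeric(translations_mm), as.numeric(center_mm))
}

new_rigid <- function(R, t, center = c(0, 0, 0)) {
  structure(list(R = R, t = t, center = center), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation matrix:\n")
  print(signif(x$R, 6))
  cat(sprintf("  translation (%s) mm, center (%s) mm\n",
              paste(signif(x$t, 5), collapse = ", "),
              paste(signif(x$center, 5), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' @param tf A `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of world points, mm.
#' @return Transformed points, same shape.
#' @export
apply_rigid <- function(tf, pts) {
  vec <- is.null(dim(pts))
  pts <- matrix(pts, ncol = 3L)
  out <- sweep(sweep(pts, 2L, tf$center, `-`) %*% t(tf$R), 2L,
               tf$center + tf$t, `+`)
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_rigid <- function(tf) {
  # p = R^T (p' - c - t) + c  ==  R^T (p' - c) + c + (-R^T t)
  new_rigid(t(tf$R), -t(tf$R) %*% tf$t, tf$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `first`, then `second`.
#' @param first,second `rigid_transform` objects.
#' @return The composed `rigid_transform` (expressed about `first`'s center).
#' @export
compose_rigid <- function(first, second) {
  # linear part is R2 R1; translation fixed by tracking first's center
  R <- second$R %*% first$R
  p0 <- first$center
  image_p0 <- apply_rigid(second, apply_rigid(first, p0))
  new_rigid(R, as.numeric(image_p0 - p0), p0)
}

#' Header-implied rigid transform mapping PET world space onto CT world space
#'
#' Derived purely from the two volume headers: the rotation aligns the PET
#' direction matrix with the CT direction matrix and the translation aligns
#' the grid origins. When both volumes sit in the same frame of reference
#' (identical orientation and origin) the result is the identity. This is
#' the metadata-only fusion step; residual misalignment is corrected with
#' [refine_rigid()].
#'
#' @param pet,ct [image_volume()] objects with world geometry.
#' @return A `rigid_transform` mapping PET world coordinates to CT world
#'   coordinates.
#' @export
fuse_from_metadata <- function(pet, ct) {
  if (!inherits(pet, "image_volume") || !inherits(ct, "image_volume"))
    stop_gq("fuse_from_metadata needs two image_volume objects",
            class = "gq_metadata_error")
  R <- ct$orientation %*% t(pet$orientation)
  t <- ct$origin - as.numeric(R %*% pet$origin)
  new_rigid(R, t, c(0, 0, 0))
}

#' Refine a header-based fusion with a manual rigid adjustment
#'
#' Composes the initial (metadata) transform with an adjustment supplied in
#' the run config — the reproducible equivalent of interactively nudging the
#' overlay for best fit.
#'
#' @param initial `rigid_transform` from [fuse_from_metadata()].
#' @param adjustment `rigid_transform` applied after `initial`.
#' @return The composed `rigid_transform`.
#' @export
refine_rigid <- function(initial, adjustment) {
  compose_rigid(initial, adjustment)
}
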