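# Internal helpers shared across modules: index arithmetic on 3-D grids and
# small argument checks. Voxel indices are 0-based in world-mapping formulas
# and 1-based wherever they index R arrays; helpers state which they use.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gq <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "graftquant_error")))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_gq("'%s' must be a positive finite scalar", name, class = "gq_argument_error")
  invisible(x)
}

# 1-based array subscripts (n x 3 integer matrix) -> linear indices
sub_to_lin <- function(sub, dm) {
  (sub[, 1L] - 1L) + dm[1L] * ((sub[, 2L] - 1L) + dm[2L] * (sub[, 3L] - 1L)) + 1L
}

# linear indices -> 1-based n x 3 subscripts
lin_to_sub <- function(lin, dm) {
  lin0 <- lin - 1L
  i <- lin0 %% dm[1L]
  j <- (lin0 %/% dm[1L]) %% dm[2L]
  k <- lin0 %/% (dm[1L] * dm[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

# Offsets (in voxels, integer n x 3) of all voxels whose centers lie within
# radius_mm of a voxel center, under anisotropic spacing. Includes (0,0,0).
sphere_offsets <- function(radius_mm, spacing) {
  nmax <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  g <- expand.grid(di = -nmax[1L]:nmax[1L],
                   dj = -nmax[2L]:nmax[2L],
                   dk = -nmax[3L]:nmax[3L])
  d2 <- (g$di * spacing[1L])^2 + (g$dj * spacing[2L])^2 + (g$dk * spacing[3L])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000
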