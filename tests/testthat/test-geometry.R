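test_that("rasterized cylinder volume approaches pi r^2 h under refinement", {
  # generic (grid-incommensurate) placement of a 20 cm3 cylinder
  voi <- cylinder_voi("muscle_L", c(25.3, 24.7, 45.2), c(0.15, 0.08, 1),
                      10, 63.662)
  errs <- vapply(c(1, 0.5), function(sp) {
    g <- image_volume(array(0, ceiling(c(55, 55, 95) / sp)), rep(sp, 3),
                      modality = "PET_SUV")
    m <- rasterize_voi(voi, g)
    abs(attr(m, "volume_ml") - voi$volume_ml) / voi$volume_ml
  }, numeric(1))
  expect_lt(errs[1], 0.02)
  expect_lt(errs[2], errs[1])
})

test_that("rasterization uses the center-inside rule", {
  g <- image_volume(array(0, c(10, 10, 10)), c(1, 1, 1), modality = "PET_SUV")
  # radius below half the voxel edge, centered between voxel centers
  voi <- cylinder_voi("graft_L", c(4.5, 4.5, 4.5), c(0, 0, 1), 0.4, 0.8)
  expect_warning(m <- rasterize_voi(voi, g), "empty mask")
  expect_false(any(m))
  expect_equal(attr(m, "volume_ml"), 0)
  # a cylinder covering exactly one column of voxel centers
  voi2 <- cylinder_voi("graft_L", c(4, 4, 4), c(0, 0, 1), 0.6, 2.5)
  m2 <- rasterize_voi(voi2, g)
  expect_equal(sum(m2), 3L)  # z = 3, 4, 5
})

test_that("mirroring reflects geometry, swaps sides and is an involution", {
  voi <- cylinder_voi("muscle_L", c(61, 40, 20), c(1, 0, 0), 8, 30, level = 2L)
  m <- mirror_voi(voi, 31)
  expect_equal(m$center, c(1, 40, 20))
  expect_equal(m$axis, c(-1, 0, 0))
  expect_identical(m$label, "muscle_R")
  expect_equal(m$radius_mm, voi$radius_mm)
  expect_equal(m$height_mm, voi$height_mm)
  back <- mirror_voi(m, 31)
  expect_equal(back$center, voi$center)
  expect_equal(back$axis, voi$axis)
  expect_identical(back$label, "muscle_L")
  # axis parallel to the plane is unchanged
  voi_z <- cylinder_voi("graft_L", c(50, 10, 10), c(0, 0, 1), 5, 10)
  expect_equal(mirror_voi(voi_z, 31)$axis, c(0, 0, 1))
})

test_that("mirroring preserves mask voxel count on a symmetric grid", {
  g <- image_volume(array(0, c(41, 21, 21)), c(1, 1, 1), modality = "PET_SUV")
  plane_x <- 20  # world x of the central voxel column
  voi <- cylinder_voi("muscle_L", c(28.3, 10.2, 10.1), c(0.2, 0.1, 1), 4, 12)
  m_l <- rasterize_voi(voi, g)
  m_r <- rasterize_voi(mirror_voi(voi, plane_x), g)
  expect_equal(sum(m_r), sum(m_l))
})

test_that("rigid transforms compose, invert and preserve distances", {
  tf <- rigid_transform(c(10, -5, 3), c(4, -2, 7), c(30, 20, 10))
  inv <- invert_rigid(tf)
  pts <- matrix(runif(60, -50, 50), 20)
  expect_lt(max(abs(apply_rigid(inv, apply_rigid(tf, pts)) - pts)), 1e-9)
  d_before <- as.matrix(dist(pts))
  d_after <- as.matrix(dist(apply_rigid(tf, pts)))
  expect_lt(max(abs(d_before - d_after)), 1e-6)
  # refine: identity adjustment, summed translations, group inverse
  expect_lt(max(abs(apply_rigid(refine_rigid(tf, rigid_transform()), pts) -
                      apply_rigid(tf, pts))), 1e-9)
  t1 <- rigid_transform(translations_mm = c(1, 2, 3))
  t2 <- rigid_transform(translations_mm = c(-4, 1, 0.5))
  expect_equal(apply_rigid(refine_rigid(t1, t2), c(0, 0, 0)),
               c(-3, 3, 3.5))
  undone <- refine_rigid(refine_rigid(tf, t1), invert_rigid(t1))
  expect_lt(max(abs(apply_rigid(undone, pts) - apply_rigid(tf, pts))), 1e-9)
})

test_that("metadata fusion recovers header-implied alignment", {
  same <- image_volume(array(0, c(4, 4, 4)), c(2, 2, 2), origin = c(1, 2, 3),
                       modality = "CT_HU")
  tf0 <- fuse_from_metadata(same, same)
  expect_lt(max(abs(tf0$R - diag(3))), 1e-12)
  expect_lt(max(abs(tf0$t)), 1e-12)
  pet <- image_volume(array(0, c(4, 4, 4)), c(2, 2, 2), origin = c(1, 2, 8),
                      modality = "PET_BQML")
  expect_equal(fuse_from_metadata(pet, same)$t, c(0, 0, -5))
  # a phantom pair written with a known misalignment: fusion inverts it
  M <- rigid_transform(c(2, -1, 0.5), c(3, -1, 2), c(79, 59, 59))
  ph <- generate_phantom(default_phantom_spec(psf_fwhm_mm = 0,
                                              misalignment = M))
  rec <- fuse_from_metadata(ph$pet, ph$ct)
  Minv <- invert_rigid(M)
  pts <- matrix(runif(30, 0, 120), 10)
  expect_lt(max(abs(apply_rigid(rec, pts) - apply_rigid(Minv, pts))), 1e-3)
})

test_that("resampling reproduces identity, constants and exact shifts", {
  set.seed(5)
  vol <- image_volume(array(runif(8 * 9 * 7), c(8, 9, 7)), c(2, 2, 2),
                      modality = "PET_SUV")
  same <- resample_to_grid(vol, rigid_transform(), vol)
  expect_equal(same$voxels, vol$voxels, tolerance = 1e-12)
  # constants stay constant in the interior under any rigid transform
  const <- image_volume(array(3.7, c(30, 30, 30)), c(2, 2, 2),
                        modality = "PET_SUV")
  tf <- rigid_transform(c(5, 3, -2), c(1.3, -0.7, 2.1), c(29, 29, 29))
  res <- resample_to_grid(const, tf, const)
  interior <- res$voxels[10:20, 10:20, 10:20]
  expect_lt(max(abs(interior - 3.7)), 1e-9)
  # one-voxel translation with nearest neighbor is an exact shift
  shift <- rigid_transform(translations_mm = c(2, 0, 0))
  sh <- resample_to_grid(vol, shift, vol, interpolation = "nearest")
  expect_equal(sh$voxels[2:8, , ], vol$voxels[1:7, , ])
})
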