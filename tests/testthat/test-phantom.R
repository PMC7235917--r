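test_that("noise-free unblurred phantom PET equals the rasterized truth", {
  ph <- generate_phantom(default_phantom_spec(psf_fwhm_mm = 0,
                                              noise_scale = 0))
  suv <- to_suv(ph$pet, ph$calibration)
  expect_equal(suv$voxels, ph$suv_truth, tolerance = 1e-12)
  # declared truth volumes match the region masks exactly
  for (i in seq_len(nrow(ph$truth))) {
    m <- ph$region_masks[[ph$truth$label[i]]]
    expect_equal(sum(m), ph$truth$n_voxels[i])
  }
  expect_true(all(ph$truth$true_suv[grep("graft", ph$truth$label)] >
                    ph$truth$true_suv[grep("muscle", ph$truth$label)]))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(default_phantom_spec(noise_scale = 0.02, seed = 9))
  b <- generate_phantom(default_phantom_spec(noise_scale = 0.02, seed = 9))
  expect_identical(a$pet$voxels, b$pet$voxels)
  expect_identical(a$ct$voxels, b$ct$voxels)
  c_ <- generate_phantom(default_phantom_spec(noise_scale = 0.02, seed = 10))
  expect_false(identical(a$pet$voxels, c_$pet$voxels))
})

test_that("PSF blur conserves total phantom activity away from the edge", {
  spec <- default_phantom_spec(psf_fwhm_mm = 6, noise_scale = 0)
  ph <- generate_phantom(spec)
  suv_blurred <- to_suv(ph$pet, ph$calibration)$voxels
  # graft spheres sit well inside the field: compare their neighbourhoods
  box <- function(arr, mask) {
    sub <- which(mask, arr.ind = TRUE)
    lo <- pmax(apply(sub, 2, min) - 8, 1)
    hi <- pmin(apply(sub, 2, max) + 8, dim(arr))
    sum(arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }
  m <- ph$region_masks$graft_L
  expect_lt(abs(box(suv_blurred, m) - box(ph$suv_truth, m)) /
              box(ph$suv_truth, m), 0.005)
})

test_that("the 0-250 HU window recovers exactly the muscle voxels", {
  ph <- generate_phantom(default_phantom_spec(noise_scale = 0))
  voi <- cylinder_voi("muscle_L", c(109, 78, 85), c(0, 0, 1), 10, 63.662)
  mask <- hu_mask(ph$ct, rasterize_voi(voi, ph$ct))
  expect_identical(mask, ph$region_masks$muscle_L &
                     rasterize_voi(voi, ph$ct))
})

test_that("segmenting the noise-free blurred phantom recovers graft volume", {
  ph <- generate_phantom(default_phantom_spec(psf_fwhm_mm = 6,
                                              noise_scale = 0))
  suv <- to_suv(ph$pet, ph$calibration)
  voi <- cylinder_voi("graft_L", c(111, 75, 30), c(0, 0, 1), 14, 32.5)
  seg <- threshold_segment(suv, rasterize_voi(voi, ph$ct), 2)
  true_vol <- ph$truth$volume_ml[ph$truth$label == "graft_L"]
  expect_lt(abs(seg$volume_ml - true_vol) / true_vol, 0.15)
})

test_that("overlapping phantom regions resolve by declaration order", {
  spec <- phantom_spec(
    dim = c(20, 20, 20), spacing_mm = c(2, 2, 2),
    body = list(center = c(19, 19), semiaxes = c(30, 30), hu = 40, suv = 0.5),
    regions = list(
      phantom_region("first", "sphere", hu = 100, suv = 2,
                     center = c(19, 19, 19), radius_mm = 8),
      phantom_region("second", "sphere", hu = 200, suv = 4,
                     center = c(23, 19, 19), radius_mm = 8)),
    psf_fwhm_mm = 0)
  expect_message(ph <- generate_phantom(spec), "already claimed")
  overlap <- ph$region_masks$first & ph$region_masks$second
  expect_false(any(overlap))
  expect_equal(ph$suv_truth[10, 10, 10], 2)  # center voxel kept by 'first'
})

test_that("synthetic cohorts respect instrument bounds and the fused rate", {
  big <- generate_cohort(cohort_spec(n = 5000, seed = 3))
  expect_true(all(big$vas_b_12m >= 0 & big$vas_b_12m <= 10))
  expect_true(all(big$vas_l_12m >= 0 & big$vas_l_12m <= 10))
  expect_true(all(big$tan_bs >= 0 & big$tan_bs <= 30 &
                    big$tan_12m >= 0 & big$tan_12m <= 30))
  expect_true(all(big$odi_12m >= 0 & big$odi_12m <= 100))
  expect_true(all(big$eq5d_12m <= 1))
  expect_true(all(big$wlk_d_12m >= 0))
  expect_true(all(big$suv_total > 0))
  expect_equal(mean(big$fused), 4 / 18, tolerance = 0.1)
  small <- generate_cohort(cohort_spec(n = 18, seed = 1))
  expect_equal(nrow(small), 18L)
  expect_identical(small, generate_cohort(cohort_spec(n = 18, seed = 1)))
})

test_that("zero uptake effect leaves fused and unfused uptake alike in law", {
  ch <- generate_cohort(cohort_spec(n = 4000, effect_suv_total = 0,
                                    seed = 21))
  ks <- suppressWarnings(stats::ks.test(ch$suv_total[ch$fused],
                                        ch$suv_total[!ch$fused]))
  expect_gt(ks$p.value, 0.001)
  shifted <- generate_cohort(cohort_spec(n = 4000, effect_suv_total = -300,
                                         seed = 21))
  expect_lt(median(shifted$suv_total[shifted$fused]),
            median(shifted$suv_total[!shifted$fused]))
})
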