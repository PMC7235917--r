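test_that("HU windowing keeps muscle and rejects bone and fat", {
  dm <- c(12, 12, 12)
  hu <- array(50, dm)                      # uniform muscle
  hu[7:12, , ] <- 700                      # bone half
  ct <- image_volume(hu, c(2, 2, 2), modality = "CT_HU")
  voi <- array(FALSE, dm); voi[4:9, 4:9, 4:9] <- TRUE
  m <- hu_mask(ct, voi)
  expect_equal(sum(m), sum(voi[4:6, 4:9, 4:9]))        # muscle half only
  expect_true(all(which(m, arr.ind = TRUE)[, 1] <= 6))
  # uniform muscle -> mask equals the VOI
  ct2 <- image_volume(array(50, dm), c(2, 2, 2), modality = "CT_HU")
  expect_equal(hu_mask(ct2, voi), voi)
  # fat only -> empty mask with a warning
  ct3 <- image_volume(array(-100, dm), c(2, 2, 2), modality = "CT_HU")
  expect_warning(m3 <- hu_mask(ct3, voi), "empty")
  expect_false(any(m3))
})

test_that("SUVpeak reproduces closed forms on constructed fields", {
  dm <- c(14, 14, 14); sp <- c(2, 2, 2)
  # constant field: peak equals the constant
  suv <- make_suv(array(2, dm), sp)
  mask <- array(TRUE, dm)
  expect_equal(as.numeric(suv_peak(suv, mask)), 2)
  # single hot voxel: peak = (10 + (k - 1)) / k with k sphere voxels
  vox <- array(1, dm); vox[7, 7, 7] <- 10
  k <- attr(suv_peak(make_suv(vox, sp), mask), "n_sphere_voxels")
  expect_equal(as.numeric(suv_peak(make_suv(vox, sp), mask)),
               (10 + (k - 1)) / k)
  # mask below the sphere volume errors
  small <- array(FALSE, dm); small[1:2, 1, 1] <- TRUE
  expect_error(suv_peak(suv, small), class = "gq_insufficient_volume_error")
})

test_that("SUVpeak equals the exhaustive brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    dm <- c(sample(8:14, 1), sample(8:14, 1), sample(8:14, 1))
    sp <- rep(sample(c(3, 4, 5), 1), 3)
    vox <- array(runif(prod(dm), 0, 4), dm)
    mask <- array(runif(prod(dm)) < 0.75, dm)
    suv <- make_suv(vox, sp)
    want <- oracle_suv_peak(vox, mask, sp)
    if (!is.finite(want$peak)) next
    got <- suv_peak(suv, mask)
    expect_equal(as.numeric(got), want$peak, tolerance = 1e-12,
                 label = sprintf("seed %d", seed))
    expect_identical(attr(got, "center_lin"), want$center)
  }
})

test_that("graft threshold combines the two muscle peaks per rule", {
  expect_equal(graft_threshold(1.2, 1.2), 1.2)
  expect_equal(graft_threshold(1.0, 1.4, "mean"), 1.2)
  expect_equal(graft_threshold(1.0, 1.4, "max"), 1.4)
  expect_equal(graft_threshold(1.0, 1.4, "per_side"), c(L = 1.0, R = 1.4))
  expect_error(graft_threshold(NA, 1.4, "per_side"),
               class = "gq_threshold_error")
  expect_error(graft_threshold(NA, 1.4, "mean"), class = "gq_threshold_error")
})

test_that("threshold segmentation filters small components and fills metrics", {
  dm <- c(20, 20, 20); sp <- c(2, 2, 2)  # voxel = 8 uL
  # uniform field: mask = VOI, totals are exact
  voi <- array(FALSE, dm); voi[5:14, 5:14, 5:14] <- TRUE
  seg <- threshold_segment(make_suv(array(3, dm), sp), voi, 2)
  expect_equal(seg$volume_ml, 1000 * 0.008)
  expect_equal(seg$suv_mean, 3)
  expect_equal(seg$suv_total, 3 * seg$volume_ml)
  # one isolated supra-threshold voxel (8 uL < 1 mL) is removed
  vox <- array(0.5, dm); vox[10, 10, 10] <- 50
  seg2 <- threshold_segment(make_suv(vox, sp), array(TRUE, dm), 2)
  expect_equal(seg2$volume_ml, 0)
  expect_equal(seg2$suv_total, 0)
  expect_true("empty_mask" %in% seg2$flags)
  # 0.5 mL and 2.0 mL blobs: only the large one survives
  vox3 <- array(0.5, dm)
  vox3[2:5, 2:5, 2:5] <- 5          # 64 vox = 0.512 mL
  vox3[10:15, 10:15, 10:16] <- 5    # 252 vox = 2.016 mL
  seg3 <- threshold_segment(make_suv(vox3, sp), array(TRUE, dm), 2)
  expect_equal(nrow(seg3$components), 1L)
  expect_equal(seg3$volume_ml, 252 * 0.008)
  expect_false(seg3$mask[3, 3, 3])
  expect_true(seg3$mask[12, 12, 12])
})

test_that("retained voxel sets match the flood-fill oracle after filtering", {
  for (seed in 1:6) {
    dm <- c(14, 14, 14); sp <- c(3, 3, 3)  # voxel 27 uL
    vox <- random_blob_field(dm, sp, n_blobs = 4, seed = seed)
    suv <- make_suv(vox, sp)
    thr <- 1.5
    seg <- threshold_segment(suv, array(TRUE, dm), thr)
    raw <- vox >= thr
    lab <- oracle_components(array(raw, dm), 26L)
    keep <- array(FALSE, dm)
    if (max(lab) > 0) {
      counts <- tabulate(lab[lab > 0])
      for (id in which(counts * prod(sp) / 1000 >= 1.0)) keep[lab == id] <- TRUE
    }
    expect_identical(seg$mask, keep, label = sprintf("seed %d", seed))
  }
})

test_that("segmentation is monotone in threshold and in the component filter", {
  dm <- c(16, 16, 16); sp <- c(2.5, 2.5, 2.5)
  vox <- random_blob_field(dm, sp, n_blobs = 5, seed = 42)
  suv <- make_suv(vox, sp)
  prev_vol <- Inf; prev_tot <- Inf
  for (thr in c(0.8, 1.2, 1.8, 2.6)) {
    seg <- threshold_segment(suv, array(TRUE, dm), thr)
    expect_lte(seg$volume_ml, prev_vol)
    expect_lte(seg$suv_total, prev_tot + 1e-9)
    prev_vol <- seg$volume_ml; prev_tot <- seg$suv_total
  }
  all_comp <- threshold_segment(suv, array(TRUE, dm), 1.5,
                                min_component_ml = 0)
  filt <- threshold_segment(suv, array(TRUE, dm), 1.5, min_component_ml = 1)
  expect_true(all(all_comp$mask[filt$mask]))
})

test_that("SUVmean <= SUVpeak <= SUVmax on non-empty results >= 1 cm3", {
  for (seed in 1:5) {
    dm <- c(15, 15, 15); sp <- c(3, 3, 3)
    vox <- random_blob_field(dm, sp, n_blobs = 3, seed = seed + 100)
    seg <- threshold_segment(make_suv(vox, sp), array(TRUE, dm), 1.0)
    if (seg$volume_ml < 1 || is.na(seg$suv_peak)) next
    expect_lte(seg$suv_mean, seg$suv_peak + 1e-12)
    expect_lte(seg$suv_peak, seg$suv_max + 1e-12)
    expect_equal(seg$suv_total, seg$suv_mean * seg$volume_ml,
                 tolerance = 1e-6)
  }
})

test_that("partial volume correction recovers true means on blurred spheres", {
  sp <- c(2, 2, 2); dmv <- c(44, 44, 44)
  grid <- image_volume(array(0, dmv), sp, modality = "PET_SUV")
  recover <- function(diam_mm, fwhm) {
    reg <- phantom_region("s", "sphere", hu = 0, suv = 4,
                          center = c(43, 43, 43), radius_mm = diam_mm / 2)
    mask <- graftquant:::rasterize_region(reg, grid)
    tru <- array(1, dmv); tru[mask] <- 4
    suv <- image_volume(gaussian_blur(tru, fwhm, sp), sp,
                        modality = "PET_SUV")
    seg <- graftquant:::new_segmentation_result(
      mask, data.frame(id = 1L, n_voxels = sum(mask),
                       volume_ml = sum(mask) * prod(sp) / 1000), suv, 1)
    pvc_correct(seg, suv, fwhm)
  }
  big <- recover(40, 6)
  expect_lt(abs(big$corrected_mean - 4) / 4, 0.05)
  expect_lt(big$suv_mean, big$corrected_mean)
  # halving the diameter: correction still at least as close as uncorrected
  small <- recover(20, 6)
  expect_lte(abs(small$corrected_mean - 4), abs(small$suv_mean - 4))
  # fwhm -> 0: correction is a no-op
  none <- recover(20, 0)
  expect_equal(none$c_suv_total, none$suv_total)
})

test_that("PVC degrades safely on empty and unstable input", {
  dm <- c(16, 16, 16); sp <- c(2, 2, 2)
  suv <- make_suv(array(1, dm), sp)
  empty <- threshold_segment(suv, array(FALSE, dm), 5)
  expect_equal(pvc_correct(empty, suv, 6)$c_suv_total, 0)
  # a tiny mask under a huge PSF drives r below the floor -> fallback
  tiny <- array(FALSE, dm); tiny[8, 8, 8] <- TRUE
  seg <- graftquant:::new_segmentation_result(
    tiny, data.frame(id = 1L, n_voxels = 1L, volume_ml = 0.008),
    suv, 0.5)
  expect_warning(out <- pvc_correct(seg, suv, 60), "floor")
  expect_true("pvc_unstable" %in% out$flags)
  expect_equal(out$c_suv_total, out$suv_total)
})

test_that("patient uptake sums across sides and levels", {
  dm <- c(10, 10, 10); sp <- c(3, 3, 3)
  mk <- function(val) {
    voi <- array(FALSE, dm); voi[3:7, 3:7, 3:7] <- TRUE
    seg <- threshold_segment(make_suv(array(val, dm), sp), voi, 1)
    pvc_correct(seg, make_suv(array(val, dm), sp), 0)
  }
  a <- mk(2); b <- mk(3)
  tot <- patient_graft_uptake(list(a, b))
  expect_equal(tot$suv_total, a$suv_total + b$suv_total)
  expect_equal(tot$c_suv_total, a$suv_total + b$suv_total)
  one <- patient_graft_uptake(a)
  expect_equal(one$suv_total, a$suv_total)
  four <- patient_graft_uptake(list(a, a, a, a))
  expect_equal(four$suv_total, 4 * a$suv_total)
  expect_error(patient_graft_uptake(list()), class = "gq_argument_error")
})
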