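# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they check.

# SUVpeak oracle: for every mask voxel, test sphere membership of the whole
# grid by explicit squared-distance computation; mean over the sphere
# clipped to the mask; centers must retain >= min_cov of the full sphere
# voxel count. First (lowest linear index) maximum wins.
oracle_suv_peak <- function(vox, mask, spacing, sphere_ml = 1.0,
                            min_cov = 0.5) {
  dm <- dim(vox)
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  sub <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                               k = seq_len(dm[3])))
  w <- sweep(sub - 1, 2, spacing, `*`)
  # full sphere voxel count on an unbounded grid
  offs <- expand.grid(a = -20:20, b = -20:20, c = -20:20)
  k_full <- sum((offs$a * spacing[1])^2 + (offs$b * spacing[2])^2 +
                  (offs$c * spacing[3])^2 <= r^2 + 1e-9)
  best <- -Inf; best_center <- NA_integer_
  for (c0 in which(mask)) {
    d2 <- rowSums((w - matrix(w[c0, ], nrow(w), 3, byrow = TRUE))^2)
    in_sphere <- d2 <= r^2 + 1e-9
    in_both <- in_sphere & as.vector(mask)
    if (sum(in_both) < min_cov * k_full) next
    m <- mean(vox[in_both])
    if (m > best) { best <- m; best_center <- c0 }
  }
  list(peak = best, center = best_center)
}

# Connected-components oracle: iterative minimum-label propagation over
# shifted copies of the array until a fixed point is reached.
oracle_components <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- array(seq_along(mask), dm)
  lab[!mask] <- NA_integer_
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  shift_arr <- function(x, by) {
    out <- array(NA_integer_, dm)
    src <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    dst <- src
    for (ax in 1:3) {
      if (by[ax] > 0) { dst[[ax]] <- (1 + by[ax]):dm[ax]; src[[ax]] <- 1:(dm[ax] - by[ax]) }
      else if (by[ax] < 0) { dst[[ax]] <- 1:(dm[ax] + by[ax]); src[[ax]] <- (1 - by[ax]):dm[ax] }
      if (length(dst[[ax]]) == 0) return(out)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    new_lab <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift_arr(lab, offs[r, ])
      better <- !is.na(new_lab) & !is.na(sh) & sh < new_lab
      new_lab[better] <- sh[better]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # renumber by order of smallest member index
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- array(0L, dm)
  for (i in seq_along(ids)) out[!is.na(lab) & lab == ids[i]] <- i
  out
}

# random smooth-ish SUV field with a few hot blobs, for segmentation tests
random_blob_field <- function(dm, spacing, n_blobs = 3, seed = 1) {
  set.seed(seed)
  vox <- array(runif(prod(dm), 0, 0.8), dm)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dm, function(n) sample.int(n, 1))
    rad <- runif(1, 1.2, 3.5)
    sub <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                                 k = seq_len(dm[3])))
    d2 <- rowSums(sweep(sub, 2, ctr)^2)
    vox[d2 <= rad^2] <- vox[d2 <= rad^2] + runif(1, 1.5, 4)
  }
  vox
}

make_suv <- function(vox, spacing = c(2, 2, 2)) {
  image_volume(vox, spacing, modality = "PET_SUV")
}
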