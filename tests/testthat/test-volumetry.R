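test_that("the 100-slice VOI spans exactly 1.8 mm at 18 um spacing", {
  vol <- voxel_volume(array(0, c(4, 4, 120)), spacing = 0.018)
  sub <- extract_voi(vol, voi_spec(5, 100))
  expect_identical(dim(sub)[3], 100L)
  expect_equal(dim(sub)[3] * sub$spacing[3], 1.8)
})

test_that("extract_voi crops exactly and checks its bounds", {
  ph <- make_phantom(tiny_spec(), seed = 1)
  nz <- dim(ph$volume)[3]
  # full-extent crop is the identity
  full <- extract_voi(ph$volume, voi_spec(1, nz))
  expect_identical(full$intensities, ph$volume$intensities)
  # cropping commutes with the ground-truth mask
  voi <- voi_spec(20, 40)
  sub <- extract_voi(ph$volume, voi)
  gt_crop <- ph$ground_truth$bone_mask[, , 20:59]
  expect_identical(unname(sub$intensities > 3500), unname(gt_crop))
  expect_error(extract_voi(ph$volume, voi_spec(90, 40)), class = "tarsalct_range_error")
  expect_error(voi_spec(0, 10), class = "tarsalct_range_error")
})

test_that("find_voi_start locates the landmark bone and honours overrides", {
  ph <- make_phantom(tiny_spec(), seed = 1)
  start <- find_voi_start(ph$volume)
  expect_identical(start, ph$ground_truth$landmark_slice)
  counts <- colSums(matrix(ph$ground_truth$bone_mask, ncol = dim(ph$volume)[3]))
  expect_identical(start, min(which(counts > 0)))
  expect_identical(find_voi_start(ph$volume, start_slice = 55), 55L)
  air <- voxel_volume(array(-900, c(10, 10, 10)), 0.018)
  expect_error(find_voi_start(air), class = "tarsalct_landmark_error")
})

test_that("bone segmentation uses a strict threshold on raw intensities", {
  # boundary case: a volume exactly at 3500 AU contains no bone
  flat <- voxel_volume(array(3500, c(8, 8, 8)), 0.018)
  expect_identical(sum(segment_bone(flat)), 0L)
  # noiseless phantom: segmentation reproduces ground truth exactly
  ph <- make_phantom(tiny_spec(), seed = 1)
  mask <- segment_bone(ph$volume)
  expect_identical(sum(mask != ph$ground_truth$bone_mask), 0L)
  # raising the threshold above every intensity empties the mask
  hi <- segmentation_params(bone_threshold = 6800)
  expect_identical(sum(segment_bone(ph$volume, hi)), 0L)
})

test_that("bone masks are monotone in the threshold", {
  ph <- make_phantom(tiny_spec(noise_sd = 400), seed = 8)
  thresholds <- c(3500, 4000, 5000, 6000)
  masks <- lapply(thresholds, function(t) {
    segment_bone(ph$volume, segmentation_params(bone_threshold = t))
  })
  for (i in seq_len(length(masks) - 1)) {
    expect_identical(sum(masks[[i + 1]] & !masks[[i]]), 0L) # higher t is a subset
    expect_lte(sum(masks[[i + 1]]), sum(masks[[i]]))
  }
})

test_that("soft segmentation windows smoothed intensities and excludes bone", {
  # smoothing a constant volume is the identity: full mask
  flat <- voxel_volume(array(300, c(20, 20, 20)), 0.018)
  empty_bone <- array(FALSE, c(20, 20, 20))
  expect_identical(sum(segment_soft(flat, bone_mask = empty_bone)), 8000L)
  # smoothing_sd 0 is a pure range threshold
  ph <- make_phantom(tiny_spec(), seed = 1)
  p0 <- segmentation_params(smoothing_sd = 0)
  raw_mask <- ph$volume$intensities >= -300 & ph$volume$intensities <= 1500
  got <- segment_soft(ph$volume, p0, bone_mask = array(FALSE, dim(ph$volume)))
  expect_identical(unname(got), unname(raw_mask))
  # disjointness with the bone mask
  bone <- segment_bone(ph$volume)
  soft <- segment_soft(ph$volume, bone_mask = bone)
  expect_identical(sum(soft & bone), 0L)
  expect_error(
    segment_soft(ph$volume, bone_mask = array(FALSE, c(2, 2, 2))),
    class = "tarsalct_contract_error"
  )
})

test_that("noiseless soft mask stays within 3% of truth, near interfaces only", {
  # needs the full-size phantom: the smoothed window misclassifies a shell
  # around each interface whose share shrinks with compartment size
  base <- acceptance_baseline()
  q <- base$q
  sl <- q$voi_used$start_slice:(q$voi_used$start_slice + q$voi_used$n_slices - 1L)
  soft <- q$soft_mask
  gt <- base$phantom$ground_truth$soft_mask[, , sl]
  expect_lt(abs(sum(soft) - sum(gt)) / sum(gt), 0.03)
  # mismatches are confined to within 0.4 mm (Chebyshev) of a tissue interface:
  # eroding either compartment by a 0.4 mm cube must clear every mismatch
  shift_arr <- function(m, ax, by) { # pad with TRUE outside the grid
    d <- dim(m)
    out <- array(TRUE, d)
    src <- lapply(d, seq_len); dst <- src
    b <- abs(by)
    if (by > 0) { dst[[ax]] <- (b + 1):d[ax]; src[[ax]] <- 1:(d[ax] - b) }
    else { dst[[ax]] <- 1:(d[ax] - b); src[[ax]] <- (b + 1):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  erode_cube <- function(mask, r_vox) {
    out <- mask
    for (ax in 1:3) {
      acc <- out
      for (s in seq_len(r_vox)) {
        acc <- acc & shift_arr(out, ax, s) & shift_arr(out, ax, -s)
      }
      out <- acc
    }
    out
  }
  r_vox <- as.integer(ceiling(0.4 / 0.018))
  mism <- soft != gt
  deep_soft <- erode_cube(gt, r_vox)
  deep_other <- erode_cube(!gt, r_vox)
  expect_identical(sum(mism & deep_soft), 0L)
  expect_identical(sum(mism & deep_other), 0L)
})

test_that("mask_volume equals a brute-force voxel count", {
  expect_identical(mask_volume(array(FALSE, c(5, 5, 5)), 0.018), 0)
  expect_equal(mask_volume(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), 0.018),
               5.832e-6)
  set.seed(11)
  for (i in 1:5) {
    mask <- array(runif(10 * 12 * 9) < 0.3, c(10, 12, 9))
    sp <- c(0.018, 0.02, 0.015)
    expect_identical(mask_volume(mask, sp), brute_mask_volume(mask, sp))
  }
  expect_error(mask_volume(array(1, c(2, 2, 2)), 0.018), class = "tarsalct_contract_error")
})

test_that("intensity histograms conserve counts and expose the AU clusters", {
  flat <- voxel_volume(array(42, c(6, 6, 6)), 0.018)
  h <- compute_histogram(flat)
  expect_identical(sum(h$counts), 216L)
  expect_identical(sum(h$counts > 0), 1L)
  ph <- make_phantom(tiny_spec(), seed = 1)
  expect_identical(length(unique(as.numeric(ph$volume$intensities))), 3L)
  h2 <- compute_histogram(ph$volume, bins = 128)
  expect_identical(sum(h2$counts), as.integer(prod(dim(ph$volume))))
  expect_error(compute_histogram(ph$volume, bins = 1), class = "tarsalct_contract_error")
})

test_that("suggested thresholds separate the soft and bone clusters", {
  two <- voxel_volume(array(rep(c(300, 5000), each = 500), c(10, 10, 10)), 0.018)
  thr <- suggest_threshold(compute_histogram(two, bins = 64))
  expect_gt(thr, 300); expect_lt(thr, 5000)
  flat <- compute_histogram(voxel_volume(array(900, c(5, 5, 5)), 0.018))
  expect_error(suggest_threshold(flat), class = "tarsalct_threshold_error")
  # noisy phantom: suggestion lands in the soft/bone gap and its mask is
  # within 1% of ground truth
  ph <- make_phantom(tiny_spec(noise_sd = 50), seed = 5)
  thr2 <- suggest_threshold(compute_histogram(ph$volume, bins = 256))
  expect_true(thr2 >= 1500 && thr2 <= 4000)
  mask <- ph$volume$intensities > thr2
  gt <- ph$ground_truth$bone_mask
  expect_lt(sum(mask != gt) / sum(gt), 0.01)
})

test_that("segmentation masks are translation-equivariant", {
  spec <- tiny_spec()
  shift_vox <- 4L
  spec2 <- spec
  shift_mm <- c(0, 0, shift_vox * 0.018)
  spec2$bones <- lapply(spec$bones, function(b) { b$center <- b$center + shift_mm; b })
  spec2$soft_envelope$center <- spec2$soft_envelope$center + shift_mm
  a <- make_phantom(spec, seed = 1)
  b <- make_phantom(spec2, seed = 1)
  ma <- segment_bone(a$volume); mb <- segment_bone(b$volume)
  nz <- dim(ma)[3]
  expect_identical(
    unname(ma[, , 1:(nz - shift_vox)]),
    unname(mb[, , (shift_vox + 1):nz])
  )
  expect_identical(sum(ma), sum(mb))
})

test_that("reorientation is idempotent on aligned input and flags degenerate input", {
  ph <- make_phantom(tiny_spec(), seed = 1)
  ro <- reorient_to_axis(ph$volume)
  expect_lt(ro$angle_deg, 1)
  expect_identical(ro$volume$intensities, ph$volume$intensities) # no resampling
  # uniform ball: ambiguous principal axis
  dims <- c(60L, 60L, 60L)
  ball <- phantom_spec(dims, bones = list(ellipsoid(dims * 0.018 / 2, rep(0.3, 3), 6700)),
                       noise_sd = 0)
  bph <- make_phantom(ball, seed = 1)
  expect_error(reorient_to_axis(bph$volume), class = "tarsalct_ambiguous_axis_error")
  # fewer than 10 foreground voxels
  air <- voxel_volume(array(-900, c(10, 10, 10)), 0.018)
  expect_error(reorient_to_axis(air), class = "tarsalct_degenerate_error")
})

test_that("a known rotation is recovered and quantification is unaffected", {
  ang <- 30
  ph0 <- make_phantom(tiny_spec(), seed = 1)
  q0 <- quantify(ph0$volume, n_slices = tiny_n_slices)
  phr <- make_phantom(tiny_spec(rotation = list(axis = c(1, 0, 0), angle_deg = ang)),
                      seed = 1)
  ro <- reorient_to_axis(phr$volume)
  expect_lt(abs(ro$angle_deg - ang), 2)
  # composed rotation should be near the identity
  resid <- ro$rotation %*% phr$ground_truth$applied_rotation
  resid_angle <- acos(max(-1, min(1, (sum(diag(resid)) - 1) / 2))) * 180 / pi
  expect_lt(resid_angle, 2)
  qr <- quantify(phr$volume, n_slices = tiny_n_slices)
  expect_lt(abs(qr$bone_volume_mm3 - q0$bone_volume_mm3) / q0$bone_volume_mm3, 0.03)
})

test_that("quantify composes the stages and reports both compartments", {
  ph <- make_phantom(tiny_spec(), seed = 1)
  q <- quantify(ph$volume, n_slices = tiny_n_slices)
  sl <- q$voi_used$start_slice:(q$voi_used$start_slice + tiny_n_slices - 1L)
  vx <- voxel_size_mm3(ph$volume)
  expect_identical(sum(q$bone_mask != ph$ground_truth$bone_mask[, , sl]), 0L)
  expect_equal(q$bone_volume_mm3, sum(ph$ground_truth$bone_mask[, , sl]) * vx)
  # the tiny envelope has a high surface-to-volume ratio, so the smoothed
  # window's interface shell weighs more here than on the full-size phantom
  # (where the 3% bound is asserted); sanity-bound it at 10%
  gt_stv <- sum(ph$ground_truth$soft_mask[, , sl]) * vx
  expect_lt(abs(q$soft_volume_mm3 - gt_stv) / gt_stv, 0.10)
  expect_identical(sum(q$bone_mask & q$soft_mask), 0L)
  # all-air input: no landmark anywhere
  air <- voxel_volume(array(-900, c(10, 10, 60)), 0.018)
  expect_error(quantify(air), class = "tarsalct_landmark_error")
})
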