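#' Segmentation parameters
#'
#' The fixed thresholds of the tarsal analysis: bone is every voxel strictly
#' greater than `bone_threshold` on the raw intensities; soft tissue is every
#' voxel whose intensity, after isotropic Gaussian smoothing with standard
#' deviation `smoothing_sd` mm, falls inclusively in
#' `[soft_low, soft_high]`, minus the bone mask when
#' `exclude_bone_from_soft` is set (bone is treated as extraneous tissue so
#' that only soft tissue is segmented).
#'
#' @param bone_threshold Bone threshold in AU (default 3500, strict `>`).
#' @param soft_low,soft_high Soft-tissue window in AU (default -300 and
#'   1500, inclusive).
#' @param smoothing_sd Gaussian SD in mm applied only to the soft-tissue
#'   channel (default 0.1; 0 disables smoothing).
#' @param exclude_bone_from_soft Remove bone voxels from the soft mask
#'   (default `TRUE`).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(bone_threshold = 3500, soft_low = -300,
                                soft_high = 1500, smoothing_sd = 0.1,
                                exclude_bone_from_soft = TRUE) {
  if (!(soft_low < soft_high && soft_high < bone_threshold)) {
    stop_tarsalct("need soft_low < soft_high < bone_threshold", "contract")
  }
  if (smoothing_sd < 0) stop_tarsalct("`smoothing_sd` must be >= 0", "contract")
  structure(
    list(
      bone_threshold = bone_threshold, soft_low = soft_low,
      soft_high = soft_high, smoothing_sd = smoothing_sd,
      exclude_bone_from_soft = isTRUE(exclude_bone_from_soft)
    ),
    class = "segmentation_params"
  )
}

#' Volume-of-interest specification
#'
#' A full-slice slab of `n_slices` consecutive slices starting at
#' `start_slice` (1-based; the first slice of the VOI). At the default 18 um
#' spacing the default 100 slices span the 1.8 mm tarsal region.
#'
#' @param start_slice First slice of the VOI (>= 1).
#' @param n_slices Number of slices (default 100).
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(start_slice, n_slices = 100L) {
  start_slice <- as.integer(start_slice)
  n_slices <- as.integer(n_slices)
  if (is.na(start_slice) || start_slice < 1L) {
    stop_tarsalct("`start_slice` must be >= 1", "range")
  }
  if (is.na(n_slices) || n_slices < 1L) {
    stop_tarsalct("`n_slices` must be >= 1", "range")
  }
  structure(list(start_slice = start_slice, n_slices = n_slices), class = "voi_spec")
}

#' Extract the slab VOI from a volume
#'
#' @param volume A [voxel_volume()].
#' @param voi A [voi_spec()]; must fit within the volume's z extent.
#' @return A [voxel_volume()] of exactly `n_slices` slices, spacing
#'   preserved.
#' @export
extract_voi <- function(volume, voi) {
  assert_voxel_volume(volume)
  if (!inherits(voi, "voi_spec")) stop_tarsalct("`voi` must be a voi_spec", "contract")
  nz <- dim(volume)[3]
  if (voi$start_slice + voi$n_slices - 1L > nz) {
    stop_tarsalct(
      sprintf(
        "VOI [%d, %d] exceeds the %d-slice z extent",
        voi$start_slice, voi$start_slice + voi$n_slices - 1L, nz
      ),
      "range"
    )
  }
  sl <- voi$start_slice:(voi$start_slice + voi$n_slices - 1L)
  voxel_volume(
    volume$intensities[, , sl, drop = FALSE],
    spacing = volume$spacing
  )
}

#' Locate the proximal VOI start slice
#'
#' Scanning in +z (proximal to distal), returns the first slice whose
#' above-threshold voxel count rises from zero -- for synthetic phantoms this
#' is the first slice of the landmark (most proximal) bone body. A manual
#' `start_slice` override always takes precedence; real anatomy requires it,
#' mirroring the observer-defined cropping at the navicular bone.
#'
#' @param volume A reoriented [voxel_volume()].
#' @param bone_threshold Threshold in AU (default 3500, strict `>`).
#' @param start_slice Optional manual override (returned unchanged).
#' @return Integer slice index (1-based).
#' @export
find_voi_start <- function(volume, bone_threshold = 3500, start_slice = NULL) {
  if (!is.null(start_slice)) return(as.integer(start_slice))
  assert_voxel_volume(volume)
  nz <- dim(volume)[3]
  counts <- colSums(matrix(volume$intensities > bone_threshold, ncol = nz))
  if (!any(counts > 0)) {
    stop_tarsalct("no voxels above the bone threshold in any slice", "landmark")
  }
  min(which(counts > 0))
}

#' Frequency histogram of VOI intensities
#'
#' @param volume A [voxel_volume()].
#' @param bins Number of equal-width bins spanning the intensity range
#'   (>= 2). A constant volume yields a single bin.
#' @return A list of class `au_histogram` with `counts`, `breaks`, `mids`;
#'   counts always sum to the voxel count.
#' @export
compute_histogram <- function(volume, bins = 256L) {
  assert_voxel_volume(volume)
  if (bins < 2L) stop_tarsalct("`bins` must be >= 2", "contract")
  x <- as.numeric(volume$intensities)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- list(counts = length(x), breaks = rng[1] + c(-0.5, 0.5), mids = rng[1])
  } else {
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    hh <- graphics::hist(x, breaks = breaks, plot = FALSE, right = TRUE,
                         include.lowest = TRUE)
    out <- list(counts = hh$counts, breaks = hh$breaks, mids = hh$mids)
  }
  structure(out, class = "au_histogram")
}

#' Suggest a bone threshold from an intensity histogram
#'
#' Otsu's between-class-variance criterion restricted to the soft/bone part
#' of the histogram (bins below `min_intensity` -- air -- are excluded).
#' Where the criterion plateaus across an empty intensity gap the midpoint of
#' the plateau is returned, i.e. the middle of the gap. Advisory only: the
#' pipeline default remains the fixed 3500 AU.
#'
#' @param histogram An `au_histogram` from [compute_histogram()].
#' @param min_intensity Lower bound of the intensities considered (default
#'   -300, the soft-tissue window's lower edge).
#' @return Threshold in AU.
#' @export
suggest_threshold <- function(histogram, min_intensity = -300) {
  if (!inherits(histogram, "au_histogram")) {
    stop_tarsalct("`histogram` must come from compute_histogram()", "contract")
  }
  keep <- histogram$mids >= min_intensity
  counts <- histogram$counts[keep]
  mids <- histogram$mids[keep]
  if (sum(counts > 0) < 2L) {
    stop_tarsalct("histogram is degenerate (fewer than 2 occupied bins)", "threshold")
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * mids) / n
  mu_tot <- mu_cum[length(mu_cum)]
  k <- seq_len(length(counts) - 1L)
  w0k <- w0[k]
  between <- (mu_tot * w0k - mu_cum[k])^2 / (w0k * (1 - w0k))
  between[!is.finite(between)] <- -Inf
  best <- max(between)
  at <- which(between >= best - 1e-9 * abs(best) - 1e-300)
  # threshold between bin `at` and `at + 1`; take the plateau midpoint
  cuts <- (mids[at] + mids[at + 1L]) / 2
  mean(range(cuts))
}

#' Threshold segmentation of bone
#'
#' Bone is every voxel strictly greater than the threshold on the raw
#' (unsmoothed) intensities.
#'
#' @param voi A [voxel_volume()] (typically the extracted VOI).
#' @param params A [segmentation_params()].
#' @return Logical array of the VOI's dimensions.
#' @export
segment_bone <- function(voi, params = segmentation_params()) {
  assert_voxel_volume(voi)
  mask <- voi$intensities > params$bone_threshold
  dim(mask) <- dim(voi$intensities)
  mask
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' The mm-scale SD is converted to voxels per axis using the spacing; the
#' kernel is truncated at 4 SD and edges are handled by replication, so a
#' constant array is returned unchanged.
#'
#' @param arr 3-D numeric array.
#' @param sd_mm Gaussian SD in mm (0 returns `arr` unchanged).
#' @param spacing Per-axis voxel spacing in mm.
#' @param truncate Kernel support in SDs (default 4).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth3 <- function(arr, sd_mm, spacing, truncate = 4) {
  if (sd_mm == 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    sigma <- sd_mm / spacing[ax]
    r <- as.integer(ceiling(truncate * sigma))
    if (r < 1L) next
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

#' Convolve one axis of a 3-D array with a centred odd-length kernel,
#' replicating edges.
#' @noRd
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  ord <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, ord)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1])
  r <- (length(k) - 1L) %/% 2L
  n <- dp[1]
  mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  # stats::filter computes sum(k[j] * x[i + r + 1 - j]); a symmetric kernel
  # makes the orientation irrelevant
  f <- stats::filter(mp, k, method = "convolution", sides = 2)
  out <- matrix(as.numeric(f[(r + 1L):(r + n), ]), nrow = n)
  a <- array(out, dp)
  aperm(a, order(ord))
}

#' Window segmentation of soft tissue
#'
#' Smooths the intensities with an isotropic Gaussian (SD
#' `params$smoothing_sd` mm, truncated at 4 SD), selects voxels whose
#' smoothed intensity lies inclusively in `[soft_low, soft_high]`, and, with
#' `exclude_bone_from_soft`, removes the bone mask so the two compartments
#' are disjoint.
#'
#' @param voi A [voxel_volume()].
#' @param params A [segmentation_params()].
#' @param bone_mask Logical array of the VOI's dimensions (from
#'   [segment_bone()]).
#' @return Logical array of the VOI's dimensions.
#' @export
segment_soft <- function(voi, params = segmentation_params(), bone_mask = NULL) {
  assert_voxel_volume(voi)
  if (!is.null(bone_mask) && !identical(dim(bone_mask), dim(voi$intensities))) {
    stop_tarsalct("`bone_mask` dimensions do not match the VOI", "contract")
  }
  sm <- gaussian_smooth3(voi$intensities, params$smoothing_sd, voi$spacing)
  mask <- sm >= params$soft_low & sm <= params$soft_high
  dim(mask) <- dim(voi$intensities)
  if (params$exclude_bone_from_soft && !is.null(bone_mask)) {
    mask <- mask & !bone_mask
  }
  mask
}

#' Mask volume in mm^3
#'
#' @param mask Logical array.
#' @param spacing Per-axis voxel spacing in mm (scalar for isotropic).
#' @return Number of `TRUE` voxels times the voxel volume.
#' @export
mask_volume <- function(mask, spacing) {
  if (!is.logical(mask)) stop_tarsalct("`mask` must be logical", "contract")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sum(mask) * prod(spacing)
}

#' Reorient a volume so the bone principal axis lies along +z
#'
#' Binarises the volume at `binarize_threshold`, computes the second-moment
#' (inertia) principal axes of the above-threshold voxel cloud, and rotates
#' the volume by the minimal rotation taking the first principal axis to +z
#' (sign chosen so the axis points distally). Intensities are trilinearly
#' resampled onto a grid padded to the rotated bounding box so nothing is
#' clipped; if the detected tilt is below `skip_angle_deg` the volume is
#' returned unresampled, keeping aligned inputs bit-identical.
#'
#' @param volume A [voxel_volume()].
#' @param binarize_threshold Foreground threshold in AU (default 3500).
#' @param fill Fill intensity for out-of-field voxels (default: minimum
#'   intensity of the input).
#' @param min_foreground Minimum number of foreground voxels (default 10).
#' @param anisotropy_min Minimum ratio of first to second principal moments;
#'   below this the axis is ambiguous (default 1.05).
#' @param skip_angle_deg Tilt below which resampling is skipped (default
#'   0.5 degrees).
#' @return A list: `volume` (reoriented), `rotation` (the applied 3 x 3
#'   matrix) and `angle_deg` (the detected tilt).
#' @export
reorient_to_axis <- function(volume, binarize_threshold = 3500, fill = NULL,
                             min_foreground = 10L, anisotropy_min = 1.05,
                             skip_angle_deg = 0.5) {
  assert_voxel_volume(volume)
  fg <- which(volume$intensities > binarize_threshold)
  if (length(fg) < min_foreground) {
    stop_tarsalct(
      sprintf("only %d foreground voxels above %g AU (need >= %d)",
              length(fg), binarize_threshold, min_foreground),
      "degenerate"
    )
  }
  d <- dim(volume)
  h <- volume$spacing
  k <- fg - 1L
  xs <- (k %% d[1] + 0.5) * h[1]
  ys <- ((k %/% d[1]) %% d[2] + 0.5) * h[2]
  zs <- (k %/% (d[1] * d[2]) + 0.5) * h[3]
  P <- cbind(xs, ys, zs)
  P <- sweep(P, 2, colMeans(P))
  M <- crossprod(P) / nrow(P)
  eg <- eigen(M, symmetric = TRUE)
  if (eg$values[1] / eg$values[2] < anisotropy_min) {
    stop_tarsalct(
      "foreground is near-spherical; principal axis is ambiguous",
      "ambiguous_axis"
    )
  }
  v <- eg$vectors[, 1]
  if (v[3] < 0) v <- -v
  angle <- acos(max(-1, min(1, v[3]))) * 180 / pi
  if (angle < skip_angle_deg) {
    return(list(volume = volume, rotation = diag(3), angle_deg = angle))
  }
  axis <- c(v[2], -v[1], 0) # v x e_z
  R <- rotation_matrix(axis, angle)
  list(
    volume = rotate_volume(volume, R, fill = fill),
    rotation = R,
    angle_deg = angle
  )
}

#' End-to-end tarsal quantification of one volume
#'
#' The per-image pipeline: reorient so the bone axis lies along +z, locate
#' (or accept) the proximal VOI start slice, extract the 100-slice slab,
#' threshold bone on the raw intensities, segment soft tissue on the
#' smoothed intensities over the same VOI, and convert voxel counts to mm^3.
#' One acquisition therefore yields both BV and STV.
#'
#' @param volume A [voxel_volume()].
#' @param voi Optional [voi_spec()]; when `NULL` the start slice is detected
#'   with [find_voi_start()] (or taken from `start_slice`) and `n_slices`
#'   slices are used.
#' @param params A [segmentation_params()].
#' @param reorient Run [reorient_to_axis()] first (default `TRUE`).
#' @param start_slice Optional manual VOI start (takes precedence over
#'   detection).
#' @param n_slices VOI length in slices when `voi` is `NULL` (default 100).
#' @return An object of class `segmentation_result`: bone/soft masks
#'   (confined to the VOI), `bone_volume_mm3`, `soft_volume_mm3`,
#'   `voi_used`, `params_used`, the reorientation `rotation` and
#'   `reorient_angle_deg`.
#' @export
quantify <- function(volume, voi = NULL, params = segmentation_params(),
                     reorient = TRUE, start_slice = NULL, n_slices = 100L) {
  assert_voxel_volume(volume)
  if (!any(volume$intensities > params$bone_threshold)) {
    stop_tarsalct("no bone anywhere in the volume", "landmark")
  }
  rotation <- diag(3)
  angle <- 0
  if (isTRUE(reorient)) {
    ro <- reorient_to_axis(volume, binarize_threshold = params$bone_threshold)
    volume <- ro$volume
    rotation <- ro$rotation
    angle <- ro$angle_deg
  }
  if (is.null(voi)) {
    start <- find_voi_start(volume, params$bone_threshold, start_slice = start_slice)
    voi <- voi_spec(start, n_slices)
  }
  sub <- extract_voi(volume, voi)
  bone <- segment_bone(sub, params)
  soft <- segment_soft(sub, params, bone)
  structure(
    list(
      bone_mask = bone,
      soft_mask = soft,
      bone_volume_mm3 = mask_volume(bone, sub$spacing),
      soft_volume_mm3 = mask_volume(soft, sub$spacing),
      voi_used = voi,
      params_used = params,
      rotation = rotation,
      reorient_angle_deg = angle
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> BV %.4f mm^3, STV %.4f mm^3 (VOI slices %d-%d, tilt %.2f deg)\n",
    x$bone_volume_mm3, x$soft_volume_mm3,
    x$voi_used$start_slice, x$voi_used$start_slice + x$voi_used$n_slices - 1L,
    x$reorient_angle_deg
  ))
  invisible(x)
}
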