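#' Describe an ellipsoid body for the phantom generator
#'
#' @param center Centre in mm (x, y, z), in grid coordinates (the grid spans
#'   `[0, n * spacing]` per axis).
#' @param semi_axes Semi-axis lengths in mm (x, y, z).
#' @param intensity Intensity of the body in AU.
#' @return A list describing the ellipsoid.
#' @export
ellipsoid <- function(center, semi_axes, intensity) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  if (length(center) != 3L || length(semi_axes) != 3L ||
      any(!is.finite(c(center, semi_axes, intensity))) || any(semi_axes <= 0)) {
    stop_tarsalct("ellipsoid needs finite center/semi_axes (> 0) and intensity", "contract")
  }
  list(center = center, semi_axes = semi_axes, intensity = as.numeric(intensity))
}

#' Parametric description of a synthetic tarsal phantom
#'
#' A phantom is a stack of ellipsoidal "bone" bodies inside an ellipsoidal
#' soft-tissue envelope, surrounded by air, optionally rigidly rotated as a
#' whole scene, optionally carrying erosion pits, with additive Gaussian
#' noise. Intensities follow the HU-like AU regime used for segmentation:
#' bone bodies must exceed 3500 AU, soft tissue must lie strictly inside
#' (-300, 1500) AU and air must be below -300 AU, so that noiseless phantoms
#' are exactly separable by the default thresholds.
#'
#' @param grid_shape Integer vector of 3 positive extents (voxels).
#' @param spacing Voxel spacing in mm (scalar or per axis); default 0.018.
#' @param bones List of [ellipsoid()] descriptors with intensity > 3500 AU.
#' @param soft_envelope [ellipsoid()] with intensity in (-300, 1500) AU, or
#'   `NULL` for a phantom without soft tissue.
#' @param air_intensity Background intensity in AU, must be < -300.
#' @param noise_sd Standard deviation of additive Gaussian noise (AU, >= 0).
#' @param rotation `NULL`, or `list(axis =, angle_deg =)` rigid rotation
#'   applied to the whole scene about the grid centre.
#' @param erosion `NULL`, or `list(fraction =, radius_mm =, seed =)` surface
#'   pits carved from bone into soft tissue (see [apply_disease()]).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing = 0.018, bones = list(),
                         soft_envelope = NULL, air_intensity = -900,
                         noise_sd = 50, rotation = NULL, erosion = NULL) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop_tarsalct("`grid_shape` must be 3 positive integers", "contract")
  }
  spec <- structure(
    list(
      grid_shape = grid_shape, spacing = spacing, bones = bones,
      soft_envelope = soft_envelope, air_intensity = as.numeric(air_intensity),
      noise_sd = as.numeric(noise_sd), rotation = rotation, erosion = erosion
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the AU intensity regimes (bone > 3500, soft in (-300, 1500), air
#' < -300) and that every ellipsoid lies inside the grid after the scene
#' rotation.
#'
#' @param spec A [phantom_spec()].
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_tarsalct("`spec` must be a phantom_spec", "contract")
  }
  for (b in spec$bones) {
    if (b$intensity <= 3500) {
      stop_tarsalct("bone intensities must exceed 3500 AU", "contract")
    }
  }
  env <- spec$soft_envelope
  if (!is.null(env) && (env$intensity <= -300 || env$intensity >= 1500)) {
    stop_tarsalct("soft-tissue intensity must lie in (-300, 1500) AU", "contract")
  }
  if (spec$air_intensity >= -300) {
    stop_tarsalct("air intensity must be below -300 AU", "contract")
  }
  if (spec$noise_sd < 0) stop_tarsalct("`noise_sd` must be >= 0", "contract")
  if (!is.null(spec$erosion)) {
    f <- spec$erosion$fraction
    if (f < 0 || f >= 1) stop_tarsalct("erosion fraction must be in [0, 1)", "range")
  }
  R <- spec_rotation_matrix(spec)
  ext <- spec$grid_shape * spec$spacing
  for (e in c(spec$bones, if (!is.null(env)) list(env))) {
    bb <- rotated_ellipsoid_bbox(e, R, ext / 2)
    if (any(bb$lo < 0) || any(bb$hi > ext)) {
      stop_tarsalct(
        sprintf(
          "ellipsoid at (%.3f, %.3f, %.3f) mm escapes the grid after rotation",
          e$center[1], e$center[2], e$center[3]
        ),
        "geometry"
      )
    }
  }
  invisible(spec)
}

spec_rotation_matrix <- function(spec) {
  if (is.null(spec$rotation)) diag(3)
  else rotation_matrix(spec$rotation$axis, spec$rotation$angle_deg)
}

#' Axis-aligned bounding box of an ellipsoid after scene rotation about `rc`
#' @noRd
rotated_ellipsoid_bbox <- function(e, R, rc) {
  ctr <- as.numeric(R %*% (e$center - rc) + rc)
  # support of the rotated ellipsoid along each grid axis
  half <- sqrt(rowSums((R %*% diag(e$semi_axes))^2))
  list(lo = ctr - half, hi = ctr + half, center = ctr)
}

#' Linear voxel indices inside an ellipsoid after scene rotation.
#' Membership is by voxel centre: a voxel belongs to the body iff its centre,
#' carried back by the inverse rotation, satisfies the ellipsoid inequality.
#' @noRd
rasterize_ellipsoid <- function(dims, spacing, e, R, rc) {
  bb <- rotated_ellipsoid_bbox(e, R, rc)
  i0 <- pmax(1L, as.integer(floor(bb$lo / spacing + 0.5)))
  i1 <- pmin(dims, as.integer(ceiling(bb$hi / spacing + 0.5)))
  if (any(i1 < i0)) return(integer(0))
  gx <- axis_centers(dims[1], spacing[1])[i0[1]:i1[1]]
  gy <- axis_centers(dims[2], spacing[2])[i0[2]:i1[2]]
  gz <- axis_centers(dims[3], spacing[3])[i0[3]:i1[3]]
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  # p = voxel centre - rotated centre; inside iff |diag(1/s) R^T p| <= 1
  px <- outer_sum3(gx - bb$center[1], numeric(ny), numeric(nz))
  py <- outer_sum3(numeric(nx), gy - bb$center[2], numeric(nz))
  pz <- outer_sum3(numeric(nx), numeric(ny), gz - bb$center[3])
  s <- e$semi_axes
  ux <- (R[1, 1] * px + R[2, 1] * py + R[3, 1] * pz) / s[1]
  uy <- (R[1, 2] * px + R[2, 2] * py + R[3, 2] * pz) / s[2]
  uz <- (R[1, 3] * px + R[2, 3] * py + R[3, 3] * pz) / s[3]
  inside <- which(ux * ux + uy * uy + uz * uz <= 1)
  if (length(inside) == 0L) return(integer(0))
  k <- (inside - 1L)
  li <- k %% nx
  lj <- (k %/% nx) %% ny
  lk <- k %/% (nx * ny)
  (i0[1] + li) + (i0[2] + lj - 1L) * dims[1] +
    (i0[3] + lk - 1L) * dims[1] * dims[2]
}

#' Render a phantom volume with exact ground truth
#'
#' Rasterises the soft envelope and bone bodies (bone overwrites soft
#' overwrites air), carves erosion pits from bone into soft intensity, then
#' adds seeded Gaussian noise. The ground-truth masks are the noiseless,
#' pre-threshold rasterisations; recorded volumes are exactly
#' voxel count x voxel volume.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise stream (erosion pits use the seed
#'   recorded in `spec$erosion`).
#' @return A list with elements `volume` (a [voxel_volume()]) and
#'   `ground_truth`: bone/soft masks, exact volumes in mm^3, the applied
#'   rotation, the landmark slice (first slice containing bone) and the seed.
#' @export
make_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  dims <- spec$grid_shape
  h <- spec$spacing
  R <- spec_rotation_matrix(spec)
  rc <- dims * h / 2

  inten <- array(spec$air_intensity, dims)
  soft_region <- NULL
  if (!is.null(spec$soft_envelope)) {
    soft_region <- rasterize_ellipsoid(dims, h, spec$soft_envelope, R, rc)
    inten[soft_region] <- spec$soft_envelope$intensity
  }
  bone_mask <- array(FALSE, dims)
  for (b in spec$bones) {
    idx <- rasterize_ellipsoid(dims, h, b, R, rc)
    bone_mask[idx] <- TRUE
    inten[idx] <- b$intensity
  }

  if (!is.null(spec$erosion) && spec$erosion$fraction > 0 && any(bone_mask)) {
    carved <- carve_erosion_pits(
      bone_mask,
      spacing = h,
      fraction = spec$erosion$fraction,
      radius_mm = spec$erosion$radius_mm %||% 0.035,
      seed = spec$erosion$seed %||% seed
    )
    bone_mask[carved] <- FALSE
    soft_int <- if (!is.null(spec$soft_envelope)) spec$soft_envelope$intensity else 300
    inten[carved] <- soft_int
  }

  soft_mask <- array(FALSE, dims)
  if (!is.null(soft_region)) {
    soft_mask[soft_region] <- TRUE
    soft_mask[bone_mask] <- FALSE
  }

  slice_counts <- colSums(matrix(bone_mask, ncol = dims[3]))
  landmark_slice <- if (any(slice_counts > 0)) min(which(slice_counts > 0)) else NA_integer_

  if (spec$noise_sd > 0) {
    inten <- withr::with_seed(
      as.integer(seed),
      inten + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
    )
  }

  vx <- prod(h)
  list(
    volume = voxel_volume(inten, spacing = h),
    ground_truth = structure(
      list(
        bone_mask = bone_mask,
        soft_mask = soft_mask,
        bone_volume_mm3 = sum(bone_mask) * vx,
        soft_volume_mm3 = sum(soft_mask) * vx,
        applied_rotation = R,
        rotation = spec$rotation,
        landmark_slice = landmark_slice,
        seed = as.integer(seed)
      ),
      class = "ground_truth"
    )
  )
}

#' Six-connectivity surface voxels of a boolean mask (linear indices)
#' @noRd
surface_voxels <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  interior <- mask
  for (ax in 1:3) for (by in c(1L, -1L)) {
    nb <- shift(mask, ax, by)
    # boundary voxels of the grid count as surface: pad with FALSE
    interior <- interior & nb
  }
  which(mask & !interior)
}

#' Carve seeded spherical pits from the bone surface until the bone voxel
#' count is reduced by `fraction` of its original value. Pit centres are a
#' seeded permutation of the original surface voxels, so for a fixed seed a
#' larger fraction always carves a superset (monotone erosion).
#' @noRd
carve_erosion_pits <- function(bone_mask, spacing, fraction, radius_mm, seed) {
  d <- dim(bone_mask)
  n0 <- sum(bone_mask)
  target <- round(fraction * n0)
  if (target == 0L) return(integer(0))
  surf <- surface_voxels(bone_mask)
  order_surf <- withr::with_seed(as.integer(seed), sample(surf))

  ri <- floor(radius_mm / spacing)
  offs <- as.matrix(expand.grid(-ri[1]:ri[1], -ri[2]:ri[2], -ri[3]:ri[3]))
  keep <- (offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
    (offs[, 3] * spacing[3])^2 <= radius_mm^2
  offs <- offs[keep, , drop = FALSE]

  removed <- integer(0)
  n_removed <- 0L
  ptr <- 1L
  work <- bone_mask
  while (n_removed < target) {
    if (ptr > length(order_surf)) {
      # surface exhausted (very deep erosion): continue from the current surface
      surf <- surface_voxels(work)
      if (length(surf) == 0L) break
      order_surf <- c(order_surf, withr::with_seed(as.integer(seed) + ptr, sample(surf)))
    }
    c_lin <- order_surf[ptr]
    ptr <- ptr + 1L
    k <- c_lin - 1L
    ci <- k %% d[1] + 1L
    cj <- (k %/% d[1]) %% d[2] + 1L
    ck <- k %/% (d[1] * d[2]) + 1L
    ii <- offs[, 1] + ci; jj <- offs[, 2] + cj; kk <- offs[, 3] + ck
    ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    lin <- (ii[ok]) + (jj[ok] - 1L) * d[1] + (kk[ok] - 1L) * d[1] * d[2]
    hit <- lin[work[lin]]
    if (length(hit)) {
      work[hit] <- FALSE
      removed <- c(removed, hit)
      n_removed <- n_removed + length(hit)
    }
  }
  removed
}

#' Default tarsal-region phantom
#'
#' Five ellipsoidal bone bodies stacked along z (navicular plus 1st-4th
#' tarsals, stylised) spanning 1.85 mm axially -- slightly more than the
#' 100-slice (1.8 mm) analysis VOI -- inside a soft-tissue envelope, on an
#' 18 um isotropic grid. Intensities: air -900 AU, soft tissue 300 AU, bone
#' 6700 AU, noise SD 50 AU, no rotation. The bone and air intensities are
#' chosen so the fixed segmentation thresholds (3500 AU for bone, -300 AU
#' for the soft window's lower bound) sit exactly at the half-maximum of the
#' corresponding tissue edges, making threshold volumetry unbiased under
#' resampling; see the package vignette.
#'
#' @return A [phantom_spec()].
#' @export
default_tarsal_spec <- function() {
  dims <- c(200L, 194L, 200L)
  h <- 0.018
  ctr <- dims * h / 2
  dz <- c(-0.775, -0.3875, 0, 0.3875, 0.775)
  dx <- c(0.06, -0.05, 0, -0.05, 0.06)
  dy <- c(-0.05, 0.06, 0, 0.06, -0.05)
  bones <- lapply(seq_along(dz), function(i) {
    ellipsoid(
      center = ctr + c(dx[i], dy[i], dz[i]),
      semi_axes = c(0.28, 0.25, 0.15),
      intensity = 6700
    )
  })
  phantom_spec(
    grid_shape = dims,
    spacing = h,
    bones = bones,
    soft_envelope = ellipsoid(ctr, c(1.70, 1.60, 1.70), 300),
    air_intensity = -900,
    noise_sd = 50,
    rotation = NULL,
    erosion = NULL
  )
}

#' Apply disease effects to a phantom specification
#'
#' Bone erosion is modelled as seeded surface pits carved until the
#' ground-truth bone volume drops by `erosion_fraction` (achieved to well
#' within 2 percent of the original volume; each pit removes far fewer
#' voxels than that). Soft-tissue swelling scales the envelope semi-axes so
#' the ground-truth soft volume (envelope minus bone, analytically) grows by
#' `swelling_factor`. If the swollen envelope would escape the grid, the
#' grid is enlarged symmetrically and all body centres are shifted
#' accordingly, which leaves every physical volume unchanged.
#'
#' @param spec A [phantom_spec()].
#' @param erosion_fraction Fraction of bone volume to remove, in [0, 1).
#' @param swelling_factor Soft-volume growth factor, >= 1.
#' @param seed Seed controlling pit placement.
#' @return A modified [phantom_spec()].
#' @export
apply_disease <- function(spec, erosion_fraction = 0, swelling_factor = 1, seed = 1L) {
  validate_phantom_spec(spec)
  if (erosion_fraction < 0 || erosion_fraction >= 1) {
    stop_tarsalct("`erosion_fraction` must be in [0, 1)", "range")
  }
  if (swelling_factor < 1) {
    stop_tarsalct("`swelling_factor` must be >= 1", "range")
  }
  if (erosion_fraction == 0 && swelling_factor == 1) return(spec)

  if (erosion_fraction > 0) {
    spec$erosion <- list(
      fraction = erosion_fraction, radius_mm = 0.035, seed = as.integer(seed)
    )
  }
  if (swelling_factor > 1) {
    if (is.null(spec$soft_envelope)) {
      stop_tarsalct("cannot swell a phantom without a soft envelope", "contract")
    }
    ve <- 4 / 3 * pi * prod(spec$soft_envelope$semi_axes)
    vb <- sum(vapply(
      spec$bones, function(b) 4 / 3 * pi * prod(b$semi_axes), numeric(1)
    ))
    scale <- ((swelling_factor * (ve - vb) + vb) / ve)^(1 / 3)
    spec$soft_envelope$semi_axes <- spec$soft_envelope$semi_axes * scale
    spec <- grow_grid_to_fit(spec)
  }
  validate_phantom_spec(spec)
  spec
}

#' Symmetrically enlarge the grid (shifting all centres) until every
#' ellipsoid fits after rotation, with a 3-voxel margin.
#' @noRd
grow_grid_to_fit <- function(spec) {
  R <- spec_rotation_matrix(spec)
  ext <- spec$grid_shape * spec$spacing
  rc <- ext / 2
  bodies <- c(spec$bones, if (!is.null(spec$soft_envelope)) list(spec$soft_envelope))
  lo <- rep(0, 3); hi <- ext
  for (e in bodies) {
    bb <- rotated_ellipsoid_bbox(e, R, rc)
    lo <- pmin(lo, bb$lo); hi <- pmax(hi, bb$hi)
  }
  need_lo <- pmax(0, -lo)
  need_hi <- pmax(0, hi - ext)
  add <- as.integer(ceiling(pmax(need_lo, need_hi) / spec$spacing)) + 3L
  add[need_lo == 0 & need_hi == 0] <- 0L
  if (all(add == 0L)) return(spec)
  shift_mm <- add * spec$spacing
  spec$grid_shape <- spec$grid_shape + 2L * add
  spec$bones <- lapply(spec$bones, function(b) { b$center <- b$center + shift_mm; b })
  if (!is.null(spec$soft_envelope)) {
    spec$soft_envelope$center <- spec$soft_envelope$center + shift_mm
  }
  spec
}
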