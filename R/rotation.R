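#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula. The axis need not be normalised.
#'
#' @param axis Length-3 numeric rotation axis.
#' @param angle_deg Rotation angle in degrees (right-handed about `axis`).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  if (length(axis) != 3L || !all(is.finite(axis))) {
    stop_tarsalct("`axis` must be a finite length-3 vector", "contract")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) {
    stop_tarsalct("rotation axis must be non-zero", "contract")
  }
  a <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Angle of a rotation matrix in degrees
#' @noRd
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Build a dense array of `u[i] + v[j] + w[k]` without forming index grids
#' @noRd
outer_sum3 <- function(u, v, w) {
  nx <- length(u); ny <- length(v); nz <- length(w)
  rep(u, times = ny * nz) +
    rep(rep(v, each = nx), times = nz) +
    rep(w, each = nx * ny)
}

#' Trilinear sampling of a 3-D array at continuous voxel-index coordinates.
#' `fi`, `fj`, `fk` are in the convention where voxel `i` is centred at index
#' coordinate `i`; positions outside `[0.5, n + 0.5]` receive `fill`, positions
#' between the outermost voxel centre and the grid edge are clamped.
#' @noRd
trilinear_sample <- function(arr, fi, fj, fk, fill) {
  d <- dim(arr)
  oob <- fi < 0.5 | fi > d[1] + 0.5 |
    fj < 0.5 | fj > d[2] + 0.5 |
    fk < 0.5 | fk > d[3] + 0.5

  i0 <- pmin.int(pmax.int(floor(fi), 1L), d[1] - 1L)
  j0 <- pmin.int(pmax.int(floor(fj), 1L), d[2] - 1L)
  k0 <- pmin.int(pmax.int(floor(fk), 1L), d[3] - 1L)
  tx <- pmin.int(pmax.int(fi - i0, 0), 1)
  ty <- pmin.int(pmax.int(fj - j0, 0), 1)
  tz <- pmin.int(pmax.int(fk - k0, 0), 1)

  sxy <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * d[1] + (k0 - 1) * sxy + 1

  v000 <- arr[base]
  v100 <- arr[base + 1]
  v010 <- arr[base + d[1]]
  v110 <- arr[base + d[1] + 1]
  v001 <- arr[base + sxy]
  v101 <- arr[base + sxy + 1]
  v011 <- arr[base + sxy + d[1]]
  v111 <- arr[base + sxy + d[1] + 1]

  c00 <- v000 * (1 - tx) + v100 * tx
  c10 <- v010 * (1 - tx) + v110 * tx
  c01 <- v001 * (1 - tx) + v101 * tx
  c11 <- v011 * (1 - tx) + v111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out <- c0 * (1 - tz) + c1 * tz
  out[oob] <- fill
  out
}

#' Rigidly rotate a voxel volume
#'
#' Applies the rotation `R` to the scene about the physical centre of the
#' grid and resamples the intensities with trilinear interpolation onto a new
#' grid (same spacing) sized to cover the rotated bounding box of the input,
#' so nothing is clipped. Out-of-field voxels receive `fill`.
#'
#' @param volume A [voxel_volume()].
#' @param R 3 x 3 rotation matrix (scene/forward rotation).
#' @param fill Intensity for voxels with no source data; defaults to the
#'   minimum intensity of the input (i.e., its darkest air value).
#' @return A [voxel_volume()] with the rotated intensities.
#' @export
rotate_volume <- function(volume, R, fill = NULL) {
  assert_voxel_volume(volume)
  fill <- fill %||% min(volume$intensities)
  d <- dim(volume)
  h <- volume$spacing
  ext <- d * h
  vc <- ext / 2

  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  rot_corners <- t(R %*% (t(corners) - vc) + vc)
  lo <- apply(rot_corners, 2, min)
  hi <- apply(rot_corners, 2, max)
  nd <- pmax(1L, as.integer(ceiling((hi - lo) / h - 1e-9)))

  # inverse map: output world point y -> source point x = R^T (y - vc) + vc
  A <- t(R)
  gx <- lo[1] + axis_centers(nd[1], h[1])
  gy <- lo[2] + axis_centers(nd[2], h[2])
  gz <- lo[3] + axis_centers(nd[3], h[3])
  b <- vc - A %*% vc
  X <- outer_sum3(A[1, 1] * gx, A[1, 2] * gy, A[1, 3] * gz) + b[1]
  Y <- outer_sum3(A[2, 1] * gx, A[2, 2] * gy, A[2, 3] * gz) + b[2]
  Z <- outer_sum3(A[3, 1] * gx, A[3, 2] * gy, A[3, 3] * gz) + b[3]

  vals <- trilinear_sample(
    volume$intensities,
    X / h[1] + 0.5, Y / h[2] + 0.5, Z / h[3] + 0.5,
    fill = fill
  )
  voxel_volume(array(vals, nd), spacing = h)
}
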