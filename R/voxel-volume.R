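#' Voxel volume container
#'
#' The carrier of all image operations: a 3-D grid of HU-like intensities in
#' arbitrary units (AU) together with per-axis voxel spacing in millimetres.
#' Axis convention: the first two axes are the in-plane x/y axes, the third
#' axis is the slice (z) axis, with +z pointing distally.
#'
#' @param intensities 3-D numeric array of intensities (AU). Must be finite.
#' @param spacing Numeric vector of voxel edge lengths in mm; either a single
#'   value (isotropic) or one value per axis. All values must be positive.
#'
#' @return An object of class `voxel_volume`: a list with elements
#'   `intensities` (3-D array) and `spacing` (length-3 numeric, mm).
#'
#' @examples
#' vol <- voxel_volume(array(0, c(4, 4, 4)), spacing = 0.018)
#' dim(vol)
#' voxel_size_mm3(vol)
#' @export
voxel_volume <- function(intensities, spacing) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_tarsalct("`intensities` must be a 3-D array", "contract")
  }
  if (any(dim(intensities) < 1L)) {
    stop_tarsalct("each axis must have extent >= 1", "contract")
  }
  if (!all(is.finite(intensities))) {
    stop_tarsalct("intensities must be finite", "contract")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_tarsalct("`spacing` must be 3 positive values (mm)", "contract")
  }
  structure(
    list(intensities = intensities, spacing = spacing),
    class = "voxel_volume"
  )
}

#' @export
dim.voxel_volume <- function(x) dim(x$intensities)

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  intensity range [%.1f, %.1f] AU\n",
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

#' Volume of one voxel in mm^3
#'
#' @param volume A [voxel_volume()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_size_mm3 <- function(volume) prod(volume$spacing)

#' Physical coordinates of voxel centres along one axis
#'
#' Voxel `i` (1-based) has its centre at `(i - 0.5) * spacing`, so the grid
#' occupies `[0, n * spacing]` mm along each axis.
#' @noRd
axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

assert_voxel_volume <- function(x, arg = "volume") {
  if (!is_voxel_volume(x)) {
    stop_tarsalct(sprintf("`%s` must be a voxel_volume", arg), "contract")
  }
  invisible(x)
}
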