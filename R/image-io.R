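#' Read a volumetric image
#'
#' Supports single-file NIfTI-1 (`.nii`, `.nii.gz`; spacing taken from the
#' header, which is authoritative) and uncompressed 16-bit multi-page TIFF
#' stacks (which carry no reliable spacing, so `spacing` must be supplied).
#'
#' @param path Path to the image file.
#' @param format `"nifti"` or `"tiff_stack"`; inferred from the file
#'   extension when `NULL`.
#' @param spacing Voxel spacing override in mm (scalar or per axis).
#'   Required for TIFF stacks; ignored with a warning for NIfTI.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = NULL, spacing = NULL) {
  if (!file.exists(path)) {
    stop_tarsalct(sprintf("file not found: %s", path), "format")
  }
  format <- format %||% infer_format(path)
  format <- match.arg(format, c("nifti", "tiff_stack"))
  if (format == "nifti") {
    if (!is.null(spacing)) {
      warning("NIfTI spacing is authoritative; `spacing` override ignored")
    }
    read_nifti(path)
  } else {
    if (is.null(spacing)) {
      stop_tarsalct(
        "TIFF stacks carry no voxel spacing; supply `spacing` explicitly",
        "metadata"
      )
    }
    voxel_volume(read_tiff_stack(path), spacing = spacing)
  }
}

#' Write a volumetric image
#'
#' Intensities are rounded and stored as signed 16-bit integers, so a
#' written file read back with [read_volume()] reproduces the input exactly
#' up to that quantisation (bit-identical for integer-valued input) with
#' spacing preserved to within float precision.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path.
#' @param format `"nifti"` or `"tiff_stack"`; inferred from the extension
#'   when `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  assert_voxel_volume(volume)
  format <- format %||% infer_format(path)
  format <- match.arg(format, c("nifti", "tiff_stack"))
  if (!dir.exists(dirname(path))) {
    stop_tarsalct(sprintf("directory does not exist: %s", dirname(path)), "io")
  }
  if (format == "nifti") write_nifti(volume, path) else write_tiff_stack(volume, path)
  invisible(path)
}

infer_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.tiff?$", lower)) return("tiff_stack")
  stop_tarsalct(
    sprintf("cannot infer image format from '%s'; pass `format`", basename(path)),
    "format"
  )
}
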