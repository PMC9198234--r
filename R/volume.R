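#' CT-like intensity volume
#'
#' A `ct_volume` bundles a 3D intensity grid (HU-like arbitrary units) with
#' its voxel spacing and world origin, in millimetres. World position of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param intensities 3D numeric array of intensities; all values finite.
#' @param spacing Numeric length-3, mm per voxel along each axis; positive.
#' @param origin Numeric length-3, mm world position of voxel (1,1,1).
#' @param specimen_id Character label for the specimen.
#' @param side `"left"` or `"right"`.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing, origin = c(0, 0, 0),
                      specimen_id = "specimen", side = c("left", "right")) {
  side <- match.arg(side)
  if (length(dim(intensities)) != 3L) {
    abort_femurfe("`intensities` must be a 3D array.", "femurfe_parameter_error")
  }
  if (!all(is.finite(intensities))) {
    abort_femurfe("All intensities must be finite.", "femurfe_parameter_error")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) {
    abort_femurfe("`spacing` must be strictly positive.", "femurfe_parameter_error")
  }
  structure(
    list(intensities = intensities, spacing = spacing,
         origin = rep_len(as.numeric(origin), 3L),
         specimen_id = as.character(specimen_id), side = side),
    class = "ct_volume"
  )
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %s (%s)  %d x %d x %d voxels, spacing %s mm\n",
              x$specimen_id, x$side, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param values 3D logical array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 world origin in mm.
#' @param provenance Optional list recording how the mask was produced
#'   (specimen id, segmentation method, intensity range).
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0),
                        provenance = list()) {
  if (length(dim(values)) != 3L || !is.logical(values)) {
    abort_femurfe("`values` must be a 3D logical array.", "femurfe_parameter_error")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) {
    abort_femurfe("`spacing` must be strictly positive.", "femurfe_parameter_error")
  }
  structure(
    list(values = values, spacing = spacing,
         origin = rep_len(as.numeric(origin), 3L), provenance = provenance),
    class = "binary_mask"
  )
}

#' @exportS3Method base::print
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$values),
              100 * mean(x$values)))
  if (!is.null(x$provenance$method)) {
    cat(sprintf("  method %s, range [%.2f, %.2f]\n",
                x$provenance$method$name,
                x$provenance$range$low, x$provenance$range$high))
  }
  invisible(x)
}

#' Read a NIfTI volume as a `ct_volume`
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @inheritParams ct_volume
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, specimen_id = basename(path), side = "left") {
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[seq_len(3)]
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = spacing,
            specimen_id = specimen_id, side = side)
}

#' Write a volume or mask to NIfTI
#'
#' @param x A [ct_volume()] or [binary_mask()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "binary_mask")) array(as.integer(x$values), dim(x$values))
         else x$intensities
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
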