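#' Construct an image volume
#'
#' The carrier object for phantoms and all image-stage outputs: a 3D
#' intensity array plus voxel spacing in mm. The third array dimension is
#' the slice axis, with slice index increasing superiorly, so "above the
#' ventricles" always means larger slice index.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3 voxel spacing in mm (x, y, slice).
#' @return an object of class `image_volume`.
#' @export
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), c(0.75, 0.75, 4))
#' voxel_volume(v)  # 2.25 mm^3
image_volume <- function(data, spacing = c(0.75, 0.75, 4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_user("image_volume: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_user("image_volume: 'spacing' must be 3 strictly positive numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], voxel volume %.4g mm^3\n",
              min(x$data), max(x$data), voxel_volume(x)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param x an `image_volume` or a length-3 spacing vector (mm).
#' @return voxel volume in mm^3 (product of the spacings).
#' @export
voxel_volume <- function(x) {
  spacing <- if (inherits(x, "image_volume")) x$spacing else as.numeric(x)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  prod(spacing)
}

# Voxel-centre physical coordinates (mm) along each axis of a grid.
axis_coords <- function(dim3, spacing) {
  lapply(1:3, function(a) (seq_len(dim3[a]) - 0.5) * spacing[a])
}
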