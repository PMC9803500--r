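#' Extract the brain from a T2-like volume
#'
#' Intensity stand-in for skull stripping on phantoms: a global Otsu
#' threshold separates head from air, the largest 26-connected foreground
#' component is kept, and in-plane holes (ventricles, dark interior
#' voxels) are filled slice by slice so the mask is a solid brain.
#'
#' @param volume an [image_volume()], finite and non-negative.
#' @return logical 3D brain mask.
#' @export
extract_brain <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  x <- volume$data
  if (any(!is.finite(x))) stop_user("extract_brain: volume has non-finite voxels")
  if (min(x) == max(x)) stop_user("extract_brain: no brain found (constant volume)")
  t <- otsu_threshold(x)
  fg <- x > t
  if (!any(fg)) stop_user("extract_brain: no brain found")
  labs <- label_components(fg, "3d26")
  sizes <- tabulate(labs[labs > 0L], nbins = attr(labs, "n"))
  mask <- labs == which.max(sizes)
  for (k in seq_len(dim(x)[3])) {
    sl <- mask[, , k]
    if (any(sl)) mask[, , k] <- EBImage::fillHull(sl * 1L) > 0
  }
  mask
}

#' Three-class tissue segmentation by intensity clustering
#'
#' One-dimensional k-means (k = 3, 10 restarts, seed-controlled) on the
#' voxel intensities inside the brain mask; classes are named by
#' ascending mean intensity, which on T2-weighted contrast is
#' white matter < grey matter < CSF.
#'
#' @param volume an [image_volume()].
#' @param mask logical brain mask from [extract_brain()].
#' @param k number of classes (default 3).
#' @param seed integer seed for the k-means restarts.
#' @return a `tissue_seg` list: `labels` (0 outside, 1 WM, 2 GM, 3 CSF),
#'   `means` (per-class mean intensity, ascending), `spacing`.
#' @export
segment_tissues <- function(volume, mask, k = 3, seed = 1) {
  stopifnot(inherits(volume, "image_volume"))
  vals <- volume$data[mask]
  if (length(vals) == 0) stop_user("segment_tissues: empty mask")
  if (length(unique(vals)) < k)
    stop_user("segment_tissues: fewer than ", k, " distinct intensities in mask")
  km <- with_seed(seed, kmeans(vals, centers = k, nstart = 10, iter.max = 100))
  ord <- order(km$centers)
  rank_of <- integer(k)
  rank_of[ord] <- seq_len(k)
  labels <- array(0L, dim(volume$data))
  labels[mask] <- rank_of[km$cluster]
  means <- sort(as.vector(km$centers))
  names(means) <- if (k == 3) c("WM", "GM", "CSF") else paste0("class", seq_len(k))
  structure(list(labels = labels, means = means, spacing = volume$spacing),
            class = "tissue_seg")
}

#' @export
print.tissue_seg <- function(x, ...) {
  cat("<tissue_seg>", paste(names(x$means), round(x$means, 1), sep = "=",
                            collapse = ", "), "\n")
  vols <- compute_tissue_volumes(x)
  cat(sprintf("  brain %.0f mm^3, WM %.0f mm^3\n",
              vols$brain_volume_mm3, vols$wm_volume_mm3))
  invisible(x)
}

#' Locate the lateral ventricles and the supraventricular boundary
#'
#' Ventricles are the CSF-class 26-connected components whose in-plane
#' centroid lies within the central third of the field of view and whose
#' volume exceeds `min_volume_mm3` (default 500 mm^3, which rejects the
#' small CSF-bright perivascular structures). The boundary slice `z_v` is
#' the superior-most slice the ventricle mask reaches.
#'
#' @param seg a `tissue_seg` from [segment_tissues()].
#' @param min_volume_mm3 minimum ventricle component volume.
#' @param central_frac in-plane centroid window as a fraction of each
#'   in-plane dimension, centred.
#' @return list with `mask` (logical ventricle mask) and `z_v`
#'   (superior-most ventricle slice index, 1-based).
#' @export
find_ventricles <- function(seg, min_volume_mm3 = 500, central_frac = 1/3) {
  stopifnot(inherits(seg, "tissue_seg"))
  csf <- seg$labels == 3L
  if (!any(csf)) stop_user("find_ventricles: ventricles not found (no CSF class)")
  labs <- label_components(csf, "3d26")
  n <- attr(labs, "n")
  d <- dim(labs)
  vv <- prod(seg$spacing)
  keep <- logical(n)
  idx <- which(labs > 0L)
  ijk <- arrayInd(idx, d)
  comp <- labs[idx]
  for (c0 in seq_len(n)) {
    sel <- comp == c0
    if (sum(sel) * vv <= min_volume_mm3) next
    cen <- colMeans(ijk[sel, , drop = FALSE])
    half <- d[1:2] * central_frac / 2
    if (abs(cen[1] - (d[1] + 1) / 2) <= half[1] &&
        abs(cen[2] - (d[2] + 1) / 2) <= half[2]) keep[c0] <- TRUE
  }
  if (!any(keep)) stop_user("find_ventricles: ventricles not found")
  mask <- array(labs > 0L & keep[pmax(labs, 1L)], d)
  z_v <- max(slice_index_array(d)[mask])
  list(mask = mask, z_v = as.integer(z_v))
}

#' Supraventricular white-matter region of interest
#'
#' The counting region: on every slice at or above the ventricle boundary
#' `z_v`, white-matter voxels plus any voxels fully enclosed by white
#' matter in-plane (CSF-bright perivascular spaces must not be excluded
#' by their own brightness), minus the ventricle mask itself.
#'
#' @param seg a `tissue_seg`.
#' @param ventricles result of [find_ventricles()], or a list with `mask`
#'   and `z_v`.
#' @param z_v optional override of the boundary slice.
#' @return list with logical `mask` and `z_v`.
#' @export
supraventricular_roi <- function(seg, ventricles, z_v = NULL) {
  stopifnot(inherits(seg, "tissue_seg"))
  z_v <- as.integer(z_v %||% ventricles$z_v)
  d <- dim(seg$labels)
  if (z_v < 1 || z_v > d[3])
    stop_user("supraventricular_roi: z_v = ", z_v, " outside the slice range")
  wm <- seg$labels == 1L
  roi <- array(FALSE, d)
  for (k in z_v:d[3]) {
    sl <- wm[, , k]
    if (!any(sl)) next
    roi[, , k] <- EBImage::fillHull(sl * 1L) > 0
  }
  roi <- roi & !ventricles$mask
  if (!any(roi)) stop_user("supraventricular_roi: empty region of interest")
  list(mask = roi, z_v = z_v)
}

#' Brain and tissue volumes from a segmentation
#'
#' Class voxel counts times the voxel volume.
#'
#' @param seg a `tissue_seg`.
#' @param spacing optional spacing override (mm).
#' @return list with `brain_volume_mm3`, `wm_volume_mm3`,
#'   `gm_volume_mm3`, `csf_volume_mm3`.
#' @export
compute_tissue_volumes <- function(seg, spacing = NULL) {
  stopifnot(inherits(seg, "tissue_seg"))
  vv <- voxel_volume(spacing %||% seg$spacing)
  list(brain_volume_mm3 = sum(seg$labels > 0L) * vv,
       wm_volume_mm3 = sum(seg$labels == 1L) * vv,
       gm_volume_mm3 = sum(seg$labels == 2L) * vv,
       csf_volume_mm3 = sum(seg$labels == 3L) * vv)
}
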