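#' Binarize a vesselness field within the counting region
#'
#' @param V 3D vesselness array (values in `[0, 1]`).
#' @param roi logical region-of-interest mask (same shape).
#' @param t threshold, strictly inside (0, 1). The default 0.25 was
#'   calibrated once on noisy calibration phantoms so that component
#'   volumes are unbiased while every embedded tube stays covered; it is
#'   recorded in the provenance of every metric.
#' @return logical mask `(V >= t) & roi`.
#' @export
threshold_vesselness <- function(V, roi, t = 0.25) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1)
    stop_user("threshold_vesselness: threshold must lie strictly in (0, 1)")
  stopifnot(identical(dim(V), dim(roi)))
  (V >= t) & roi
}

#' Assemble the per-subject perivascular-space metrics
#'
#' @param labels filtered component label array ([label_components()] then
#'   [filter_components()]).
#' @param spacing voxel spacing (mm).
#' @param wm_volume_mm3,brain_volume_mm3 tissue volumes passed through
#'   from the segmentation stage.
#' @param provenance named list recording the parameters that produced
#'   the mask (threshold, scales, connectivity, seeds, config hash).
#' @return a `vrs_metrics` object: `vrs_count`, `vrs_volume_mm3`,
#'   `wm_volume_mm3`, `brain_volume_mm3`, `components` (per-component
#'   voxel count and volume), `provenance`.
#' @export
compute_vrs_metrics <- function(labels, spacing, wm_volume_mm3 = NA_real_,
                                brain_volume_mm3 = NA_real_,
                                provenance = list()) {
  vv <- voxel_volume(spacing)
  n <- attr(labels, "n") %||% max(labels, 0L)
  sizes <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  structure(list(
    vrs_count = as.integer(n),
    vrs_volume_mm3 = sum(sizes) * vv,
    wm_volume_mm3 = wm_volume_mm3,
    brain_volume_mm3 = brain_volume_mm3,
    components = data.frame(component = seq_len(n), voxels = sizes,
                            volume_mm3 = sizes * vv),
    provenance = provenance),
    class = "vrs_metrics")
}

#' @export
print.vrs_metrics <- function(x, ...) {
  cat("<vrs_metrics>\n")
  cat(sprintf("  VRs count : %d\n", x$vrs_count))
  cat(sprintf("  VRs volume: %.2f mm^3\n", x$vrs_volume_mm3))
  cat(sprintf("  WM volume : %.0f mm^3\n", x$wm_volume_mm3))
  cat(sprintf("  Brain vol : %.0f mm^3\n", x$brain_volume_mm3))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(v), collapse = ","), ""),
                               sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vrs_metrics <- function(x, ...) {
  data.frame(vrs_count = x$vrs_count, vrs_volume_mm3 = x$vrs_volume_mm3,
             wm_volume_mm3 = x$wm_volume_mm3,
             brain_volume_mm3 = x$brain_volume_mm3)
}

#' Pipeline configuration for one subject
#'
#' @param vesselness a [vesselness_params()].
#' @param threshold vesselness threshold in (0, 1).
#' @param min_voxels,max_voxels component size filter (voxels).
#' @param connectivity `"3d26"` (one anatomical space crossing slices
#'   counts once; default) or `"2d8"` (per-slice counting).
#' @param seg_seed seed for the k-means tissue clustering.
#' @param min_ventricle_volume_mm3 ventricle detector volume floor.
#' @param save_intermediates optional directory for stage outputs
#'   (NIfTI).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(vesselness = vesselness_params(), threshold = 0.25,
                            min_voxels = 2, max_voxels = Inf,
                            connectivity = c("3d26", "2d8"), seg_seed = 1,
                            min_ventricle_volume_mm3 = 500,
                            save_intermediates = NULL) {
  connectivity <- match.arg(connectivity)
  if (threshold <= 0 || threshold >= 1)
    stop_user("pipeline_config: threshold must lie strictly in (0, 1)")
  structure(list(vesselness = vesselness, threshold = threshold,
                 min_voxels = min_voxels, max_voxels = max_voxels,
                 connectivity = connectivity, seg_seed = seg_seed,
                 min_ventricle_volume_mm3 = min_ventricle_volume_mm3,
                 save_intermediates = save_intermediates),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_user("[stage ", stage, "] ", conditionMessage(e)))
}

#' Run the full image-to-metrics pipeline on one subject
#'
#' Chains brain extraction, tissue segmentation, ventricle detection,
#' supraventricular ROI construction, multi-scale 2D vesselness,
#' thresholding, connected-component labelling, size filtering and
#' volumetry. Deterministic given (volume, config): the only stochastic
#' stage is the k-means restart set, which is seed-controlled.
#'
#' @param volume an [image_volume()].
#' @param config a [pipeline_config()].
#' @return a `vrs_metrics` object whose provenance records the threshold,
#'   scale set, beta, connectivity, segmentation seed and config hash.
#' @export
run_subject_pipeline <- function(volume, config = pipeline_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(config, "pipeline_config"))
  brain <- run_stage("extract_brain", extract_brain(volume))
  seg <- run_stage("segment_tissues",
                   segment_tissues(volume, brain, seed = config$seg_seed))
  vent <- run_stage("find_ventricles",
                    find_ventricles(seg, config$min_ventricle_volume_mm3))
  roi <- run_stage("supraventricular_roi", supraventricular_roi(seg, vent))
  ves <- run_stage("vesselness", vesselness_volume(volume, config$vesselness))
  mask <- run_stage("threshold",
                    threshold_vesselness(ves$V, roi$mask, config$threshold))
  labs <- run_stage("label_components",
                    label_components(mask, config$connectivity))
  labs <- run_stage("filter_components",
                    filter_components(labs, config$min_voxels, config$max_voxels))
  vols <- compute_tissue_volumes(seg)
  prov <- list(threshold = config$threshold,
               scales = config$vesselness$scales,
               beta = config$vesselness$beta,
               c = config$vesselness$c %||% "adaptive",
               connectivity = config$connectivity,
               seg_seed = config$seg_seed,
               z_v = roi$z_v,
               config_hash = object_hash(config[setdiff(names(config),
                                                        "save_intermediates")]))
  if (!is.null(config$save_intermediates)) {
    dir.create(config$save_intermediates, recursive = TRUE, showWarnings = FALSE)
    write_nifti(image_volume(ves$V, volume$spacing),
                file.path(config$save_intermediates, "vesselness.nii.gz"))
    write_nifti(image_volume(array(as.integer(labs), dim(labs)), volume$spacing),
                file.path(config$save_intermediates, "vrs_labels.nii.gz"))
    write_nifti(image_volume(seg$labels, volume$spacing),
                file.path(config$save_intermediates, "tissue_labels.nii.gz"))
  }
  compute_vrs_metrics(labs, volume$spacing, vols$wm_volume_mm3,
                      vols$brain_volume_mm3, prov)
}
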