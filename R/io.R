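# --- NIfTI ------------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1 file, reorients it to RAS+ so that the third axis
#' points superiorly (the package's "above the ventricles" convention),
#' and returns it with the voxel spacing from the header.
#'
#' @param path file path (.nii or .nii.gz).
#' @return an [image_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_user("read_nifti: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_user("read_nifti: malformed NIfTI: ",
                                                conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop_user("read_nifti: expected 3D data, got ", length(dim(img)), "D")
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  data <- as.array(img)
  if (any(!is.finite(data)))
    stop_user("read_nifti: volume contains non-finite voxels")
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(data), dim(data)), spacing)
}

#' Write an image volume as NIfTI-1
#'
#' Stores the data as float32 with an RAS+ affine built from the voxel
#' spacing.
#'
#' @param volume an [image_volume()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::sform(img) <- structure(diag(c(volume$spacing, 1)), code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "float")
    TRUE
  }, error = function(e) stop_user("write_nifti: cannot write ", path, ": ",
                                   conditionMessage(e)))
  invisible(path)
}

# --- cohort CSV -------------------------------------------------------------

cohort_schema <- c("subject_id", "group", "age_months", "sex", "ga_weeks",
                   "duration_min", "course_days", "hc_cm", "vrs_count",
                   "vrs_volume_mm3", "wm_volume_mm3", "brain_volume_mm3")
cohort_groups <- c("SFS>5M", "SFS<=5M", "control")

parse_numeric_strict <- function(v, col) {
  v <- trimws(v)
  out <- rep(NA_real_, length(v))
  filled <- !(is.na(v) | v == "" | toupper(v) == "NA")
  bad <- filled & !grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v)
  if (any(bad))
    stop_user("read_cohort_csv: column '", col, "' has non-numeric value '",
              v[which(bad)[1]], "'")
  out[filled] <- as.numeric(v[filled])
  out
}

#' Read a cohort table from CSV
#'
#' Enforces the interchange schema (`subject_id, group, age_months, sex,
#' ga_weeks, duration_min, course_days, hc_cm, vrs_count,
#' vrs_volume_mm3, wm_volume_mm3, brain_volume_mm3`), strict numeric
#' parsing (no thousands separators), known group labels, and the
#' duration/course contract: empty if and only if the subject is a
#' control.
#'
#' @param path CSV file path.
#' @return a typed cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_user("read_cohort_csv: no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(cohort_schema, names(raw))
  if (length(missing))
    stop_user("read_cohort_csv: schema mismatch, missing column(s): ",
              paste(missing, collapse = ", "))
  out <- raw[cohort_schema]
  bad_group <- setdiff(unique(out$group), cohort_groups)
  if (length(bad_group))
    stop_user("read_cohort_csv: unknown group label '", bad_group[1], "'")
  numcols <- setdiff(cohort_schema, c("subject_id", "group", "sex"))
  for (col in numcols) out[[col]] <- parse_numeric_strict(out[[col]], col)
  is_control <- out$group == "control"
  if (any(is_control & (!is.na(out$duration_min) | !is.na(out$course_days))))
    stop_user("read_cohort_csv: control subject has a seizure duration/course")
  if (any(!is_control & (is.na(out$duration_min) | is.na(out$course_days))))
    stop_user("read_cohort_csv: SFS subject missing seizure duration/course")
  out$group <- factor(out$group, levels = cohort_groups)
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[intersect(cohort_schema, names(cohort))], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

# --- fixture sets -----------------------------------------------------------

#' Write a reproducible phantom + cohort fixture set
#'
#' Simulates every configured phantom (noisy volume plus ground-truth
#' label map), generates the cohort CSV, and writes a JSON manifest
#' recording each file with its seed and MD5 so the set can be
#' regenerated bit-for-bit and verified.
#'
#' @param out_dir writable output directory (created if needed).
#' @param phantom_configs list of [phantom_config()] objects.
#' @param cohort_cfg a [cohort_config()] or NULL.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_set <- function(out_dir, phantom_configs = list(),
                              cohort_cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_user("write_fixture_set: cannot create directory ", out_dir)
  files <- list()
  for (i in seq_along(phantom_configs)) {
    cfg <- phantom_configs[[i]]
    sim <- simulate_phantom(cfg)
    vol_path <- file.path(out_dir, sprintf("phantom_%02d.nii.gz", i))
    lab_path <- file.path(out_dir, sprintf("phantom_%02d_truth.nii.gz", i))
    write_nifti(sim$volume, vol_path)
    write_nifti(image_volume(sim$truth$vrs_labels + 0, sim$volume$spacing),
                lab_path)
    files[[basename(vol_path)]] <- list(seed = cfg$seed,
                                        md5 = unname(tools::md5sum(vol_path)))
    files[[basename(lab_path)]] <- list(seed = cfg$seed,
                                        md5 = unname(tools::md5sum(lab_path)))
  }
  if (!is.null(cohort_cfg)) {
    coh <- generate_cohort(cohort_cfg)
    coh_path <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(coh, coh_path)
    files[["cohort.csv"]] <- list(seed = cohort_cfg$seed,
                                  md5 = unname(tools::md5sum(coh_path)))
  }
  manifest <- list(tool_version = as.character(utils::packageVersion("vrsquant")),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# --- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The resolved parameter blocks of every stage, suitable for YAML
#' round-tripping; every run writes its resolved copy next to its
#' outputs so any reported metric is reproducible.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "vrsquant-output",
    log_level = "info",
    phantom = list(n_structures = 25L, full = FALSE, noise_sigma = 5),
    vesselness = list(scales = c(0.375, 0.75, 1.125, 1.5), beta = 0.5,
                      c = NULL),
    quantify = list(threshold = 0.25, min_voxels = 2L, max_voxels = NULL,
                    connectivity = "3d26"),
    stats = list(span = 0.5, cutoff_metric = "vrs_count", alpha = 0.05))
}

validate_config_keys <- function(user, default, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(default))
      stop_user("config: unknown key '", full, "'")
    if (is.list(user[[k]]) && is.list(default[[k]]) &&
        !is.null(names(default[[k]])))
      validate_config_keys(user[[k]], default[[k]], full)
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending key path; known keys
#' override the defaults of [default_run_config()].
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return resolved configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_user("config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop_user("config: top level must be a mapping")
  validate_config_keys(user, cfg)
  modifyList(cfg, user, keep.null = TRUE)
}

write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved-config.yaml"))
}

build_manifest <- function(cfg, seeds, files, timings) {
  list(tool_version = as.character(utils::packageVersion("vrsquant")),
       config_hash = object_hash(cfg),
       seeds = seeds,
       files = lapply(files, function(f) unname(tools::md5sum(f))),
       timings_s = timings)
}
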