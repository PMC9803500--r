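#' Describe one embedded perivascular-space structure
#'
#' Visible Virchow-Robin spaces appear on axial T2 slices either as linear
#' (a vessel running in-plane or obliquely) or circular (a vessel crossed
#' end-on) bright structures. Both are modelled as cylinders of CSF-like
#' intensity: `kind = "linear"` with a free orientation, `kind = "circular"`
#' as a through-plane cylinder seen as a disk on each slice it crosses.
#'
#' @param kind `"linear"` or `"circular"`.
#' @param center structure centre in (fractional) voxel coordinates, length 3.
#' @param orientation axis direction (length-3, need not be unit length);
#'   forced to the slice axis for circular structures.
#' @param length_mm cylinder length in mm (default 6 linear / 4 circular).
#' @param radius_mm cylinder radius in mm (default 0.75, one in-plane voxel
#'   at the acquisition geometry).
#' @param intensity painted intensity; `NULL` means the phantom's CSF mean.
#' @return a `vrs_structure` spec.
#' @export
vrs_structure <- function(kind = c("linear", "circular"), center,
                          orientation = c(0, 0, 1), length_mm = NULL,
                          radius_mm = 0.75, intensity = NULL) {
  kind <- match.arg(kind)
  if (kind == "circular") orientation <- c(0, 0, 1)
  if (is.null(length_mm)) length_mm <- if (kind == "linear") 6 else 4
  if (!is.numeric(center) || length(center) != 3L)
    stop_user("vrs_structure: 'center' must be length-3 voxel coordinates")
  if (radius_mm <= 0) stop_user("vrs_structure: 'radius_mm' must be > 0")
  if (length_mm < radius_mm)
    stop_user("vrs_structure: 'length_mm' must be >= 'radius_mm'")
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop_user("vrs_structure: zero orientation vector")
  structure(list(kind = kind, center = as.numeric(center),
                 orientation = as.numeric(orientation) / nrm,
                 length_mm = length_mm, radius_mm = radius_mm,
                 intensity = intensity),
            class = "vrs_structure")
}

#' Phantom configuration
#'
#' Defaults give a desk-scale T2-like head phantom: 160 x 160 in-plane at
#' the acquisition's 0.75 mm pixel (a 120 mm field of view), 24 slices of
#' 4 mm. `full = TRUE` switches to the full acquisition matrix
#' (320 x 320, 240 mm field of view). Intensities follow T2 contrast:
#' CSF brightest, then grey matter, then white matter.
#'
#' @param dim grid size in voxels (x, y, slices).
#' @param spacing voxel spacing in mm.
#' @param wm_mean,gm_mean,csf_mean class mean intensities (T2-like scale);
#'   must satisfy `csf_mean > gm_mean > wm_mean`.
#' @param background_mean near-zero air intensity.
#' @param noise_sigma Rician noise level applied by [add_rician_noise()]
#'   in convenience wrappers (the raw phantom is noiseless).
#' @param brain_frac ellipsoid semi-axes as a fraction of the half field
#'   of view along each axis.
#' @param wm_frac normalised radius below which tissue is white matter
#'   (the shell outside it is grey matter).
#' @param ventricle_offset_mm lateral offset of the two paramedian
#'   ventricle ellipsoids from the midline.
#' @param ventricle_semiaxes_mm ventricle ellipsoid semi-axes (mm).
#' @param ventricle_top_slice superior-most slice index the ventricles
#'   reach (1-based); defines the supraventricular boundary.
#' @param structures list of [vrs_structure()] specs.
#' @param seed integer seed fixing the phantom (and any noise drawn from
#'   its convenience wrappers) bit-for-bit.
#' @param full logical; use the full 320 x 320 acquisition matrix.
#' @return a validated `phantom_config`.
#' @export
phantom_config <- function(dim = c(160, 160, 24), spacing = c(0.75, 0.75, 4),
                           wm_mean = 100, gm_mean = 130, csf_mean = 200,
                           background_mean = 2, noise_sigma = 5,
                           brain_frac = c(0.84, 0.92, 0.88), wm_frac = 0.85,
                           ventricle_offset_mm = 10,
                           ventricle_semiaxes_mm = c(7, 20, 14),
                           ventricle_top_slice = 12,
                           structures = list(), seed = 1, full = FALSE) {
  if (full) dim <- c(320, 320, dim[3])
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop_user("phantom_config: spacing must be positive")
  if (!(csf_mean > gm_mean && gm_mean > wm_mean))
    stop_user("phantom_config: T2 ordering requires csf_mean > gm_mean > wm_mean")
  if (noise_sigma < 0) stop_user("phantom_config: noise_sigma must be >= 0")
  if (ventricle_top_slice < 1 || ventricle_top_slice > dim[3])
    stop_user("phantom_config: ventricle_top_slice outside the slice range")
  ok <- vapply(structures, inherits, logical(1), what = "vrs_structure")
  if (length(structures) && !all(ok))
    stop_user("phantom_config: 'structures' must be vrs_structure objects")
  structure(list(dim = dim, spacing = spacing, wm_mean = wm_mean,
                 gm_mean = gm_mean, csf_mean = csf_mean,
                 background_mean = background_mean, noise_sigma = noise_sigma,
                 brain_frac = brain_frac, wm_frac = wm_frac,
                 ventricle_offset_mm = ventricle_offset_mm,
                 ventricle_semiaxes_mm = ventricle_semiaxes_mm,
                 ventricle_top_slice = as.integer(ventricle_top_slice),
                 structures = structures, seed = seed),
            class = "phantom_config")
}

# Normalised squared ellipsoid radius field over the grid.
ellipsoid_rho2 <- function(coords, center_mm, semiaxes_mm) {
  dx <- (coords[[1]] - center_mm[1]) / semiaxes_mm[1]
  dy <- (coords[[2]] - center_mm[2]) / semiaxes_mm[2]
  dz <- (coords[[3]] - center_mm[3]) / semiaxes_mm[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
}

# Logical mask of voxel centres inside a finite cylinder.
rasterize_cylinder <- function(dim3, spacing, center_mm, axis, length_mm, radius_mm) {
  coords <- axis_coords(dim3, spacing)
  half <- length_mm / 2
  reach <- half + radius_mm
  lo <- center_mm - reach
  hi <- center_mm + reach
  idx <- lapply(1:3, function(a) which(coords[[a]] >= lo[a] - spacing[a] &
                                       coords[[a]] <= hi[a] + spacing[a]))
  if (any(lengths(idx) == 0)) return(NULL)
  g <- expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]])
  px <- coords[[1]][g$i] - center_mm[1]
  py <- coords[[2]][g$j] - center_mm[2]
  pz <- coords[[3]][g$k] - center_mm[3]
  ax <- px * axis[1] + py * axis[2] + pz * axis[3]
  rad2 <- pmax(px^2 + py^2 + pz^2 - ax^2, 0)
  inside <- abs(ax) <= half & rad2 <= radius_mm^2
  if (!any(inside)) return(NULL)
  cbind(g$i[inside], g$j[inside], g$k[inside])
}

#' Generate a noiseless T2-like phantom with exact ground truth
#'
#' Builds a brain ellipsoid (white-matter core, grey-matter shell) above a
#' near-zero background, carves two paramedian CSF ventricles, and paints
#' every configured perivascular structure at its specified intensity.
#' Noise is deliberately not applied here; see [add_rician_noise()].
#'
#' @param config a [phantom_config()].
#' @return list with `volume` (an [image_volume()]) and `truth`, the ground
#'   truth holding `vrs_labels` (0 = background, k = structure id),
#'   `tissue` (0 outside, 1 WM, 2 GM, 3 CSF), `ventricle_mask`,
#'   `vrs_count`, `vrs_volume_mm3` (labelled voxels x voxel volume),
#'   `ventricle_top_slice`, and `overlaps` (id pairs merged in the mask).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim
  sp <- config$spacing
  coords <- axis_coords(d, sp)
  extent <- d * sp
  center <- extent / 2
  semi <- config$brain_frac * extent / 2

  rho2 <- ellipsoid_rho2(coords, center, semi)
  tissue <- array(0L, d)
  tissue[rho2 <= 1] <- 2L                      # grey-matter shell
  tissue[rho2 <= config$wm_frac^2] <- 1L       # white-matter core

  vz <- config$ventricle_semiaxes_mm[3]
  top_mm <- (config$ventricle_top_slice - 0.5) * sp[3] + 0.45 * sp[3]
  vcen_z <- top_mm - vz
  vent <- array(FALSE, d)
  for (side in c(-1, 1)) {
    vc <- c(center[1] + side * config$ventricle_offset_mm, center[2], vcen_z)
    vent <- vent | (ellipsoid_rho2(coords, vc, config$ventricle_semiaxes_mm) <= 1)
  }
  vent <- vent & tissue == 1L
  tissue[vent] <- 3L

  img <- array(config$background_mean, d)
  img[tissue == 1L] <- config$wm_mean
  img[tissue == 2L] <- config$gm_mean
  img[tissue == 3L] <- config$csf_mean

  vrs_labels <- array(0L, d)
  overlaps <- list()
  for (k in seq_along(config$structures)) {
    s <- config$structures[[k]]
    cen_mm <- (s$center - 0.5) * sp
    vox <- rasterize_cylinder(d, sp, cen_mm, s$orientation, s$length_mm, s$radius_mm)
    if (is.null(vox))
      stop_user("generate_phantom: structure ", k, " rasterizes to no voxels")
    lin <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
    if (any(tissue[lin] != 1L))
      stop_user("generate_phantom: structure ", k,
                " has voxels outside the white-matter compartment")
    prev <- unique(vrs_labels[lin])
    prev <- prev[prev != 0L]
    if (length(prev))
      overlaps <- c(overlaps, lapply(prev, function(p) c(p, k)))
    new <- lin[vrs_labels[lin] == 0L]
    vrs_labels[new] <- k
    img[lin] <- s$intensity %||% config$csf_mean
  }

  nvox <- sum(vrs_labels > 0L)
  truth <- list(vrs_labels = vrs_labels, tissue = tissue, ventricle_mask = vent,
                vrs_count = length(config$structures),
                vrs_volume_mm3 = nvox * prod(sp),
                ventricle_top_slice = config$ventricle_top_slice,
                overlaps = overlaps)
  list(volume = image_volume(img, sp), truth = truth)
}

#' Add Rician (magnitude-MR) noise to a volume
#'
#' Each voxel value v is replaced by `sqrt((v + n1)^2 + n2^2)` with n1, n2
#' independent zero-mean Gaussians of standard deviation `sigma` -- the
#' noise model of magnitude MR reconstruction. At zero signal this gives a
#' Rayleigh law (mean `sigma * sqrt(pi / 2)`); at high signal-to-noise it
#' approaches additive Gaussian noise of the same sigma.
#'
#' @param volume an [image_volume()].
#' @param sigma noise level in intensity units; 0 returns the input
#'   unchanged.
#' @param seed integer seed; the same (volume, sigma, seed) always yields
#'   the same output.
#' @return a noisy [image_volume()].
#' @export
add_rician_noise <- function(volume, sigma, seed = 1) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop_user("add_rician_noise: 'sigma' must be a single number >= 0")
  if (sigma == 0) return(volume)
  n <- length(volume$data)
  noisy <- with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    sqrt((as.vector(volume$data) + n1)^2 + n2^2)
  })
  image_volume(array(noisy, dim(volume$data)), volume$spacing)
}

#' Draw well-separated random perivascular structures for a phantom
#'
#' Samples structure centres inside the supraventricular white matter of
#' the configured phantom geometry (slices at and above the ventricle top,
#' away from the tissue boundaries), alternating linear and circular
#' kinds, with a minimum centre-to-centre separation so that the true
#' structure count is unambiguous.
#'
#' @param config a [phantom_config()] (its `structures` are ignored).
#' @param n number of structures.
#' @param seed integer seed.
#' @param min_sep_mm minimum centre separation (mm).
#' @param length_range_mm range of linear structure lengths (mm).
#' @return a list of [vrs_structure()] specs, usable as
#'   `phantom_config(structures = ...)`.
#' @export
random_vrs_structures <- function(config, n, seed = 1, min_sep_mm = 8,
                                  length_range_mm = c(3, 8)) {
  stopifnot(inherits(config, "phantom_config"), n >= 0)
  if (n == 0) return(list())
  d <- config$dim
  sp <- config$spacing
  coords <- axis_coords(d, sp)
  extent <- d * sp
  center <- extent / 2
  semi <- config$brain_frac * extent / 2
  rho2 <- ellipsoid_rho2(coords, center, semi)

  # candidate interior: well inside WM, above the ventricles, clear of them
  vz <- config$ventricle_semiaxes_mm[3]
  top_mm <- (config$ventricle_top_slice - 0.5) * sp[3] + 0.45 * sp[3]
  vent_guard <- array(FALSE, d)
  for (side in c(-1, 1)) {
    vc <- c(center[1] + side * config$ventricle_offset_mm, center[2], top_mm - vz)
    vent_guard <- vent_guard |
      (ellipsoid_rho2(coords, vc, config$ventricle_semiaxes_mm + c(3, 3, 6)) <= 1)
  }
  zidx <- slice_index_array(d)
  tissue_wm <- rho2 <= config$wm_frac^2 & !vent_guard
  cand <- which(rho2 <= (0.75 * config$wm_frac)^2 & !vent_guard &
                zidx >= config$ventricle_top_slice & zidx <= d[3] - 1L)
  if (!length(cand))
    stop_user("random_vrs_structures: no candidate supraventricular WM voxels")

  with_seed(seed, {
    axes <- list()   # per placed structure: endpoints of the cylinder axis
    specs <- list()
    tries <- 0
    while (length(specs) < n && tries < 1000 * n) {
      tries <- tries + 1
      lin <- sample(cand, 1)
      ijk <- arrayInd(lin, d)
      pos_mm <- (as.numeric(ijk) - 0.5) * sp
      if (length(specs) %% 2 == 0) {
        ang <- runif(1, 0, pi)
        s <- vrs_structure("linear", center = as.numeric(ijk),
                           orientation = c(cos(ang), sin(ang), 0),
                           length_mm = runif(1, length_range_mm[1],
                                             length_range_mm[2]))
      } else {
        s <- vrs_structure("circular", center = as.numeric(ijk))
      }
      a <- pos_mm - s$orientation * s$length_mm / 2
      b <- pos_mm + s$orientation * s$length_mm / 2
      # keep the whole capsule away from every placed one (segment-segment
      # distance), so thresholded masks cannot bridge components
      if (length(axes) &&
          min(vapply(axes, function(e) segment_distance(a, b, e$a, e$b),
                     numeric(1))) < min_sep_mm) next
      # the structure must rasterize fully inside supraventricular WM
      vox <- rasterize_cylinder(d, sp, pos_mm, s$orientation, s$length_mm,
                                s$radius_mm)
      if (is.null(vox)) next
      linv <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
      # every voxel must sit in supraventricular WM and clear of the
      # ventricle guard: a CSF-bright voxel 26-adjacent to the ventricles
      # would merge into their component and corrupt the boundary slice
      if (!all(tissue_wm[linv]) || any(vent_guard[linv]) ||
          any(vox[, 3] < config$ventricle_top_slice))
        next
      specs[[length(specs) + 1]] <- s
      axes[[length(axes) + 1]] <- list(a = a, b = b)
    }
    if (length(specs) < n)
      stop_user("random_vrs_structures: could not place ", n,
                " structures at min_sep_mm = ", min_sep_mm)
    specs
  })
}

# Minimum distance between two 3D segments (a1-b1, a2-b2).
segment_distance <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1
  d2 <- b2 - a2
  r <- a1 - a2
  A <- sum(d1 * d1); B <- sum(d1 * d2); C <- sum(d2 * d2)
  D <- sum(d1 * r); E <- sum(d2 * r)
  den <- A * C - B^2
  s <- if (den > 1e-12) max(0, min(1, (B * E - C * D) / den)) else 0
  t <- if (C > 1e-12) max(0, min(1, (B * s + E) / C)) else 0
  s <- if (A > 1e-12) max(0, min(1, (B * t - D) / A)) else 0
  p <- a1 + s * d1
  q <- a2 + t * d2
  sqrt(sum((p - q)^2))
}

# 3D array whose value at every voxel is its slice index.
slice_index_array <- function(dim3) {
  array(rep(seq_len(dim3[3]), each = dim3[1] * dim3[2]), dim3)
}

#' Simulate a noisy phantom in one call
#'
#' Convenience wrapper: [generate_phantom()] followed by
#' [add_rician_noise()] at the configured `noise_sigma`, with the noise
#' seed derived from the config seed.
#'
#' @param config a [phantom_config()].
#' @return list with `volume` (noisy), `clean` (noiseless) and `truth`.
#' @export
simulate_phantom <- function(config) {
  ph <- generate_phantom(config)
  noisy <- add_rician_noise(ph$volume, config$noise_sigma,
                            seed = derive_seed(config$seed, "rician"))
  list(volume = noisy, clean = ph$volume, truth = ph$truth)
}
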