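# Symmetric (mirror) 1D padding indices for length n and pad p.
pad_idx <- function(n, p) {
  if (p == 0) return(seq_len(n))
  left <- pmin(pmax(p:1, 1L), n)
  right <- pmin(pmax(n:(n - p + 1), 1L), n)
  c(left, seq_len(n), right)
}

# Convolve along the first dimension with symmetric boundary handling.
conv_dim1 <- function(X, kern) {
  n <- nrow(X)
  p <- (length(kern) - 1L) %/% 2L
  Xp <- X[pad_idx(n, p), , drop = FALSE]
  out <- matrix(0, n, ncol(X))
  for (t in seq_along(kern))
    out <- out + kern[t] * Xp[t:(t + n - 1L), , drop = FALSE]
  out
}

conv_sep <- function(X, kern_x, kern_y) {
  t(conv_dim1(t(conv_dim1(X, kern_x)), kern_y))
}

# Sampled Gaussian-derivative kernels (order 0, 1 or 2), in pixel units.
# Discrete moments are corrected so sampling cannot leak: the smoothing
# kernel sums to 1, the first-derivative kernel is exact on linear ramps,
# and the second-derivative kernel annihilates constants and ramps and is
# exact on quadratics, even at sub-pixel sigma.
gaussian_kernel <- function(sigma_px, order = 0L) {
  r <- max(1L, ceiling(4 * sigma_px))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    g1 <- -t / sigma_px^2 * g
    return(g1 / (-sum(t * g1)))
  }
  if (order == 2L) {
    g2 <- (t^2 / sigma_px^4 - 1 / sigma_px^2) * g
    g2 <- g2 - sum(g2) / length(g2)
    return(g2 * (2 / sum(t^2 * g2)))
  }
  stop("unsupported derivative order")
}

#' Parameters of the multi-scale 2D Frangi filter
#'
#' @param scales Gaussian scales sigma in mm (default 0.375--1.5 mm,
#'   bracketing the sub-millimetre calibre of visible perivascular
#'   spaces; the filter responds maximally when sigma is near half the
#'   structure width).
#' @param beta blobness weight of the eccentricity term (default 0.5, the
#'   customary choice).
#' @param c structureness weight; `NULL` (default) resolves it
#'   adaptively per slice and scale to half the maximum Hessian
#'   Frobenius norm, a standard data-driven setting.
#' @return a `vesselness_params` list. Polarity is fixed bright-on-dark,
#'   as perivascular spaces are CSF-bright on T2.
#' @export
vesselness_params <- function(scales = c(0.375, 0.75, 1.125, 1.5),
                              beta = 0.5, c = NULL) {
  if (!length(scales) || any(scales <= 0))
    stop_user("vesselness_params: scales must be positive (mm)")
  if (beta <= 0) stop_user("vesselness_params: beta must be > 0")
  if (!is.null(c) && c <= 0) stop_user("vesselness_params: c must be > 0")
  structure(list(scales = as.numeric(scales), beta = beta, c = c,
                 polarity = "bright"),
            class = "vesselness_params")
}

#' Scale-normalised 2D Hessian of an axial slice
#'
#' Gaussian-derivative convolution at physical scale `sigma` (mm,
#' converted to pixels through the in-plane spacing so results are
#' resolution-independent), with symmetric boundary handling, multiplied
#' by sigma^2 (gamma = 1 scale normalisation) for cross-scale
#' comparability.
#'
#' @param slice numeric matrix (one axial slice; first index = x).
#' @param sigma scale in mm, > 0.
#' @param spacing in-plane pixel spacing in mm, length 2.
#' @return a `hessian_field` list with matrices `Hxx`, `Hxy`, `Hyy` and
#'   the scale `sigma`.
#' @export
hessian_2d <- function(slice, sigma, spacing = c(0.75, 0.75)) {
  stopifnot(is.matrix(slice))
  if (sigma <= 0) stop_user("hessian_2d: sigma must be > 0")
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop_user("hessian_2d: spacing must be > 0")
  sx <- sigma / spacing[1]
  sy <- sigma / spacing[2]
  if (min(sx, sy) < 0.5)
    warning("hessian_2d: sigma below half a pixel; response is undersmoothed",
            call. = FALSE)
  g0x <- gaussian_kernel(sx, 0); g1x <- gaussian_kernel(sx, 1); g2x <- gaussian_kernel(sx, 2)
  g0y <- gaussian_kernel(sy, 0); g1y <- gaussian_kernel(sy, 1); g2y <- gaussian_kernel(sy, 2)
  # pixel-unit derivatives -> mm^-2, then gamma-normalise by sigma^2
  Hxx <- conv_sep(slice, g2x, g0y) * sigma^2 / spacing[1]^2
  Hyy <- conv_sep(slice, g0x, g2y) * sigma^2 / spacing[2]^2
  Hxy <- conv_sep(slice, g1x, g1y) * sigma^2 / (spacing[1] * spacing[2])
  structure(list(Hxx = Hxx, Hxy = Hxy, Hyy = Hyy, sigma = sigma),
            class = "hessian_field")
}

#' Closed-form eigenvalues of a 2D Hessian field
#'
#' Per-pixel eigenvalues of the symmetric 2x2 Hessian, ordered by
#' absolute value so `|lambda1| <= |lambda2|`; an exact tie
#' `|lambda1| == |lambda2|` is broken by `lambda1 >= lambda2`.
#'
#' @param h a `hessian_field` from [hessian_2d()].
#' @return list of matrices `l1`, `l2`.
#' @export
eigvals_2d <- function(h) {
  stopifnot(inherits(h, "hessian_field"))
  half_tr <- (h$Hxx + h$Hyy) / 2
  disc <- sqrt(((h$Hxx - h$Hyy) / 2)^2 + h$Hxy^2)
  e1 <- half_tr + disc   # algebraically larger
  e2 <- half_tr - disc
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  list(l1 = l1, l2 = l2)
}

#' Frangi vesselness measure for bright 2D tubular structures
#'
#' `V = exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` when
#' `lambda2 < 0` (bright structure on dark background) and 0 otherwise,
#' with blobness `R_B = lambda1 / lambda2` (set to 0 where
#' `lambda2 == 0`, where the structureness factor vanishes anyway) and
#' structureness `S = sqrt(lambda1^2 + lambda2^2)`.
#'
#' @param l1,l2 eigenvalue matrices from [eigvals_2d()] (or scalars).
#' @param beta,c positive weights.
#' @return vesselness in `[0, 1]`, same shape as the input.
#' @export
#' @examples
#' vesselness_2d(0, -10, beta = 0.5, c = 5)  # 1 - exp(-2)
vesselness_2d <- function(l1, l2, beta = 0.5, c = 1) {
  if (beta <= 0 || c <= 0) stop_user("vesselness_2d: beta and c must be > 0")
  Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  S2 <- l1^2 + l2^2
  V <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c^2)))
  V[l2 >= 0] <- 0
  V
}

#' Multi-scale 2D vesselness of one axial slice
#'
#' Per-pixel maximum of the Frangi measure over the configured scale set,
#' recording the scale attaining the maximum. The structureness weight
#' `c`, when not fixed in the parameters, is resolved per slice as half
#' the maximum gamma-normalised Hessian Frobenius norm across the whole
#' scale set: one shared c keeps the scale responses comparable, which is
#' what makes the per-pixel argmax a meaningful scale estimate
#' (normalising each scale by its own maximum would erase the amplitude
#' ordering and collapse the argmax to the first scale).
#'
#' @param slice numeric matrix.
#' @param params a [vesselness_params()].
#' @param spacing in-plane spacing (mm), length 2.
#' @return a `vesselness_map` list: `V` (in `[0, 1]`), `scale` (argmax
#'   scale in mm, NA where V = 0), `params`.
#' @export
multiscale_vesselness <- function(slice, params = vesselness_params(),
                                  spacing = c(0.75, 0.75)) {
  stopifnot(inherits(params, "vesselness_params"))
  V <- matrix(0, nrow(slice), ncol(slice))
  best_scale <- matrix(NA_real_, nrow(slice), ncol(slice))
  eigs <- lapply(params$scales, function(s)
    eigvals_2d(hessian_2d(slice, s, spacing)))
  smax <- sqrt(max(vapply(eigs, function(ev) max(ev$l1^2 + ev$l2^2),
                          numeric(1))))
  # a flat slice leaves only machine-epsilon residue in the Hessian;
  # don't let the adaptive c amplify it into a response
  if (smax > 1e-10 * (max(abs(slice)) + 1)) {
    c_eff <- params$c %||% (smax / 2)
    for (i in seq_along(params$scales)) {
      Vs <- vesselness_2d(eigs[[i]]$l1, eigs[[i]]$l2, params$beta, c_eff)
      upd <- Vs > V
      V[upd] <- Vs[upd]
      best_scale[upd] <- params$scales[i]
    }
  }
  structure(list(V = V, scale = best_scale, params = params),
            class = "vesselness_map")
}

#' Multi-scale vesselness of every axial slice of a volume
#'
#' @param volume an [image_volume()].
#' @param params a [vesselness_params()].
#' @return list with 3D arrays `V` and `scale`.
#' @export
vesselness_volume <- function(volume, params = vesselness_params()) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  V <- array(0, d)
  sc <- array(NA_real_, d)
  for (k in seq_len(d[3])) {
    vm <- multiscale_vesselness(volume$data[, , k], params, volume$spacing[1:2])
    V[, , k] <- vm$V
    sc[, , k] <- vm$scale
  }
  list(V = V, scale = sc, params = params)
}
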