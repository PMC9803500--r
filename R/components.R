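#' Label connected components of a binary mask
#'
#' Standard connected-component labelling with the two connectivities the
#' counting stage needs: `"3d26"` (26-neighbour, default) so a
#' perivascular space spanning adjacent slices counts once, or `"2d8"`
#' (8-neighbour within each slice, no through-plane links) for per-slice
#' counting. Implemented as a frontier breadth-first search over a
#' 1-voxel zero-padded copy, so each frontier expansion is a single
#' vectorised neighbourhood lookup.
#'
#' @param mask logical 3D array.
#' @param connectivity `"3d26"` or `"2d8"`.
#' @return integer array of the same shape, 0 = background, with attribute
#'   `"n"` giving the number of components.
#' @export
label_components <- function(mask, connectivity = c("3d26", "2d8")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  dp <- d + 2L
  maskp <- array(FALSE, dp)
  maskp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.logical(mask)
  maskv <- as.vector(maskp)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  if (connectivity == "2d8") off <- off[off$dk == 0, ]
  deltas <- off$di + dp[1] * off$dj + dp[1] * dp[2] * off$dk

  labs <- integer(length(maskv))
  fg <- which(maskv)
  ncomp <- 0L
  for (seed in fg) {
    if (labs[seed] != 0L) next
    ncomp <- ncomp + 1L
    labs[seed] <- ncomp
    frontier <- seed
    while (length(frontier)) {
      nb <- as.vector(outer(frontier, deltas, `+`))
      nb <- unique(nb[maskv[nb] & labs[nb] == 0L])
      labs[nb] <- ncomp
      frontier <- nb
    }
  }
  labp <- array(labs, dp)
  out <- labp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  out <- array(out, d)
  attr(out, "n") <- ncomp
  out
}

#' Remove components outside a size range
#'
#' Suppresses single-voxel noise components (the default keeps components
#' of at least 2 voxels, with no upper limit) and densely relabels the
#' survivors 1..K in ascending original-label order.
#'
#' @param labels integer label array from [label_components()].
#' @param min_voxels minimum component size in voxels (>= 1).
#' @param max_voxels maximum component size in voxels.
#' @return filtered, densely relabelled integer array with attribute `"n"`.
#' @export
filter_components <- function(labels, min_voxels = 2, max_voxels = Inf) {
  if (min_voxels < 1) stop_user("filter_components: min_voxels must be >= 1")
  n <- max(labels, 0L)
  if (n == 0L) {
    attr(labels, "n") <- 0L
    return(labels)
  }
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  keep <- which(sizes >= min_voxels & sizes <= max_voxels)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  out <- labels
  pos <- out > 0L
  out[pos] <- map[out[pos]]
  attr(out, "n") <- length(keep)
  out
}
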