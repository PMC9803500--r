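# Independent oracles and small fixture builders shared across test files.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force connected-component labelling by stack-based flood fill with
# an explicit neighbour offset set; deliberately naive and independent of
# the package's frontier-BFS implementation.
brute_label <- function(mask, offsets) {
  d <- dim(mask)
  labs <- array(0L, d)
  comp <- 0L
  for (lin in which(mask)) {
    if (labs[lin] != 0L) next
    comp <- comp + 1L
    stack <- lin
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labs[cur] != 0L) next
      labs[cur] <- comp
      ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(offsets))) {
        nb <- ijk + offsets[r, ]
        if (any(nb < 1) || any(nb > d)) next
        nlin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[nlin] && labs[nlin] == 0L) stack <- c(stack, nlin)
      }
    }
  }
  attr(labs, "n") <- comp
  labs
}

offsets_3d26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(g != 0) > 0, ]
})
offsets_2d8 <- offsets_3d26[offsets_3d26[, 3] == 0, ]
offsets_2d4 <- offsets_2d8[rowSums(abs(offsets_2d8)) == 1, ]

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free samples only).
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  U_obs <- sum(outer(x, y, `>`))
  U_obs <- min(U_obs, n1 * (n - n1) - U_obs)
  sets <- utils::combn(n, n1)
  Us <- apply(sets, 2, function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    u <- sum(outer(xx, yy, `>`))
    min(u, n1 * (n - n1) - u)
  })
  mean(Us <= U_obs)
}

# Tricube-weighted least-squares fit evaluated at a single point; the
# independent check for the package's local regression.
wls_at_point <- function(x, y, x0, span, degree = 1) {
  q <- ceiling(span * length(x))
  d <- abs(x - x0)
  idx <- order(d)[seq_len(q)]
  w <- (1 - pmin(d[idx] / d[idx[q]], 1)^3)^3
  if (degree == 0) return(weighted.mean(y[idx], w))
  fit <- lm(y[idx] ~ I(x[idx] - x0), weights = w)
  unname(coef(fit)[1])
}

# A small phantom configuration used by the image-stage tests (full default
# geometry; structures supplied per test).
test_phantom <- function(structures = list(), seed = 1, ...) {
  phantom_config(structures = structures, seed = seed, ...)
}

# Bilinear rotation of a matrix about its centre (degrees), used by the
# rotation-equivariance test.
rotate_bilinear <- function(img, angle_deg) {
  n <- nrow(img); m <- ncol(img)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    # source coordinates under inverse rotation
    xs <- cx + cos(th) * (i - cx) + sin(th) * (j - cy)
    ys <- cy - sin(th) * (i - cx) + cos(th) * (j - cy)
    x0 <- floor(xs); y0 <- floor(ys)
    if (x0 < 1 || y0 < 1 || x0 + 1 > n || y0 + 1 > m) next
    fx <- xs - x0; fy <- ys - y0
    out[i, j] <- img[x0, y0] * (1 - fx) * (1 - fy) +
      img[x0 + 1, y0] * fx * (1 - fy) +
      img[x0, y0 + 1] * (1 - fx) * fy +
      img[x0 + 1, y0 + 1] * fx * fy
  }
  out
}

# Gaussian-profile bright ridge through the image centre at a given angle.
ridge_image <- function(n = 80, spacing = 0.75, sd_mm = 0.75, angle_deg = 0,
                        amp = 100) {
  th <- angle_deg * pi / 180
  cx <- (n + 1) / 2
  xs <- ((1:n) - cx) * spacing
  img <- matrix(0, n, n)
  for (j in 1:n) {
    # signed distance from pixel (i, j) to the ridge line
    d <- xs * -sin(th) + xs[j] * cos(th)
    img[, j] <- amp * exp(-d^2 / (2 * sd_mm^2))
  }
  img
}
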