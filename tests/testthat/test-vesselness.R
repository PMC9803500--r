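test_that("Hessian of simple analytic fields matches closed forms", {
  sp <- c(0.75, 0.75)
  n <- 64
  xs <- ((1:n) - 0.5) * sp[1]
  # constant image: zero response (moment-corrected kernels, fp residue only)
  h0 <- hessian_2d(matrix(5, n, n), 0.75, sp)
  expect_lt(max(abs(h0$Hxx), abs(h0$Hxy), abs(h0$Hyy)), 1e-12)
  # f = x^2 (mm): Hxx = 2 sigma^2 after gamma-normalisation, Hyy = Hxy = 0
  fx2 <- matrix(xs^2, n, n)
  for (sig in c(0.375, 0.75, 1.5)) {
    h <- hessian_2d(matrix(xs^2, n, n, byrow = FALSE), sig, sp)
    interior <- 20:44
    expect_equal(max(abs(h$Hxx[interior, interior] - 2 * sig^2)), 0,
                 tolerance = 1e-8)
    expect_equal(max(abs(h$Hyy[interior, interior])), 0, tolerance = 1e-8)
    expect_equal(max(abs(h$Hxy[interior, interior])), 0, tolerance = 1e-8)
  }
  # f = x * y: Hxy = sigma^2 in the interior
  fxy <- outer(xs, xs)
  h <- hessian_2d(fxy, 0.75, sp)
  expect_equal(max(abs(h$Hxy[20:44, 20:44] - 0.75^2)), 0, tolerance = 1e-8)
  expect_error(hessian_2d(fxy, -1, sp), "sigma")
  expect_warning(hessian_2d(fxy, 0.2, sp), "undersmoothed")
})

test_that("eigenvalues use the closed form with the |l1| <= |l2| ordering", {
  hf <- function(a, b, c) structure(list(Hxx = matrix(a), Hxy = matrix(b),
                                         Hyy = matrix(c)),
                                    class = "hessian_field")
  ev <- eigvals_2d(hf(2, 0, -5))
  expect_equal(c(ev$l1[1], ev$l2[1]), c(2, -5))
  # pure off-diagonal: eigenvalues {1, -1}, tie broken by l1 >= l2
  ev <- eigvals_2d(hf(0, 1, 0))
  expect_equal(c(ev$l1[1], ev$l2[1]), c(1, -1))
  # trace and determinant preserved on random fields
  set.seed(4)
  H <- hf(rnorm(1), rnorm(1), rnorm(1))
  M <- matrix(rnorm(3 * 500), 500)
  l1 <- l2 <- numeric(500)
  for (i in 1:500) {
    e <- eigvals_2d(hf(M[i, 1], M[i, 2], M[i, 3]))
    l1[i] <- e$l1[1]; l2[i] <- e$l2[1]
    expect_lte(abs(l1[i]), abs(l2[i]) + 1e-12)
  }
  expect_equal(l1 + l2, M[, 1] + M[, 3], tolerance = 1e-12)
  expect_equal(l1 * l2, M[, 1] * M[, 3] - M[, 2]^2, tolerance = 1e-10)
})

test_that("the vesselness measure follows the bright-tube formula", {
  # polarity: positive second eigenvalue is rejected outright
  expect_equal(vesselness_2d(0, 3, 0.5, 5), 0)
  expect_equal(vesselness_2d(0, 0, 0.5, 5), 0)
  # direct evaluation: l1 = 0, l2 = -10, beta = .5, c = 5 -> 1 - exp(-2)
  expect_equal(vesselness_2d(0, -10, 0.5, 5), 1 - exp(-2), tolerance = 1e-12)
  expect_error(vesselness_2d(0, -1, beta = 0, c = 1), "beta")
  # range on random eigenvalue fields
  set.seed(8)
  l2 <- rnorm(1e4, 0, 3); l1 <- l2 * runif(1e4, -1, 1)
  V <- vesselness_2d(l1, l2, 0.5, 2)
  expect_true(all(V >= 0 & V <= 1))
  expect_true(all(V[l2 >= 0] == 0))
})

test_that("multi-scale analysis selects a scale near half the ridge width", {
  sp <- c(0.75, 0.75)
  img <- ridge_image(80, 0.75, sd_mm = 0.75, angle_deg = 0)
  vm <- multiscale_vesselness(img, vesselness_params(), sp)
  centre <- which(abs(((1:80) - 40.5) * 0.75) <= 0.4)  # ridge spine columns
  spine <- vm$scale[20:60, centre]
  # gamma = 1 favours sigma near (ridge sd)..sqrt(2)*(ridge sd)
  expect_gte(mean(spine %in% c(0.75, 1.125)), 0.9)
  # flat slice gives identically zero response
  flat <- multiscale_vesselness(matrix(7, 40, 40), vesselness_params(), sp)
  expect_true(all(flat$V == 0))
  # strong separation between ridge and background response
  Vc <- max(vm$V[30:50, centre])
  Vbg <- max(vm$V[30:50, 5:15])
  expect_gte(Vc - Vbg, 0.5)
  expect_true(all(vm$V >= 0 & vm$V <= 1))
})

test_that("vesselness is rotation-equivariant", {
  sp <- c(0.75, 0.75)
  p <- vesselness_params(c = 50)  # fixed c so the two images are comparable
  # exact check under a 90-degree grid rotation
  img <- ridge_image(64, 0.75, 0.75, angle_deg = 0) +
    ridge_image(64, 0.75, 1.2, angle_deg = 0) * 0.3
  V0 <- multiscale_vesselness(img, p, sp)$V
  V90 <- multiscale_vesselness(t(img)[, 64:1], p, sp)$V
  expect_equal(max(abs(V90 - t(V0)[, 64:1])), 0, tolerance = 1e-10)
  # oblique rotation within interpolation tolerance
  V35 <- multiscale_vesselness(ridge_image(64, 0.75, 0.75, angle_deg = 35),
                               p, sp)$V
  Vrot <- rotate_bilinear(V0, 35)
  ok <- !is.na(Vrot)
  inner <- matrix(FALSE, 64, 64); inner[16:48, 16:48] <- TRUE
  expect_lte(mean(abs(V35 - Vrot)[ok & inner]), 0.05)
})

test_that("brightening a ridge never lowers its centre response", {
  sp <- c(0.75, 0.75)
  p <- vesselness_params(c = 100)  # fixed structureness weight
  amps <- c(20, 50, 100, 200, 400)
  centre_v <- vapply(amps, function(a) {
    vm <- multiscale_vesselness(ridge_image(48, 0.75, 0.75, amp = a), p, sp)
    vm$V[24, 24]
  }, numeric(1))
  expect_true(all(diff(centre_v) >= -1e-12))
})
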