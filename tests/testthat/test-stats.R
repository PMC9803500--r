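# --- Mann-Whitney -----------------------------------------------------------

test_that("Mann-Whitney matches hand-derived exact cases", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.1)          # 2 * (1 / C(6,3)) * 1 of 10 orderings
  expect_equal(t1$method, "exact")
  # identical tied samples: U = n^2/2, p capped at 1
  t2 <- mann_whitney_u(c(5, 5, 7, 7), c(5, 5, 7, 7))
  expect_equal(t2$U, 8)
  expect_equal(t2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("exact p agrees with full enumeration for all small sizes", {
  set.seed(11)
  for (n1 in 2:5) for (n2 in n1:min(5, 12 - n1)) {
    x <- sample(100, n1); y <- sample(200:300, n2)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, enum_mw_p(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
  # a few random tie-free draws at larger exact sizes
  for (rep in 1:20) {
    x <- rnorm(7); y <- rnorm(8)
    expect_equal(mann_whitney_u(x, y)$p, enum_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("the tie-corrected approximation tracks the exact distribution", {
  # exact bound computed by enumeration over the whole n1 = n2 = 8 support
  exact_p <- function(U) min(1, 2 * pwilcox(U, 8, 8))
  approx_p <- function(U) {
    sig <- sqrt(8 * 8 * 17 / 12)
    min(1, 2 * pnorm((U - 32 + 0.5) / sig))
  }
  devs <- vapply(0:32, function(U) abs(exact_p(U) - approx_p(U)), numeric(1))
  expect_lte(max(devs), 0.012)
  # and the package's approximation path equals wilcox.test's corrected one
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(25); y <- rnorm(30)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$U, min(ref$statistic, 25 * 30 - ref$statistic),
                 ignore_attr = TRUE)
  }
  # ties engage the corrected variance
  xt <- rep(1:5, 6); yt <- rep(2:6, 5)
  expect_equal(mann_whitney_u(xt, yt)$p,
               suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                            correct = TRUE))$p.value,
               tolerance = 1e-10)
})

test_that("Bonferroni threshold renders as the published .017", {
  thr <- bonferroni_threshold(0.05, 3)
  expect_equal(as.numeric(thr), 0.05 / 3)
  expect_equal(attr(thr, "rendered"), ".017")
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 10)), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("pairwise comparisons flag at the adjusted level", {
  coh <- generate_cohort(cohort_config(seed = 14))
  pc <- pairwise_group_comparisons(coh, "vrs_count")
  expect_equal(nrow(pc), 3)
  expect_equal(attr(attr(pc, "threshold"), "rendered"), ".017")
  expect_error(pairwise_group_comparisons(coh, "nope"), "no column")
  # a metric identical across groups is never flagged
  coh$flatmetric <- 1
  expect_false(any(pairwise_group_comparisons(coh, "flatmetric")$significant))
  # tiny groups go through the exact path and match enumeration
  tiny <- data.frame(group = rep(c("a", "b"), each = 3),
                     m = c(10, 11, 14, 20, 25, 21))
  pt <- pairwise_group_comparisons(tiny, "m")
  expect_equal(pt$p, enum_mw_p(c(10, 11, 14), c(20, 25, 21)))
})

# --- Pearson ----------------------------------------------------------------

test_that("Pearson correlation matches closed forms and cor.test", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_equal(pearson_r(c(1, 2, 3), -c(1, 3, 2))$r, -0.5)  # sign contract
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  set.seed(5)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  got <- pearson_r(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # affine invariance with positive slope
  expect_equal(pearson_r(3 * x + 7, y / 2 - 1)$r, got$r, tolerance = 1e-12)
})

test_that("the correlation panel reproduces the published sign pattern", {
  big <- generate_cohort(cohort_config(n = c("SFS>5M" = 3000), seed = 6))
  panel <- correlation_panel(big, "SFS>5M")
  expect_equal(nrow(panel), 4)
  expect_true(all(sign(panel$r) == c(1, 1, -1, -1)))
  expect_equal(panel$r[1], 0.778, tolerance = 0.05)  # duration ~ count
  expect_error(correlation_panel(big, "control"), "not applicable")
})

# --- LOESS and cutoff -------------------------------------------------------

test_that("local linear smoothing reproduces polynomials exactly", {
  set.seed(2)
  x <- sort(runif(60, 0, 10))
  fit_const <- loess_fit(x, rep(3, 60), span = 0.5)
  expect_equal(max(abs(fit_const$fitted - 3)), 0, tolerance = 1e-10)
  y <- 2 * x - 5
  for (span in c(0.3, 0.5, 1)) {
    fit <- loess_fit(x, y, span = span)
    expect_equal(max(abs(fit$fitted - (2 * fit$grid - 5))), 0,
                 tolerance = 1e-8)
  }
  expect_error(loess_fit(x[1:4], y[1:4]), "at least 5")
  expect_error(loess_fit(x, y, span = 0.02), "3 neighbours")
})

test_that("grid values equal a directly computed tricube WLS fit", {
  set.seed(9)
  x <- runif(50, 0, 10)
  y <- sin(x) + rnorm(50, 0, 0.1)
  fit <- loess_fit(x, y, span = 0.4)
  for (i in c(20, 100, 180))
    expect_equal(fit$fitted[i], wls_at_point(x, y, fit$grid[i], 0.4),
                 tolerance = 1e-9)
  # and tracks stats::loess with an exact (direct) surface closely
  ref <- loess(y ~ x, span = 0.4, degree = 1,
               control = loess.control(surface = "direct"))
  expect_lt(mean(abs(fit$fitted - predict(ref, fit$grid))), 0.02)
})

test_that("degenerate local designs fall back to a local mean with warning", {
  x <- c(rep(1, 10), 5, 6, 7)
  y <- c(rnorm(10), 3, 3, 3)
  expect_warning(fit <- loess_fit(x, y, span = 0.6), "degenerate")
  expect_true(all(is.finite(fit$fitted)))
})

test_that("a slope break is located by maximum curvature", {
  recover <- function(bp) {
    cuts <- vapply(1:50, function(s) {
      set.seed(s)
      x <- runif(70, 0.5, 12)
      y <- 450 + 80 * pmax(x - bp, 0) + rnorm(70, 0, 20)
      detect_cutoff(loess_fit(x, y, span = 0.5))$cutoff
    }, numeric(1))
    median(cuts)
  }
  for (bp in c(4, 5, 6, 7, 8))
    expect_lte(abs(recover(bp) - bp), 0.5)
  # near the short left arm the corner smears into the boundary
  expect_lte(abs(recover(3) - 3), 0.75)
})

test_that("flat and linear curves admit no cutoff", {
  set.seed(1)
  x <- sort(runif(40, 0, 10))
  expect_error(detect_cutoff(loess_fit(x, 5 + 2 * x, span = 0.5)),
               "no cutoff")
  expect_error(detect_cutoff(loess_fit(x, rep(2, 40), span = 0.5)),
               "no cutoff")
  # profile bookkeeping on a detectable curve
  y <- pmax(x - 5, 0) * 10 + rnorm(40)
  cut <- detect_cutoff(loess_fit(x, y, span = 0.5))
  expect_true(cut$cutoff > min(x) && cut$cutoff < max(x))
  expect_equal(cut$criterion, "max_abs_second_difference")
  expect_equal(nrow(cut$profile), 198)
})

# --- summaries and report ---------------------------------------------------

test_that("group summaries report mean +- SD and male counts", {
  coh <- generate_cohort(cohort_config(seed = 3))
  s <- summarize_groups(coh)
  gt_count <- s[s$group == "SFS>5M" & s$variable == "vrs_count", ]
  expect_equal(gt_count$mean, mean(coh$vrs_count[coh$group == "SFS>5M"]))
  expect_match(gt_count$formatted, "±")
  male <- s[s$variable == "male" & s$group == "control", ]
  expect_equal(male$mean, mean(coh$sex[coh$group == "control"] == "M"))
  # a single-subject group is flagged with SD 0
  single <- data.frame(group = "g", sex = "M", v = 3)
  ss <- summarize_groups(single)
  expect_true(all(ss$single_subject))
  expect_equal(ss$sd[ss$variable == "v"], 0)
  expect_error(summarize_groups(data.frame()), "empty")
})

test_that("the cohort report writes every table", {
  coh <- generate_cohort(cohort_config(seed = 8))
  out <- withr::local_tempdir()
  rep <- cohort_report(coh, out_dir = out)
  for (f in c("table1.csv", "table2.csv", "correlations.csv", "cutoff.csv",
              "report.txt"))
    expect_true(file.exists(file.path(out, f)))
  expect_equal(attr(rep$adjusted_alpha, "rendered"), ".017")
  expect_equal(nrow(rep$correlations), 8)  # 4 pairs x 2 seizure groups
  expect_true(any(grepl("chi-square", rep$table1_tests$metric)))
  t2 <- utils::read.csv(file.path(out, "table2.csv"))
  expect_true(all(c("metric", "U", "p_rendered", "significant") %in% names(t2)))
})
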