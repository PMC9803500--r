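# --- Mann-Whitney -----------------------------------------------------------

#' Two-sided Mann-Whitney U test
#'
#' U counts pairwise wins of x over y (ties half-counted) and is reported
#' as the smaller of the two sides, `min(U, n1*n2 - U)`. The p-value is
#' exact (from the full null distribution of U) when `n1 + n2 <= 16` and
#' the pooled sample is tie-free, otherwise a normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used. With
#' n1 = n2 = 8 the approximation stays within 0.011 of the exact value
#' over the whole support.
#'
#' @param x,y numeric samples (non-empty; NAs dropped).
#' @return an `mw_test` list: `U`, `p`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_user("mann_whitney_u: empty sample")
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 16 && !ties) {
    p <- min(1, 2 * pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    n <- n1 + n2
    tt <- table(c(x, y))
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z))
    }
    method <- "normal_tie_corrected"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p %s [%s]\n",
              x$U, x$n1, x$n2, format_pvalue(x$p), x$method))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise level divided by the number of comparisons; for the three
#' pairwise group comparisons at alpha = 0.05 this renders as .017.
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return adjusted threshold, with attribute `"rendered"` giving the
#'   3-decimal report form (e.g. `".017"`).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_user("bonferroni_threshold: alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop_user("bonferroni_threshold: m must be >= 1")
  thr <- alpha / m
  attr(thr, "rendered") <- sub("^0", "", sprintf("%.3f", thr))
  thr
}

# Report rendering of a p-value: 3 decimals with a "<.001" floor.
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' All pairwise Mann-Whitney comparisons of one metric across groups
#'
#' Runs the two-sided test for every group pair and flags significance at
#' the Bonferroni threshold with m = the number of pairwise comparisons
#' (3 for the three study groups, giving the .017 level; the number of
#' metrics is deliberately not folded in).
#'
#' @param cohort cohort `data.frame` with a `group` column.
#' @param metric metric column name (e.g. `"vrs_count"`).
#' @param alpha family-wise level (default 0.05).
#' @return a `vrs_comparisons` data.frame: groups, n, U, p, rendering,
#'   significance flag; the threshold is attached as an attribute.
#' @export
pairwise_group_comparisons <- function(cohort, metric, alpha = 0.05) {
  if (!metric %in% names(cohort))
    stop_user("pairwise_group_comparisons: no column '", metric, "'")
  groups <- levels(factor(cohort$group))
  if (length(groups) < 2)
    stop_user("pairwise_group_comparisons: need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  thr <- bonferroni_threshold(alpha, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    t <- mann_whitney_u(cohort[[metric]][cohort$group == g1],
                        cohort[[metric]][cohort$group == g2])
    data.frame(metric = metric, group1 = g1, group2 = g2,
               n1 = t$n1, n2 = t$n2, U = t$U, p = t$p,
               p_rendered = format_pvalue(t$p),
               significant = t$p < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  class(out) <- c("vrs_comparisons", class(out))
  out
}

#' @export
print.vrs_comparisons <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Pairwise Mann-Whitney comparisons (adjusted alpha %s):\n",
              attr(thr, "rendered")))
  print.data.frame(x)
  invisible(x)
}

# --- Pearson ----------------------------------------------------------------

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y numeric vectors (pairwise-complete, n >= 3, both with
#'   nonzero variance).
#' @return a `cor_result` list: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_user("pearson_r: need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop_user("pearson_r: zero variance")
  r <- as.numeric(cor(x, y))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), two-sided p %s\n",
              x$r, x$n, format_pvalue(x$p)))
  invisible(x)
}

#' Correlation panel of VRs metrics against duration and course
#'
#' The four correlations the study reports per seizure group: seizure
#' duration and course-after-onset against perivascular-space count and
#' volume.
#'
#' @param cohort cohort `data.frame`.
#' @param group which seizure group to use (must have duration/course).
#' @return data.frame with columns `var1`, `var2`, `r`, `p`,
#'   `p_rendered`, `n`.
#' @export
correlation_panel <- function(cohort, group) {
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (!nrow(sub)) stop_user("correlation_panel: no subjects in group '", group, "'")
  if (all(is.na(sub$duration_min)))
    stop_user("correlation_panel: not applicable to this group ",
              "(no seizure duration recorded)")
  pairs <- list(c("duration_min", "vrs_count"), c("duration_min", "vrs_volume_mm3"),
                c("course_days", "vrs_count"), c("course_days", "vrs_volume_mm3"))
  rows <- lapply(pairs, function(p) {
    ct <- pearson_r(sub[[p[1]]], sub[[p[2]]])
    data.frame(group = group, var1 = p[1], var2 = p[2], r = ct$r, p = ct$p,
               p_rendered = format_pvalue(ct$p), n = ct$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- LOESS and cutoff detection ---------------------------------------------

#' Local linear regression with tricube weights (LOESS)
#'
#' At each of `grid_n` equispaced evaluation points over the range of x,
#' fits a weighted linear (or constant) regression over the
#' `ceiling(span * n)` nearest x-neighbours with tricube weights
#' `w = (1 - (d / d_max)^3)^3`. A degenerate local design (all window x
#' equal) falls back to the local weighted mean with a warning.
#'
#' @param x,y numeric data (n >= 5, NAs dropped pairwise).
#' @param span fraction of points per local fit, in (0, 1]; must give at
#'   least 3 neighbours.
#' @param degree local polynomial degree, 0 or 1 (default 1).
#' @param grid_n number of evaluation points (default 200).
#' @return a `vrs_loess` list: `x`, `y`, `span`, `degree`, `grid`,
#'   `fitted`.
#' @export
loess_fit <- function(x, y, span = 0.5, degree = 1, grid_n = 200) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop_user("loess_fit: need at least 5 points")
  if (span <= 0 || span > 1) stop_user("loess_fit: span must lie in (0, 1]")
  q <- ceiling(span * n)
  if (q < 3) stop_user("loess_fit: span gives fewer than 3 neighbours")
  if (!degree %in% c(0, 1)) stop_user("loess_fit: degree must be 0 or 1")
  grid <- seq(min(x), max(x), length.out = grid_n)
  degenerate <- FALSE
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    idx <- order(d)[seq_len(q)]
    dmax <- d[idx[q]]
    if (dmax == 0) {
      degenerate <<- TRUE
      return(mean(y[idx]))
    }
    w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
    # an equidistant window puts every point at d_max (weight 0); fall
    # back to equal weights rather than a 0/0 mean
    if (sum(w) == 0) w <- rep(1, length(w))
    if (degree == 0 || length(unique(x[idx])) < 2) {
      if (degree == 1) degenerate <<- TRUE
      return(weighted.mean(y[idx], w))
    }
    X <- cbind(1, x[idx] - x0)
    b <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * y[idx])),
                  error = function(e) NULL)
    if (is.null(b)) {
      degenerate <<- TRUE
      weighted.mean(y[idx], w)
    } else b[1]
  }, numeric(1))
  if (degenerate)
    warning("loess_fit: degenerate local design; fell back to local mean",
            call. = FALSE)
  structure(list(x = x, y = y, span = span, degree = degree,
                 grid = grid, fitted = fitted),
            class = "vrs_loess")
}

#' @export
print.vrs_loess <- function(x, ...) {
  cat(sprintf("<vrs_loess> n = %d, span = %g, degree = %d, %d grid points\n",
              length(x$x), x$span, x$degree, length(x$grid)))
  invisible(x)
}

#' @export
plot.vrs_loess <- function(x, ...) {
  plot(x$x, x$y, xlab = "x", ylab = "y", ...)
  lines(x$grid, x$fitted, lwd = 2)
  invisible(x)
}

#' Detect a cutoff as the point of maximum curvature of a LOESS curve
#'
#' The cutoff is the interior grid point maximising the absolute second
#' difference of the fitted curve, with the outer 5% of the grid
#' excluded; the criterion profile is returned for plotting. A flat
#' curve (criterion below `tol` times the data scale) raises an error.
#'
#' @param fit a `vrs_loess` from [loess_fit()].
#' @param exclude_frac fraction of the grid excluded at each end.
#' @param tol flatness tolerance relative to the data scale.
#' @return a `vrs_cutoff` list: `cutoff` (same units as x), `criterion`,
#'   `profile` (grid point, criterion value), `span`.
#' @export
detect_cutoff <- function(fit, exclude_frac = 0.05, tol = 1e-9) {
  stopifnot(inherits(fit, "vrs_loess"))
  g <- fit$grid
  f <- fit$fitted
  m <- length(g)
  d2 <- abs(diff(f, differences = 2))
  centers <- 2:(m - 1)
  lo <- floor(exclude_frac * m)
  hi <- ceiling((1 - exclude_frac) * m)
  keep <- centers > lo & centers <= hi
  scale <- diff(range(fit$y))
  if (max(d2[keep]) < tol * max(scale, 1))
    stop_user("detect_cutoff: no cutoff detectable (flat curve)")
  best <- centers[keep][which.max(d2[keep])]
  structure(list(cutoff = g[best],
                 criterion = "max_abs_second_difference",
                 profile = data.frame(grid = g[centers], value = d2,
                                      excluded = !keep),
                 span = fit$span),
            class = "vrs_cutoff")
}

#' @export
print.vrs_cutoff <- function(x, ...) {
  cat(sprintf("LOESS cutoff: %.3f (criterion %s, span %g)\n",
              x$cutoff, x$criterion, x$span))
  invisible(x)
}

# --- group summaries and report ---------------------------------------------

#' Per-group mean +- SD summary of a cohort
#'
#' Mean and SD for every numeric subject column per group (SD reported as
#' 0 with a flag for single-subject groups) plus male counts and
#' percentages, in a per-group demographics-and-metrics table layout.
#'
#' @param cohort cohort `data.frame`.
#' @return data.frame with `group`, `variable`, `n`, `mean`, `sd`,
#'   `formatted` ("mean +- sd" or "k (p%)"), `single_subject` flag.
#' @export
summarize_groups <- function(cohort) {
  if (!nrow(cohort)) stop_user("summarize_groups: empty cohort")
  numcols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  groups <- levels(factor(cohort$group))
  rows <- list()
  for (g in groups) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    for (v in numcols) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      n <- length(vals)
      if (n == 0) next
      m <- mean(vals)
      s <- if (n > 1) sd(vals) else 0
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, n = n, mean = m, sd = s,
        formatted = sprintf("%.2f ± %.2f", m, s),
        single_subject = n == 1, stringsAsFactors = FALSE)
    }
    if ("sex" %in% names(sub)) {
      k <- sum(sub$sex == "M")
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = "male", n = nrow(sub), mean = k / nrow(sub),
        sd = NA_real_,
        formatted = sprintf("%d (%.2f%%)", k, 100 * k / nrow(sub)),
        single_subject = nrow(sub) == 1, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full statistics report of a cohort
#'
#' Reproduces the analysis workflow on a cohort table: demographic
#' summaries with pairwise Mann-Whitney p-values (chi-square for sex),
#' the metric comparisons at the Bonferroni-adjusted level, the
#' correlation panels per seizure group, and LOESS cutoff detection on
#' the pooled seizure groups. Writes `table1.csv`, `table2.csv`,
#' `correlations.csv`, `cutoff.csv` and a plain-text `report.txt` when
#' `out_dir` is given.
#'
#' @param cohort cohort `data.frame`.
#' @param out_dir optional output directory.
#' @param span,cutoff_metric LOESS span and which metric is smoothed
#'   against duration for the cutoff (defaults 0.5, `"vrs_count"`).
#' @param alpha family-wise level.
#' @return list with `table1`, `table2`, `correlations`, `cutoff`
#'   (cutoff object or NULL), `adjusted_alpha`.
#' @export
cohort_report <- function(cohort, out_dir = NULL, span = 0.5,
                          cutoff_metric = "vrs_count", alpha = 0.05) {
  summary <- summarize_groups(cohort)
  demo <- c("age_months", "ga_weeks", "course_days", "duration_min", "hc_cm")
  demo <- intersect(demo, names(cohort))
  t1_tests <- do.call(rbind, lapply(demo, function(v) {
    sub <- cohort[!is.na(cohort[[v]]), ]
    if (length(unique(sub$group)) < 2) return(NULL)
    pairwise_group_comparisons(sub, v, alpha)
  }))
  if ("sex" %in% names(cohort) && length(unique(cohort$group)) >= 2) {
    sx <- suppressWarnings(chisq.test(table(cohort$group, cohort$sex)))
    sex_row <- data.frame(metric = "sex (chi-square)", group1 = "all",
                          group2 = "all", n1 = nrow(cohort), n2 = NA,
                          U = NA, p = sx$p.value,
                          p_rendered = format_pvalue(sx$p.value),
                          significant = NA, stringsAsFactors = FALSE)
    t1_tests <- rbind(t1_tests, sex_row)
  }
  metrics <- intersect(c("vrs_count", "vrs_volume_mm3", "wm_volume_mm3",
                         "brain_volume_mm3", "hc_cm"), names(cohort))
  t2_tests <- do.call(rbind, lapply(metrics, function(v)
    pairwise_group_comparisons(cohort, v, alpha)))
  sfs <- cohort[!is.na(cohort$duration_min), , drop = FALSE]
  cors <- do.call(rbind, lapply(unique(as.character(sfs$group)), function(g)
    correlation_panel(cohort, g)))
  cut <- NULL
  if (nrow(sfs) >= 5) {
    fit <- loess_fit(sfs$duration_min, sfs[[cutoff_metric]], span = span)
    cut <- tryCatch(detect_cutoff(fit), vrsquant_user_error = function(e) NULL)
  }
  thr <- bonferroni_threshold(alpha, 3)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(merge_summary_tests(summary, t1_tests),
                     file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(t2_tests, file.path(out_dir, "table2.csv"), row.names = FALSE)
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    cut_df <- data.frame(
      cutoff_min = if (is.null(cut)) NA_real_ else cut$cutoff,
      criterion = if (is.null(cut)) NA_character_ else cut$criterion,
      span = span, metric = cutoff_metric)
    utils::write.csv(cut_df, file.path(out_dir, "cutoff.csv"), row.names = FALSE)
    writeLines(render_report(summary, t1_tests, t2_tests, cors, cut, thr),
               file.path(out_dir, "report.txt"))
  }
  list(table1 = summary, table1_tests = t1_tests, table2 = t2_tests,
       correlations = cors, cutoff = cut, adjusted_alpha = thr)
}

# Stack the per-group summary block and the pairwise-test block into one
# table-1-style CSV layout.
merge_summary_tests <- function(summary, tests) {
  top <- data.frame(kind = "summary", group = summary$group,
                    variable = summary$variable, n = summary$n,
                    value = summary$formatted, group1 = NA, group2 = NA,
                    p = NA, stringsAsFactors = FALSE)
  if (is.null(tests)) return(top)
  bottom <- data.frame(kind = "test", group = NA, variable = tests$metric,
                       n = NA, value = NA, group1 = tests$group1,
                       group2 = tests$group2, p = tests$p_rendered,
                       stringsAsFactors = FALSE)
  rbind(top, bottom)
}

render_report <- function(summary, t1_tests, t2_tests, cors, cut, thr) {
  c(sprintf("Cohort statistics report (adjusted alpha %s, Bonferroni m = 3)",
            attr(thr, "rendered")),
    "",
    "Group summaries (mean ± SD):",
    sprintf("  %-10s %-18s %s", summary$group, summary$variable,
            summary$formatted),
    "",
    "Pairwise metric comparisons (Mann-Whitney U, two-sided):",
    sprintf("  %-16s %s vs %s: U = %s, p = %s%s", t2_tests$metric,
            t2_tests$group1, t2_tests$group2, format(t2_tests$U),
            t2_tests$p_rendered,
            ifelse(!is.na(t2_tests$significant) & t2_tests$significant,
                   " *", "")),
    "",
    "Correlations with duration and course:",
    sprintf("  %-8s %s ~ %s: r = %.3f, p = %s", cors$group, cors$var1,
            cors$var2, cors$r, cors$p_rendered),
    "",
    if (is.null(cut)) "LOESS cutoff: not detectable" else
      sprintf("LOESS cutoff on seizure duration: %.2f min (criterion %s, span %g)",
              cut$cutoff, cut$criterion, cut$span))
}
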