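# --- truncated-normal machinery ---------------------------------------------

# Mean and SD of N(mu, sigma^2) truncated to (a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) return(c(NaN, NaN))
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  if (is.na(Z) || Z <= 0) return(c(NaN, NaN))
  ad <- if (is.finite(al)) al * dnorm(al) else 0
  bd <- if (is.finite(be)) be * dnorm(be) else 0
  dz <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dz / Z
  v <- sigma^2 * (1 + (ad - bd) / Z - (dz / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that N(mu, sigma^2) truncated to (a, b] has the
# requested mean and SD. Identity when the bounds are effectively inactive.
# The mean is always matched exactly (1-D root in mu, monotone); the SD is
# matched as closely as the truncated-normal family allows -- on a doubly
# bounded interval some printed (mean, SD) pairs are not exactly
# realisable and the nearest SD is used.
match_truncnorm <- function(mean, sd, a = -Inf, b = Inf) {
  if (!is.finite(a) && !is.finite(b)) return(c(mean, sd))
  got <- truncnorm_moments(mean, sd, a, b)
  if (all(is.finite(got)) && max(abs(got - c(mean, sd))) < 1e-6 * max(sd, 1))
    return(c(mean, sd))
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), a, b)
    if (any(!is.finite(mo))) return(1e12)
    sum(((mo - c(mean, sd)) / c(max(abs(mean), 1), sd))^2)
  }
  starts <- list(c(mean, log(sd)), c(mean, log(2 * sd)),
                 c(mean - sd, log(3 * sd)), c(mean, log(sd / 2)))
  fit <- NULL
  for (s in starts) {
    f <- optim(s, obj, control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  sigma <- exp(fit$par[2])
  # re-solve mu so the truncated mean is exact at this sigma
  mean_err <- function(mu) {
    m <- truncnorm_moments(mu, sigma, a, b)[1]
    # far outside the window the truncated mean saturates at the bound
    if (!is.finite(m)) m <- if (mu < (a + min(b, a + 6 * sigma)) / 2)
      a else min(b, mu)
    m - mean
  }
  lo <- fit$par[1] - 10 * sigma
  hi <- fit$par[1] + 10 * sigma
  mu <- tryCatch(uniroot(mean_err, c(lo, hi), tol = 1e-10)$root,
                 error = function(e)
                   stop_user("match_truncnorm: cannot match mean ", mean,
                             " on (", a, ", ", b, "]"))
  c(mu, sigma)
}

# Quantile function of the truncated normal, for copula margins.
qtruncnorm <- function(u, mu, sigma, a = -Inf, b = Inf) {
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  qnorm(pa + u * (pb - pa), mu, sigma)
}

# --- correlation-matrix completion ------------------------------------------

# Project a symmetric matrix to the nearest correlation matrix by
# alternating eigenvalue clipping and unit-diagonal rescaling.
nearest_psd_correlation <- function(R, eps = 1e-8, maxit = 200) {
  X <- R
  for (i in seq_len(maxit)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= eps && max(abs(diag(X) - 1)) < 1e-12) break
    vals <- pmax(e$values, eps)
    X <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(X))
    X <- X / tcrossprod(d)
    X <- (X + t(X)) / 2
    diag(X) <- 1
  }
  X
}

# Assemble the (duration, course, count, volume) correlation matrix from the
# four published pairs plus the two completion defaults; repair to PSD only
# if needed and refuse when repair moves a specified entry too far.
build_group_correlation <- function(target, dur_course_cor, count_vol_cor,
                                    max_shift = 0.1) {
  R <- diag(4)
  dimnames(R) <- list(c("duration", "course", "count", "volume"),
                      c("duration", "course", "count", "volume"))
  R["duration", "course"] <- R["course", "duration"] <- dur_course_cor
  R["count", "volume"] <- R["volume", "count"] <- count_vol_cor
  R["duration", "count"] <- R["count", "duration"] <- target[["duration_count"]]
  R["duration", "volume"] <- R["volume", "duration"] <- target[["duration_volume"]]
  R["course", "count"] <- R["count", "course"] <- target[["course_count"]]
  R["course", "volume"] <- R["volume", "course"] <- target[["course_volume"]]
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= 1e-8)
    return(R)
  Rp <- nearest_psd_correlation(R)
  shift <- abs(Rp - R)
  specified <- matrix(FALSE, 4, 4, dimnames = dimnames(R))
  specified["duration", c("count", "volume")] <- TRUE
  specified["course", c("count", "volume")] <- TRUE
  specified <- specified | t(specified)
  worst <- max(shift[specified])
  if (worst > max_shift) {
    at <- which(shift == worst & specified, arr.ind = TRUE)[1, ]
    stop_user("infeasible correlation matrix: PSD repair moves (",
              rownames(R)[at[1]], ", ", colnames(R)[at[2]], ") by ",
              round(worst, 3), " (> ", max_shift, ")")
  }
  Rp
}

# --- cohort configuration ----------------------------------------------------

margin <- function(mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, lo < hi)
  list(mean = mean, sd = sd, lo = lo, hi = hi)
}

default_group_params <- function() {
  list(
    "SFS>5M" = list(
      n = 30, male_prop = 0.70,
      age = margin(28.07, 15.12, 6, 60),
      ga = margin(39.73, 1.07, 37, 45),
      duration = margin(7.16, 1.23, 5, 15),
      course = margin(9.60, 1.32, 0, 15),
      hc = margin(70.82, 10.18, 0, Inf),
      count = margin(642.70, 100.62, 0, Inf),
      volume = margin(8514.63, 835.33, 0, Inf),
      wm = margin(300670, 155800, 1, Inf),
      brain = margin(880010, 156410, 1, Inf),
      correlations = c(duration_count = 0.778, duration_volume = 0.702,
                       course_count = -0.812, course_volume = -0.807)),
    "SFS<=5M" = list(
      n = 40, male_prop = 0.7333,
      age = margin(26.89, 15.92, 6, 60),
      ga = margin(39.80, 0.94, 37, 45),
      duration = margin(2.70, 0.45, 0.5, 5),
      course = margin(9.40, 1.43, 0, 15),
      hc = margin(71.64, 11.35, 0, Inf),
      count = margin(445.80, 66.10, 0, Inf),
      volume = margin(6390.43, 692.74, 0, Inf),
      wm = margin(321420, 70520, 1, Inf),
      brain = margin(894290, 81100, 1, Inf),
      correlations = c(duration_count = 0.563, duration_volume = 0.568,
                       course_count = -0.628, course_volume = -0.562)),
    "control" = list(
      n = 35, male_prop = 0.7429,
      age = margin(27.83, 17.04, 6, 60),
      ga = margin(39.41, 1.14, 37, 45),
      duration = NULL, course = NULL,
      hc = margin(71.26, 10.04, 0, Inf),
      count = margin(430.77, 182.55, 0, Inf),
      volume = margin(6048.37, 111.50, 0, Inf),
      wm = margin(308510, 134450, 1, Inf),
      brain = margin(916730, 181910, 1, Inf),
      correlations = NULL))
}

#' Cohort-generator configuration
#'
#' Defaults reproduce the published study population: three groups
#' (seizures longer than 5 minutes, 5 minutes or shorter, and seizure-free
#' controls of n = 30 / 40 / 35), each with the published mean +- SD for
#' age, gestational age, head circumference, seizure duration (minutes,
#' truncated to its group's side of the 5-minute boundary within the
#' 0.5--15 minute febrile-seizure range), course from seizure onset to
#' scan (days, truncated to (0, 15]), perivascular-space count and volume,
#' white-matter and brain volume, and the published within-group
#' correlations of (duration, course) with (count, volume). The two
#' correlation pairs the study does not report are completed with
#' `dur_course_cor` and `count_vol_cor`.
#'
#' @param groups per-group parameter list; see the package source's
#'   `default_group_params()` for the full shape. Each group carries `n`,
#'   `male_prop`, a `margin(mean, sd, lo, hi)` per numeric column and a
#'   4-vector of target correlations (or `NULL` for controls).
#' @param n optional named vector overriding the per-group sample sizes.
#' @param dur_course_cor completion value for the unreported
#'   duration--course correlation.
#' @param count_vol_cor completion value for the unreported count--volume
#'   correlation.
#' @param seed integer root seed.
#' @return a validated `cohort_config`.
#' @export
cohort_config <- function(groups = default_group_params(), n = NULL,
                          dur_course_cor = -0.5, count_vol_cor = 0.85,
                          seed = 1) {
  if (!is.null(n)) {
    for (g in names(n)) {
      if (!g %in% names(groups)) stop_user("cohort_config: unknown group '", g, "'")
      groups[[g]]$n <- as.integer(n[[g]])
    }
  }
  for (g in names(groups)) {
    if (groups[[g]]$n < 2) stop_user("cohort_config: group '", g, "' needs n >= 2")
    # completion must succeed at configuration time
    if (!is.null(groups[[g]]$correlations))
      build_group_correlation(groups[[g]]$correlations, dur_course_cor, count_vol_cor)
  }
  structure(list(groups = groups, dur_course_cor = dur_course_cor,
                 count_vol_cor = count_vol_cor, seed = seed),
            class = "cohort_config")
}

# --- generation --------------------------------------------------------------

# Draw n values whose truncated-normal law has exactly the configured
# moments, from supplied uniforms (copula) or fresh ones.
draw_margin <- function(m, u) {
  p <- match_truncnorm(m$mean, m$sd, m$lo, m$hi)
  qtruncnorm(u, p[1], p[2], m$lo, m$hi)
}

#' Generate a synthetic subject cohort
#'
#' Within each seizure group the four linked variables (seizure duration,
#' course after onset, perivascular-space count, perivascular-space
#' volume) are drawn through a Gaussian copula: a latent 4-variate normal
#' with the group's completed correlation matrix is mapped through
#' truncated-normal margins whose parent parameters are moment-matched so
#' the truncated law has exactly the configured mean and SD. Margins are
#' therefore exact and the latent correlations survive the mild
#' truncation essentially unattenuated. Controls have no duration or
#' course (NA). Remaining covariates are independent truncated normals;
#' sex is Bernoulli with the group's male proportion.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with columns `subject_id, group, age_months,
#'   sex, ga_weeks, duration_min, course_days, hc_cm, vrs_count,
#'   vrs_volume_mm3, wm_volume_mm3, brain_volume_mm3`; the config is
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' table(coh$group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- list()
  for (g in names(config$groups)) {
    gp <- config$groups[[g]]
    n <- gp$n
    rows[[g]] <- with_seed(derive_seed(config$seed, paste0("cohort/", g)), {
      if (!is.null(gp$correlations)) {
        R <- build_group_correlation(gp$correlations, config$dur_course_cor,
                                     config$count_vol_cor)
        Z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = R)
        U <- pnorm(Z)
        duration <- draw_margin(gp$duration, U[, 1])
        course <- draw_margin(gp$course, U[, 2])
        count <- draw_margin(gp$count, U[, 3])
        volume <- draw_margin(gp$volume, U[, 4])
      } else {
        Z <- MASS::mvrnorm(n, mu = c(0, 0),
                           Sigma = matrix(c(1, config$count_vol_cor,
                                            config$count_vol_cor, 1), 2))
        U <- pnorm(Z)
        duration <- rep(NA_real_, n)
        course <- rep(NA_real_, n)
        count <- draw_margin(gp$count, U[, 1])
        volume <- draw_margin(gp$volume, U[, 2])
      }
      data.frame(
        group = g,
        age_months = draw_margin(gp$age, runif(n)),
        sex = ifelse(runif(n) < gp$male_prop, "M", "F"),
        ga_weeks = draw_margin(gp$ga, runif(n)),
        duration_min = duration,
        course_days = course,
        hc_cm = draw_margin(gp$hc, runif(n)),
        vrs_count = round(count),
        vrs_volume_mm3 = volume,
        wm_volume_mm3 = draw_margin(gp$wm, runif(n)),
        brain_volume_mm3 = draw_margin(gp$brain, runif(n)),
        stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out$group <- factor(out$group, levels = names(config$groups))
  attr(out, "config") <- config
  out
}
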