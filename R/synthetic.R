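# Synthetic subject generator calibrated to the published group summaries.
#
# Metric level: per (sex, age, type) group, (BMI, 7 metrics) are drawn from
# a multivariate normal with the printed group means/SDs. The within-type
# BMI-metric correlation rho_w is calibrated by moment matching so that the
# POOLED (across the three types of a stratum) sample correlation converges
# to the printed pooled value: the pooled covariance splits into a
# between-group part driven by the group mean differences plus a
# within-group part rho_w * sum_g w_g sd_Bg sd_Mg.

pooled_moments <- function(n, mean, sd) {
  w <- n / sum(n)
  grand <- sum(w * mean)
  between <- sum(w * (mean - grand)^2)
  within <- sum(w * sd^2)
  list(w = w, grand = grand, between_var = between, within_var = within,
       total_var = between + within)
}

#' Calibrate the within-type correlation for one stratum and metric
#'
#' Solves the pooled-correlation moment identity for the common within-type
#' correlation rho_w such that pooling the three type-specific bivariate
#' normals (BMI, metric) with the given group sizes, means and SDs yields
#' the target pooled Pearson correlation:
#' \deqn{r_{pooled} = \frac{cov_{between} + \rho_w \sum_g w_g \sigma_{Bg}\sigma_{Mg}}
#'                         {\sigma^{tot}_B \, \sigma^{tot}_M}}
#' where the between-group covariance and variances come from size-weighted
#' group means, and total variances are within + between.
#'
#' @param n Group sizes (one per type).
#' @param bmi_mean,bmi_sd BMI mean and SD per type.
#' @param met_mean,met_sd Metric mean and SD per type.
#' @param target_r Target pooled Pearson correlation, |r| < 1.
#' @return The within-type correlation rho_w in (-1, 1).
#' @export
calibrate_within_correlation <- function(n, bmi_mean, bmi_sd,
                                         met_mean, met_sd, target_r) {
  stopifnot(length(n) == length(bmi_mean), length(n) == length(met_mean))
  if (abs(target_r) >= 1) stop("|target_r| must be < 1")
  w <- n / sum(n)
  mb <- pooled_moments(n, bmi_mean, bmi_sd)
  mm <- pooled_moments(n, met_mean, met_sd)
  cov_between <- sum(w * (bmi_mean - mb$grand) * (met_mean - mm$grand))
  within_scale <- sum(w * bmi_sd * met_sd)
  rho <- (target_r * sqrt(mb$total_var * mm$total_var) - cov_between) /
    within_scale
  if (abs(rho) >= 1)
    stop("target correlation unattainable with given group structure")
  rho
}

#' Pooled correlation implied by group structure and a within correlation
#'
#' Forward form of the calibration identity: the asymptotic pooled Pearson
#' correlation obtained when each type contributes a bivariate normal with
#' within-type correlation `rho_w`. Inverse of
#' [calibrate_within_correlation()].
#'
#' @inheritParams calibrate_within_correlation
#' @param rho_w Common within-type correlation.
#' @return The implied pooled correlation.
#' @export
implied_pooled_correlation <- function(n, bmi_mean, bmi_sd,
                                       met_mean, met_sd, rho_w) {
  w <- n / sum(n)
  mb <- pooled_moments(n, bmi_mean, bmi_sd)
  mm <- pooled_moments(n, met_mean, met_sd)
  cov_between <- sum(w * (bmi_mean - mb$grand) * (met_mean - mm$grand))
  (cov_between + rho_w * sum(w * bmi_sd * met_sd)) /
    sqrt(mb$total_var * mm$total_var)
}

#' Build a calibrated synthetic-data configuration
#'
#' Combines the published group summaries with within-type correlations
#' calibrated so that pooled BMI-metric correlations match the published
#' stratum values. Metric-metric within-type correlations default to zero;
#' the assembled per-group correlation matrix is repaired to the nearest
#' positive-definite matrix if needed.
#'
#' @param group_specs data.frame as [study_group_specs()].
#' @param target_r data.frame as [study_bmi_correlations()]; rows define the
#'   pooled BMI-metric targets per stratum.
#' @param metric_corr Optional within-type metric-metric correlation matrix
#'   (7 x 7, names from [metric_names()]); default zero off-diagonal.
#' @return An object of class `synthetic_config`: list with `group_specs`
#'   and `rho_w` (data.frame sex, age_group, metric, rho_w).
#' @export
synthetic_config <- function(group_specs = study_group_specs(),
                             target_r = study_bmi_correlations(),
                             metric_corr = NULL) {
  rho <- target_r
  rho$rho_w <- NA_real_
  for (i in seq_len(nrow(rho))) {
    g <- group_specs[group_specs$sex == rho$sex[i] &
                       group_specs$age_group == rho$age_group[i], ]
    m <- rho$metric[i]
    rho$rho_w[i] <- calibrate_within_correlation(
      g$n, g$bmi_mean, g$bmi_sd,
      g[[paste0(m, "_mean")]], g[[paste0(m, "_sd")]], rho$r[i])
  }
  mets <- metric_names()
  if (is.null(metric_corr)) {
    metric_corr <- diag(length(mets))
    dimnames(metric_corr) <- list(mets, mets)
  }
  structure(list(group_specs = group_specs, rho_w = rho,
                 metric_corr = metric_corr),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>", nrow(x$group_specs), "groups,",
      nrow(x$rho_w), "calibrated within-type correlations\n")
  invisible(x)
}

# Correlation matrix for one group: BMI first, then the 7 metrics.
group_correlation_matrix <- function(config, sex, age_group) {
  mets <- metric_names()
  k <- length(mets) + 1
  R <- diag(k)
  dimnames(R) <- list(c("bmi", mets), c("bmi", mets))
  R[mets, mets] <- config$metric_corr[mets, mets]
  diag(R) <- 1
  rw <- config$rho_w[config$rho_w$sex == sex &
                       config$rho_w$age_group == age_group, ]
  R["bmi", rw$metric] <- rw$rho_w
  R[rw$metric, "bmi"] <- rw$rho_w
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    warning("within-type correlation matrix not positive definite; ",
            "repaired to nearest positive-definite matrix")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  R
}

#' Generate metric-level synthetic subjects
#'
#' Draws per-group multivariate-normal (BMI, metrics) samples with the
#' calibrated within-type correlation structure. Deterministic for a fixed
#' seed set by the caller (the function does not reseed).
#'
#' @param config A `synthetic_config`.
#' @param strata Optional subset, e.g. `list(sex = "M", age_group = "20s")`.
#' @param n_per_group Optional override of group sizes (single number or a
#'   vector recycled across groups), e.g. for large-sample calibration
#'   checks.
#' @return data.frame with columns `subject_id`, `sex`, `age_group`, `type`,
#'   `bmi`, and the seven metric columns.
#' @export
generate_metric_level <- function(config, strata = NULL, n_per_group = NULL) {
  gs <- config$group_specs
  if (!is.null(strata)) {
    if (!is.null(strata$sex)) gs <- gs[gs$sex %in% strata$sex, ]
    if (!is.null(strata$age_group))
      gs <- gs[gs$age_group %in% strata$age_group, ]
  }
  if (!is.null(n_per_group)) gs$n <- rep(n_per_group, length.out = nrow(gs))
  vars <- c("bmi", metric_names())
  out <- vector("list", nrow(gs))
  for (i in seq_len(nrow(gs))) {
    g <- gs[i, ]
    R <- group_correlation_matrix(config, g$sex, g$age_group)
    mu <- vapply(vars, function(v) g[[paste0(v, "_mean")]], numeric(1))
    s <- vapply(vars, function(v) g[[paste0(v, "_sd")]], numeric(1))
    Sigma <- R * tcrossprod(s)
    X <- MASS::mvrnorm(g$n, mu = mu, Sigma = Sigma)
    if (g$n == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, vars))
    d <- data.frame(
      subject_id = sprintf("%s%s_%s_%04d", g$sex, g$age_group, g$type,
                           seq_len(g$n)),
      sex = g$sex, age_group = g$age_group, type = g$type,
      stringsAsFactors = FALSE)
    d[vars] <- as.data.frame(X)
    out[[i]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
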