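# Pearson correlations between BMI and facial metrics, and Fisher-z
# comparison of two correlation magnitudes across independent samples.

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation with the usual two-sided p-value from the
#' t distribution with n - 2 degrees of freedom (as `stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE))
}

#' Fisher-z comparison of two independent correlations
#'
#' Transforms both correlations with Fisher's z = atanh(r), standardizes
#' their difference by sqrt(1/(n1-3) + 1/(n2-3)), and returns the two-sided
#' standard-normal p-value.
#'
#' @param r1,n1 First correlation and its sample size (n1 >= 4, |r1| < 1).
#' @param r2,n2 Second correlation and its sample size.
#' @return Object of class `correlation_comparison`: list with `r1`, `n1`,
#'   `r2`, `n2`, `z1`, `z2`, `z_stat`, `p`.
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z_stat <- (z1 - z2) / se
  structure(
    list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z1 = z1, z2 = z2,
         z_stat = z_stat, p = 2 * pnorm(abs(z_stat), lower.tail = FALSE)),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("Fisher z: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d), z = %.3f, p = %.4f\n",
              x$r1, x$n1, x$r2, x$n2, x$z_stat, x$p))
  invisible(x)
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' BMI-facial-metric correlation report
#'
#' Per sex, the pooled correlation of BMI with each metric in the 20s and
#' 60s age strata (with significance stars at .05/.01/.001), the Fisher-z
#' p-value comparing the 20s and 60s correlations, and -- where external
#' published (r, n) pairs are supplied -- the Fisher-z p-value comparing
#' the 20s correlation with the external one.
#'
#' @param records data.frame with columns `sex`, `age_group`, `bmi` and
#'   metric columns (e.g. from [generate_metric_level()]).
#' @param external Optional data.frame with columns `sex`, `metric`, `r`,
#'   `n`; defaults to [external_bmi_correlations()].
#' @param min_n Minimum stratum size; smaller cells are reported as NA.
#' @return data.frame with one row per sex x metric.
#' @export
correlation_table <- function(records, external = external_bmi_correlations(),
                              min_n = 4) {
  rows <- list()
  for (sx in unique(records$sex)) {
    for (m in metric_names()) {
      cell <- function(age) {
        d <- records[records$sex == sx & records$age_group == age, ]
        if (nrow(d) < min_n) return(NULL)
        pearson_r(d$bmi, d[[m]])
      }
      c20 <- cell("20s"); c60 <- cell("60s")
      p_age <- if (!is.null(c20) && !is.null(c60))
        fisher_compare(c20$r, c20$n, c60$r, c60$n)$p else NA_real_
      ext <- external[external$sex == sx & external$metric == m, ]
      p_ext <- if (!is.null(c20) && nrow(ext) == 1)
        fisher_compare(c20$r, c20$n, ext$r, ext$n)$p else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, metric = m,
        r_20s = if (is.null(c20)) NA_real_ else c20$r,
        n_20s = if (is.null(c20)) NA_integer_ else c20$n,
        sig_20s = if (is.null(c20)) "" else sig_stars(c20$p),
        r_60s = if (is.null(c60)) NA_real_ else c60$r,
        n_60s = if (is.null(c60)) NA_integer_ else c60$n,
        sig_60s = if (is.null(c60)) "" else sig_stars(c60$p),
        p_20s_vs_60s = p_age, p_20s_vs_external = p_ext,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
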