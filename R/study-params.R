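# Published group summary statistics used to calibrate the synthetic-data
# generator and as inputs to the correlation comparisons. Values are the
# study's printed per-stratum means (SDs) for BMI and the seven facial
# metrics, per Sasang type within each sex x age stratum, and the printed
# pooled BMI-metric Pearson correlations with their sample sizes.

#' Study group summary statistics
#'
#' Printed mean/SD of BMI and each facial metric for the 12 groups
#' (3 Sasang types x 2 sexes x 2 age groups), with group sizes.
#'
#' @return data.frame with columns `sex`, `age_group`, `type`, `n`, and
#'   `<var>_mean` / `<var>_sd` for `bmi` and each metric.
#' @export
study_group_specs <- function() {
  # columns: mean, sd per variable; rows TE, SE, SY per stratum
  strata <- list(
    list(sex = "M", age_group = "20s", n = c(96, 57, 77),
         bmi  = list(c(25.1, 3.4),  c(20.7, 2.1),  c(22.3, 2.0)),
         PAR  = list(c(0.045, 0.002), c(0.046, 0.002), c(0.046, 0.0018)),
         WHR  = list(c(2.16, 0.14), c(2.08, 0.13), c(2.11, 0.14)),
         CJWR = list(c(1.13, 0.05), c(1.17, 0.05), c(1.16, 0.05)),
         eye_size = list(c(32.60, 1.79), c(31.66, 1.80), c(32.19, 1.72)),
         LF_FH = list(c(0.63, 0.03), c(0.62, 0.03), c(0.62, 0.02)),
         FW_LFH = list(c(1.21, 0.06), c(1.19, 0.07), c(1.19, 0.06)),
         EH_mean = list(c(16.58, 2.11), c(16.22, 1.86), c(16.63, 1.68))),
    list(sex = "F", age_group = "20s", n = c(93, 54, 82),
         bmi  = list(c(19.35, 2.28), c(16.63, 2.18), c(17.38, 1.94)),
         PAR  = list(c(0.047, 0.002), c(0.048, 0.002), c(0.048, 0.002)),
         WHR  = list(c(2.18, 0.13), c(2.14, 0.13), c(2.15, 0.13)),
         CJWR = list(c(1.16, 0.04), c(1.19, 0.05), c(1.18, 0.05)),
         eye_size = list(c(31.72, 1.73), c(31.16, 1.77), c(31.52, 1.60)),
         LF_FH = list(c(0.61, 0.02), c(0.60, 0.02), c(0.60, 0.02)),
         FW_LFH = list(c(1.23, 0.05), c(1.23, 0.05), c(1.25, 0.05)),
         EH_mean = list(c(17.92, 1.85), c(17.82, 1.97), c(18.04, 2.06))),
    list(sex = "M", age_group = "60s", n = c(87, 51, 80),
         bmi  = list(c(24.18, 2.74), c(19.99, 2.66), c(21.88, 2.60)),
         PAR  = list(c(0.045, 0.002), c(0.045, 0.002), c(0.045, 0.002)),
         WHR  = list(c(2.08, 0.14), c(1.99, 0.13), c(2.02, 0.11)),
         CJWR = list(c(1.06, 0.04), c(1.11, 0.05), c(1.09, 0.04)),
         eye_size = list(c(29.62, 1.96), c(28.70, 2.34), c(29.06, 2.03)),
         LF_FH = list(c(0.62, 0.02), c(0.61, 0.02), c(0.62, 0.02)),
         FW_LFH = list(c(1.21, 0.06), c(1.19, 0.06), c(1.20, 0.05)),
         EH_mean = list(c(18.29, 2.57), c(17.72, 3.12), c(18.28, 2.98))),
    list(sex = "F", age_group = "60s", n = c(90, 60, 84),
         bmi  = list(c(21.03, 1.97), c(17.54, 2.03), c(19.13, 2.08)),
         PAR  = list(c(0.047, 0.002), c(0.048, 0.003), c(0.047, 0.003)),
         WHR  = list(c(2.13, 0.15), c(2.12, 0.13), c(2.12, 0.16)),
         CJWR = list(c(1.07, 0.04), c(1.10, 0.04), c(1.09, 0.04)),
         eye_size = list(c(28.99, 1.86), c(28.22, 2.40), c(28.90, 1.94)),
         LF_FH = list(c(0.63, 0.02), c(0.62, 0.02), c(0.62, 0.02)),
         FW_LFH = list(c(1.21, 0.06), c(1.22, 0.05), c(1.21, 0.06)),
         EH_mean = list(c(20.28, 3.18), c(19.90, 2.87), c(19.47, 2.76)))
  )
  vars <- c("bmi", metric_names())
  types <- c("TE", "SE", "SY")
  out <- do.call(rbind, lapply(strata, function(s) {
    rows <- data.frame(sex = s$sex, age_group = s$age_group, type = types,
                       n = s$n, stringsAsFactors = FALSE)
    for (v in vars) {
      rows[[paste0(v, "_mean")]] <- vapply(s[[v]], `[`, numeric(1), 1)
      rows[[paste0(v, "_sd")]]   <- vapply(s[[v]], `[`, numeric(1), 2)
    }
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Study pooled BMI-facial-metric correlations
#'
#' Printed pooled (across Sasang types, within sex x age stratum) Pearson
#' correlations between BMI and each facial metric, with stratum sample
#' sizes and printed significance levels.
#'
#' @return data.frame with columns `sex`, `age_group`, `metric`, `r`, `n`,
#'   `sig` (significance stars as printed: "", "*", "**", "***").
#' @export
study_bmi_correlations <- function() {
  m <- metric_names()
  build <- function(sex, age, n, r, sig)
    data.frame(sex = sex, age_group = age, metric = m, r = r, n = n,
               sig = sig, stringsAsFactors = FALSE)
  rbind(
    build("M", "20s", 230, c(-0.30, 0.30, -0.40, 0.29, 0.12, 0.12, 0.05),
          c("***", "***", "***", "***", "", "", "")),
    build("F", "20s", 229, c(-0.23, 0.28, -0.29, 0.26, 0.10, 0.05, 0.16),
          c("***", "***", "***", "***", "", "", "*")),
    build("M", "60s", 219, c(-0.18, 0.28, -0.40, 0.27, 0.07, 0.16, 0.11),
          c("**", "***", "***", "***", "", "*", "")),
    build("F", "60s", 234, c(-0.28, 0.06, -0.27, 0.21, 0.29, 0.052, 0.12),
          c("***", "", "***", "**", "***", "", ""))
  )
}

#' External reference correlations (young Caucasian/African cohort)
#'
#' Published BMI correlations of PAR, WHR and CJWR from an earlier study of
#' young Caucasian and African adults, used as the external comparison arm
#' of the Fisher-z tests.
#'
#' @return data.frame with columns `sex`, `metric`, `r`, `n`.
#' @export
external_bmi_correlations <- function() {
  data.frame(
    sex = rep(c("M", "F"), each = 3),
    metric = rep(c("PAR", "WHR", "CJWR"), 2),
    r = c(-0.22, 0.17, -0.20, -0.12, 0.36, -0.29),
    n = rep(c(187, 194), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Published TE-type predictive equations
#'
#' The four stratum-specific logistic equations for the probability of the
#' TaeEum type, in the published sign convention
#' `probability = 1 / (1 + exp(x))` with
#' `x = intercept + b_bmi * BMI + b_cjwr * CJWR`.
#'
#' @return data.frame with columns `stratum`, `intercept`, `b_bmi`, `b_cjwr`.
#' @export
te_equations <- function() {
  data.frame(
    stratum = c("M20s", "M60s", "F20s", "F60s"),
    intercept = c(0.236, -8.572, 0.556, -1.77824),
    b_bmi = c(-0.454, -0.373, -0.4617, -0.54430),
    b_cjwr = c(9.237, 16.254, 6.9579, 11.99360),
    stringsAsFactors = FALSE
  )
}
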