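# One-way ANOVA across Sasang types with Duncan multiple-range post-hoc
# lettering (a > b > c by descending mean, groups sharing a letter not
# significantly different).

#' One-way ANOVA
#'
#' Standard between/within mean-square F test across k groups.
#'
#' @param groups Named list of numeric vectors, one per group (each n >= 2).
#' @return List with `F`, `df_between`, `df_within`, `p`, `mse`,
#'   `group_means`, `group_sds`, `group_ns`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- length(all_x) - length(groups)
  ms_b <- ss_between / df_b
  mse <- ss_within / df_w
  Fstat <- ms_b / mse
  list(F = Fstat, df_between = df_b, df_within = df_w,
       p = pf(Fstat, df_b, df_w, lower.tail = FALSE), mse = mse,
       group_means = means,
       group_sds = vapply(groups, sd, numeric(1)),
       group_ns = ns)
}

#' Duncan multiple-range critical value
#'
#' The studentized-range quantile at Duncan's protection level
#' `1 - (1 - alpha)^(p - 1)` for a span of `p` ordered means and `df`
#' error degrees of freedom.
#'
#' @param p Number of ordered means spanned (>= 2).
#' @param df Error degrees of freedom.
#' @param alpha Per-comparison significance level.
#' @return The critical studentized-range value.
#' @export
duncan_q <- function(p, df, alpha = 0.05) {
  qtukey(1 - (1 - (1 - alpha)^(p - 1)), nmeans = p, df = df)
}

#' Duncan multiple-range test with letter display
#'
#' Orders group means descending and compares every span of p adjacent
#' ordered means against the critical range
#' `q(alpha_p, p, df) * sqrt(MSE / n_h)`, with protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` and `n_h` the harmonic mean of the
#' group sizes (for unequal n). A span is declared significant only if it
#' exceeds its critical range and no enclosing span was retained as
#' non-significant. Letters are assigned so that groups not separated share
#' a letter; `a` marks the highest mean.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return List with `letters` (named character vector, group order as
#'   input), `means`, `anova` (the [one_way_anova()] result) and
#'   `critical_ranges`.
#' @export
duncan_letters <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  ord <- order(an$group_means, decreasing = TRUE)
  means_o <- an$group_means[ord]
  n_h <- k / sum(1 / an$group_ns)
  se <- sqrt(an$mse / n_h)
  crit <- vapply(2:k, function(p) duncan_q(p, an$df_within, alpha) * se,
                 numeric(1))
  names(crit) <- paste0("p", 2:k)

  # nonsig[i, j]: ordered means i..j retained as not significantly
  # different. Protection rule: a span is retained if its range does not
  # exceed the critical range OR it lies inside a retained larger span
  # (no subrange of a non-significant range is declared significant).
  # Processed from the largest span down so enclosing spans are known.
  nonsig <- diag(TRUE, k)
  if (k >= 2) {
    for (span in k:2) {
      for (i in 1:(k - span + 1)) {
        j <- i + span - 1
        within_retained <- FALSE
        if (span < k) {
          for (a2 in 1:i) {
            for (b2 in j:k) {
              if ((b2 - a2) > (j - i) && nonsig[a2, b2]) {
                within_retained <- TRUE; break
              }
            }
            if (within_retained) break
          }
        }
        nonsig[i, j] <- nonsig[j, i] <-
          within_retained || (means_o[i] - means_o[j]) <= crit[span - 1]
      }
    }
  }

  # letter assignment: maximal runs of consecutively non-different ordered
  # groups share a letter (the nonsig matrix is a staircase on ordered
  # means, so runs are contiguous)
  runs <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    i:j
  })
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(seq_along(runs), function(s)
      s != r && all(runs[[r]] %in% runs[[s]]) &&
        length(runs[[s]]) > length(runs[[r]]), logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  lett_o <- rep("", k)
  for (r in seq_along(runs))
    lett_o[runs[[r]]] <- paste0(lett_o[runs[[r]]], letters[r])
  letts <- setNames(rep("", k), names(an$group_means))
  letts[names(means_o)] <- lett_o
  list(letters = letts[names(an$group_means)], means = an$group_means,
       anova = an, critical_ranges = crit)
}

#' Tables-1/2-style group comparison report
#'
#' For each sex x age stratum, the per-type mean (SD) of BMI and every
#' metric, the one-way ANOVA p-value across types, and Duncan letters.
#'
#' @param records data.frame with `sex`, `age_group`, `type`, `bmi` and
#'   metric columns.
#' @param alpha Duncan significance level.
#' @return data.frame with one row per stratum x variable.
#' @export
group_comparison_table <- function(records, alpha = 0.05) {
  vars <- c("bmi", metric_names())
  types <- c("TE", "SE", "SY")
  rows <- list()
  for (sx in unique(records$sex)) {
    for (ag in unique(records$age_group)) {
      d <- records[records$sex == sx & records$age_group == ag, ]
      if (!nrow(d)) next
      for (v in vars) {
        grps <- lapply(types, function(ty) d[[v]][d$type == ty])
        names(grps) <- types
        grps <- grps[vapply(grps, length, integer(1)) >= 2]
        dl <- duncan_letters(grps, alpha = alpha)
        row <- data.frame(sex = sx, age_group = ag, variable = v,
                          F = dl$anova$F, p = dl$anova$p,
                          stringsAsFactors = FALSE)
        for (ty in names(grps)) {
          row[[paste0(ty, "_mean")]] <- dl$anova$group_means[[ty]]
          row[[paste0(ty, "_sd")]] <- dl$anova$group_sds[[ty]]
          row[[paste0(ty, "_letter")]] <-
            if (dl$anova$p < alpha) dl$letters[[ty]] else ""
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
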