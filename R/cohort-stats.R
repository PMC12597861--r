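# Group comparisons: Student's t (pooled variance), one-way ANOVA,
# Bonferroni adjustment and Cohen's d. The test engines are the stock R
# implementations; the wrappers standardise output shape and conventions.

#' Two-group Student's t test
#'
#' Two-sided pooled-variance (Student's) t test for independent groups, or
#' the paired t test on differences. Two constant equal groups return the
#' degenerate convention t = 0, p = 1 instead of erroring.
#'
#' @param a,b Numeric vectors (n >= 2 each; equal lengths when paired).
#' @param paired Paired test.
#' @param welch Use the Welch (unequal-variance) form instead.
#' @return Tibble with `t`, `df`, `p_value`.
#' @export
group_t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  if (paired && length(a) != length(b)) abort("paired test needs equal lengths")
  degenerate <- if (paired) sd(a - b) == 0 else sd(a) == 0 && sd(b) == 0
  if (degenerate) {
    equal <- if (paired) all(a == b) else mean(a) == mean(b)
    if (equal) {
      return(tibble(t = 0, df = if (paired) length(a) - 1 else
        length(a) + length(b) - 2, p_value = 1))
    }
    return(tibble(t = Inf * sign(mean(a) - mean(b)),
                  df = if (paired) length(a) - 1 else length(a) + length(b) - 2,
                  p_value = 0))
  }
  tt <- t.test(a, b, paired = paired, var.equal = !welch && !paired)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Cohen's d effect size (pooled SD, first group minus second)
#'
#' @param a,b Numeric vectors with n >= 2 each.
#' @return Effect size (missing-value marker when the pooled SD is zero).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) return(na_marker())
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' One-way analysis of variance
#'
#' @param groups List of at least 3 numeric vectors, each with n >= 2.
#' @return Tibble with `F`, `df1`, `df2`, `p_value` (degenerate
#'   zero-within-variance designs report the machine-maximum F and p = 0).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    abort("one_way_anova needs >= 3 groups; use group_t_test for two")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("each group needs n >= 2")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, function(v) var(v) == 0, logical(1)))) {
    ms_between <- var(vapply(groups, mean, numeric(1)))
    if (ms_between == 0) {
      return(tibble(F = 0, df1 = length(groups) - 1,
                    df2 = length(y) - length(groups), p_value = 1))
    }
    return(tibble(F = .Machine$double.xmax, df1 = length(groups) - 1,
                  df2 = length(y) - length(groups), p_value = 0))
  }
  fit <- summary(aov(y ~ g))[[1]]
  tibble(F = fit[["F value"]][1], df1 = fit[["Df"]][1], df2 = fit[["Df"]][2],
         p_value = fit[["Pr(>F)"]][1])
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param m Family size (defaults to `length(p_values)`).
#' @return Adjusted p values, `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Compare per-sample metrics between two cohorts
#'
#' Runs the independent-samples Student's t test per metric, applies a
#' Bonferroni correction over the family of metrics tested together, and
#' computes Cohen's d. Metrics with fewer than 2 non-missing samples in
#' either group are skipped with a message.
#'
#' @param metrics Per-sample metric tibble (e.g. [dysplasia_summary()])
#'   with a grouping column.
#' @param group_col Name of the grouping column (two levels).
#' @param metric_cols Metric columns to test (default: all numeric columns
#'   except counts). They form one Bonferroni family.
#' @param alpha Significance threshold used for the `significant` flag
#'   (applied to the adjusted p).
#' @param welch Use Welch's t instead of the pooled-variance form.
#' @return Tibble of class `cohort_comparison`, one row per tested metric:
#'   group means/medians/SDs and n, raw and Bonferroni-adjusted p, Cohen's d
#'   and the test name.
#' @export
cohort_compare <- function(metrics, group_col = "group",
                           metric_cols = NULL, alpha = 0.05, welch = FALSE) {
  need_cols(metrics, group_col)
  g <- metrics[[group_col]]
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2) abort("cohort_compare needs exactly 2 groups")
  if (is.null(metric_cols)) {
    num <- vapply(metrics, is.numeric, logical(1))
    metric_cols <- setdiff(names(metrics)[num],
                           c("n_events", "n_erythroid", "binucleate_n"))
  }
  rows <- purrr::map(metric_cols, function(mc) {
    a <- metrics[[mc]][g == lev[1]]
    b <- metrics[[mc]][g == lev[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      message("skipping metric '", mc, "': fewer than 2 samples per group")
      return(NULL)
    }
    tt <- group_t_test(a, b, welch = welch)
    tibble(metric = mc,
           group_1 = lev[1], group_2 = lev[2],
           n_1 = length(a), n_2 = length(b),
           mean_1 = mean(a), mean_2 = mean(b),
           median_1 = median(a), median_2 = median(b),
           sd_1 = sd(a), sd_2 = sd(b),
           t = tt$t, df = tt$df, p_value = tt$p_value,
           cohens_d = cohens_d(a, b),
           test = if (welch) "welch_t" else "student_t")
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_adjusted <- bonferroni(out$p_value)
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  }
  class(out) <- c("cohort_comparison", class(out))
  out
}

#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(n_metrics = nrow(x),
         n_significant = sum(x$significant),
         family_size = nrow(x))
}
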