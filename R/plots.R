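# ggplot2 views of the main result types.

#' Maturation gating scatter plot
#'
#' CD117 versus CD105 (log scale) of erythroid events, coloured by assigned
#' maturation stage.
#'
#' @param features Annotated feature tibble (after [maturation_split()]).
#' @param config A [gating_config()] (cutpoints drawn as reference lines).
#' @return A ggplot object.
#' @export
plot_maturation <- function(features, config = gating_config()) {
  df <- features %>%
    filter(.data$erythroid) %>%
    mutate(l105 = log_intensity(.data$cd105), l117 = log_intensity(.data$cd117))
  ggplot(df, aes(x = .data$l105, y = .data$l117,
                 colour = .data$stage_label)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_vline(xintercept = config$cd105_pos, linetype = 2) +
    ggplot2::geom_hline(yintercept = config$cd117_pos, linetype = 2) +
    labs(x = "CD105 (log10 intensity)", y = "CD117 (log10 intensity)",
         colour = "stage") +
    theme_bw()
}

#' DNA-content histogram with fitted ploidy windows
#'
#' @param features Annotated feature tibble.
#' @param model A [fit_ploidy()] object.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_ploidy <- function(features, model, bins = 80) {
  df <- features %>% filter(.data$erythroid, !is.na(.data$draq5_total))
  win <- tidy(model)
  ggplot(df, aes(x = .data$draq5_total)) +
    geom_histogram(bins = bins, fill = "grey70", colour = NA) +
    geom_vline(xintercept = c(win$lower, win$upper), linetype = 3) +
    geom_vline(xintercept = model$g1_peak, colour = "red") +
    labs(x = "total DRAQ5 (a.u.)", y = "events",
         title = "DNA content with G1 and G2/M windows") +
    theme_bw()
}

#' @export
autoplot.ploidy_model <- function(object, features, ...) {
  plot_ploidy(features, object, ...)
}

#' Per-stage nuclear condensation by cohort
#'
#' Boxplots of the per-sample mean condensation ratio (bright detail
#' intensity of DRAQ5 per square micrometre of nucleus) for each maturation
#' stage and group.
#'
#' @param summary_tbl Output of [dysplasia_summary()] (needs a `group`
#'   column).
#' @return A ggplot object.
#' @export
plot_condensation <- function(summary_tbl) {
  df <- summary_tbl %>%
    select(all_of(c("sample_id", "group", "cond_proery", "cond_baso",
                    "cond_mature"))) %>%
    tidyr::pivot_longer(-all_of(c("sample_id", "group")),
                        names_to = "stage", values_to = "condensation") %>%
    mutate(stage = factor(.data$stage,
                          levels = c("cond_proery", "cond_baso", "cond_mature"),
                          labels = c("ProEry", "Baso", "Mature")))
  ggplot(df, aes(x = .data$stage, y = .data$condensation,
                 fill = .data$group)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(y = "condensation (BDI-DRAQ5 / nuclear area)", x = NULL) +
    theme_bw()
}

#' @export
autoplot.cohort_comparison <- function(object, ...) {
  df <- object %>%
    mutate(metric = stats::reorder(.data$metric, abs(.data$cohens_d)))
  ggplot(df, aes(x = .data$cohens_d, y = .data$metric,
                 colour = .data$significant)) +
    geom_point(size = 2) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Cohen's d (group 1 - group 2)", y = NULL,
         colour = "adj. p < alpha") +
    theme_bw()
}
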