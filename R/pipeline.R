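#' Run the full synthetic-cohort study pipeline
#'
#' End-to-end composition of every stage: simulate (render + extract) the
#' MDS-like and NBM-like cohorts, run QC and immunophenotypic gating,
#' calibrate the binucleate refinement gates on a dedicated labelled
#' calibration sample (rendered with enriched binucleate and abnormal-nucleus
#' fractions so the gate boxes are estimated from a few hundred labelled
#' cells), detect binucleates, flag abnormal nuclei at the fixed published
#' aspect-ratio-intensity cutoff (or one recomputed from the NBM reference),
#' fit a per-sample DNA-content model and classify ploidy, build the NBM
#' size reference and flag megaloblasts, and summarise per-sample dysplasia
#' metrics plus cohort statistics.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @param gate_config A [gating_config()].
#' @param feat_config A [feature_config()].
#' @param ari_cutoff Fixed abnormal-nucleus cutoff on ARI (default 0.8, the
#'   published value); set `NULL` to use the NBM-derived mean - 2SD instead.
#' @param require_both Passed to [aberrant_gate()].
#' @param progress Print per-sample progress lines.
#' @return List with `features` (fully annotated event table), `truth`,
#'   `params`, `reference`, `binucleate_gates`, `ploidy_models` (per
#'   sample), `summary` (per-sample metrics) and `comparison` (MDS vs NBM
#'   cohort statistics).
#' @export
run_study <- function(config = simulation_config(), seed = 1,
                      gate_config = gating_config(),
                      feat_config = feature_config(),
                      ari_cutoff = 0.8, require_both = FALSE,
                      progress = FALSE) {
  sim <- simulate_cohort(config, seed, groups = c("MDS", "NBM"),
                         extract = TRUE, feat_config = feat_config,
                         progress = progress)
  cal <- calibration_sample(config, seed, gate_config = gate_config,
                            feat_config = feat_config)
  res <- annotate_study(sim$features, cal$gates, config = gate_config,
                        ari_cutoff = ari_cutoff, require_both = require_both)
  nbm_ann <- res$features %>% filter(.data$group == "NBM")
  reference <- build_reference(nbm_ann)
  if (is.null(ari_cutoff)) {
    res$features <- flag_abnormal_nuclei(res$features, ref = reference)
  }
  feats <- megaloblast_flags(res$features, reference)
  summ <- dysplasia_summary(feats)
  comp <- cohort_compare(summ)
  list(features = feats, truth = sim$truth, params = sim$params,
       reference = reference, binucleate_gates = cal$gates,
       ploidy_models = res$ploidy_models, summary = summ, comparison = comp)
}

#' Render a labelled calibration sample and calibrate refinement gates
#'
#' One extra sample at NBM geometry with enriched binucleate and
#' abnormal-nucleus fractions; its ground-truth labels replace the published
#' manual confirmation step when placing the binucleate refinement gates.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed (a dedicated stream index is used).
#' @param gate_config,feat_config Stage configurations.
#' @return List with `features`, `truth` and `gates`.
#' @export
calibration_sample <- function(config, seed = 1,
                               gate_config = gating_config(),
                               feat_config = feature_config()) {
  pars <- sample_cohort_params(config, "NBM", seed)[1, ]
  pars$sample_id <- "CAL_01"
  pars$binucleate_frac <- 0.10
  pars$abnormal_frac <- 0.15
  set.seed(sample_seed(seed, "NBM", 499L))
  # enough events that the enriched sample carries well over the minimum
  # number of labelled binucleate candidates
  n_cal <- max(config$events_per_sample, 1000L)
  truth <- sample_event_truth(n_cal, pars,
                              config$groups[["NBM"]], config)
  lay <- channel_layout(pixel_size_um = config$pixel_size_um)
  rows <- vector("list", nrow(truth))
  for (k in seq_len(nrow(truth))) {
    rows[[k]] <- extract_core(render_event(truth[k, ], config, lay),
                              lay, feat_config)
  }
  fe <- as_tibble(as.data.frame(do.call(rbind, rows)))
  fe <- dplyr::bind_cols(
    tibble(event_id = truth$event_id, sample_id = truth$sample_id,
           group = "CAL", analyzable = fe$analyzable > 0),
    fe %>% select(-"analyzable"))
  ann <- annotate_events(fe, gate_config)
  gates <- calibrate_binucleate_gates(ann, truth$binucleate)
  list(features = ann, truth = truth, gates = gates)
}

#' Annotate a simulated study table with all gates and dysplasia flags
#'
#' @param features Combined feature tibble of both cohorts (needs
#'   `sample_id`, `group`).
#' @param gates A [binucleate_gates()] object.
#' @param config A [gating_config()].
#' @param ari_cutoff Fixed ARI cutoff (`NULL` to defer reference-based
#'   flagging to the caller).
#' @param require_both Passed to [aberrant_gate()].
#' @return List with annotated `features` and per-sample `ploidy_models`.
#' @export
annotate_study <- function(features, gates = binucleate_gates(),
                           config = gating_config(), ari_cutoff = 0.8,
                           require_both = FALSE) {
  ann <- annotate_events(features, config, require_both = require_both) %>%
    detect_binucleates(gates)
  if (!is.null(ari_cutoff)) {
    ann <- flag_abnormal_nuclei(ann, cutoff = ari_cutoff)
  }
  models <- list()
  parts <- split(ann, ann$sample_id)
  parts <- lapply(parts, function(df) {
    if (sum(df$erythroid) >= 100) {
      m <- fit_ploidy(df)
      models[[df$sample_id[1]]] <<- m
      add_ploidy(df, m)
    } else {
      df$ploidy_class <- NA_character_
      df
    }
  })
  ann <- bind_rows(parts) %>% arrange(.data$sample_id, .data$event_id)
  list(features = ann, ploidy_models = models)
}

#' Extract the recovery quantities of the study
#'
#' Computes, from an annotated study, the headline cohort quantities:
#' sample-averaged percentages of abnormal nuclei, confirmed binucleates,
#' euploid binucleates and the aberrant population per group, and the
#' pooled Mature-stage shares of abnormal and binucleate events in the MDS
#' cohort.
#'
#' @param study Output of [run_study()].
#' @return Named list of scalar values.
#' @export
study_recovery <- function(study) {
  s <- study$summary
  fx <- study$features
  grp_mean <- function(col, grp) {
    mean(s[[col]][s$group == grp], na.rm = TRUE)
  }
  mds <- fx %>% filter(.data$group == "MDS")
  ab <- mds$abnormal_nucleus & !mds$binucleate_confirmed
  list(
    abnormal_pct_mds = grp_mean("abnormal_pct", "MDS"),
    abnormal_pct_nbm = grp_mean("abnormal_pct", "NBM"),
    abnormal_mature_share_mds =
      100 * sum(ab & mds$stage_label == "Mature", na.rm = TRUE) / sum(ab),
    binucleate_pct_mds = grp_mean("binucleate_pct", "MDS"),
    binucleate_pct_nbm = grp_mean("binucleate_pct", "NBM"),
    binuc_mature_share_mds =
      100 * sum(mds$binucleate_confirmed & mds$stage_label == "Mature",
                na.rm = TRUE) / sum(mds$binucleate_confirmed),
    binuc_euploid_pct_mds = grp_mean("binuc_euploid_pct", "MDS"),
    binuc_euploid_pct_nbm = grp_mean("binuc_euploid_pct", "NBM"),
    aberrant_pct_mds = grp_mean("aberrant_pct", "MDS"),
    aberrant_pct_nbm = grp_mean("aberrant_pct", "NBM")
  )
}
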