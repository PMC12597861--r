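# Dysplasia metrics: abnormal nuclei, binucleates with ploidy, megaloblastoid
# change, nuclear condensation and the per-sample metric table.

density_mode <- function(x, ...) {
  d <- stats::density(x, n = 512, ...)
  d$x[which.max(d$y)]
}

#' Normal reference: stage-wise sizes and pooled nuclear aspect ratio
#'
#' From annotated normal-bone-marrow samples, computes for each maturation
#' stage the mean and SD of cell area (pooled within sample, then averaged
#' across samples) with the megaloblast cutoff mean + 2SD, and the pooled
#' mean and SD of the DRAQ5 aspect ratio intensity over all NBM erythroid
#' events with the abnormal-nucleus cutoff mean - 2SD.
#'
#' @param nbm_features Annotated feature tibble of the reference samples
#'   (needs `sample_id`, `erythroid`, `stage_label`, `cell_area_um2`,
#'   `ari_draq5`); at least 2 samples.
#' @return An object of class `ery_reference`.
#' @export
build_reference <- function(nbm_features) {
  need_cols(nbm_features, c("sample_id", "erythroid", "stage_label",
                            "cell_area_um2", "ari_draq5"))
  ery <- nbm_features %>%
    filter(.data$erythroid, .data$stage_label %in% stage_names())
  n_samp <- dplyr::n_distinct(ery$sample_id)
  if (n_samp < 2) abort("reference requires at least 2 NBM samples")
  per_stage <- ery %>%
    group_by(.data$sample_id, .data$stage_label) %>%
    summarise(m = mean(.data$cell_area_um2, na.rm = TRUE),
              s = sd(.data$cell_area_um2, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$stage_label) %>%
    summarise(area_mean = mean(.data$m), area_sd = mean(.data$s),
              .groups = "drop") %>%
    mutate(megaloblast_cutoff = .data$area_mean + 2 * .data$area_sd)
  missing_stage <- setdiff(stage_names(), per_stage$stage_label)
  if (length(missing_stage) > 0) {
    abort(paste0("stage absent from all reference samples: ",
                 paste(missing_stage, collapse = ", ")))
  }
  ari <- ery$ari_draq5[!is.na(ery$ari_draq5)]
  structure(list(
    stages = per_stage,
    ari_mean = mean(ari),
    ari_sd = sd(ari),
    abnormal_ari_cutoff = mean(ari) - 2 * sd(ari),
    n_reference_samples = n_samp
  ), class = "ery_reference")
}

#' @export
print.ery_reference <- function(x, ...) {
  cat("<ery_reference> built from", x$n_reference_samples, "NBM samples\n")
  cat("  ARI", round(x$ari_mean, 3), "+/-", round(x$ari_sd, 3),
      "-> abnormal-nucleus cutoff", round(x$abnormal_ari_cutoff, 3), "\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.ery_reference <- function(x, ...) {
  x$stages %>% rename(stage = "stage_label")
}

#' @export
glance.ery_reference <- function(x, ...) {
  tibble(ari_mean = x$ari_mean, ari_sd = x$ari_sd,
         abnormal_ari_cutoff = x$abnormal_ari_cutoff,
         n_reference_samples = x$n_reference_samples)
}

#' Flag abnormal (asymmetric / elongated / bilobed) nuclei
#'
#' An erythroid QC-passing event is abnormal when its DRAQ5 aspect ratio
#' intensity falls strictly below the cutoff (the published fixed value is
#' 0.8, derived as NBM mean - 2SD). Confirmed binucleates, when already
#' annotated, are excluded: the abnormal-nucleus statistic never counts
#' them.
#'
#' @param features Annotated feature tibble.
#' @param ref An [build_reference()] object, or `NULL` when `cutoff` given.
#' @param cutoff Fixed cutoff overriding the reference-derived one.
#' @return Input tibble with logical `abnormal_nucleus` column.
#' @export
flag_abnormal_nuclei <- function(features, ref = NULL, cutoff = NULL) {
  need_cols(features, c("erythroid", "ari_draq5"))
  if (is.null(cutoff)) {
    if (is.null(ref)) abort("provide either `ref` or a fixed `cutoff`")
    cutoff <- ref$abnormal_ari_cutoff
  }
  flag <- features$erythroid & !is.na(features$ari_draq5) &
    features$ari_draq5 < cutoff
  if ("binucleate_confirmed" %in% names(features)) {
    flag <- flag & !features$binucleate_confirmed
  }
  features$abnormal_nucleus <- flag
  features
}

#' Rectangular refinement gates for binucleate confirmation
#'
#' Bounds on the two published scatter-gate axes pairs: symmetry-2 versus
#' circularity of the nuclear mask, then aspect ratio intensity versus
#' compactness. Events inside all four intervals are confirmed.
#'
#' @param symmetry2,circularity,ari,compactness Numeric length-2 intervals.
#' @return An object of class `binucleate_gates`.
#' @export
binucleate_gates <- function(symmetry2 = c(0.52, 0.70),
                             circularity = c(1.5, 3.2),
                             ari = c(0.22, 0.40),
                             compactness = c(0.50, 0.75)) {
  structure(list(symmetry2 = symmetry2, circularity = circularity,
                 ari = ari, compactness = compactness),
            class = "binucleate_gates")
}

#' @export
print.binucleate_gates <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("  %-12s [%.3f, %.3f]\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

#' @export
tidy.binucleate_gates <- function(x, ...) {
  tibble(axis = names(unclass(x)),
         lower = vapply(unclass(x), `[`, numeric(1), 1),
         upper = vapply(unclass(x), `[`, numeric(1), 2))
}

#' Calibrate binucleate refinement gates on a labelled sample
#'
#' Replaces the interactive visual confirmation step: gate bounds are set to
#' central quantile boxes of the four refinement axes among *labelled true
#' binucleates* that pass the lobe-count candidate step, slightly expanded.
#' Calibration requires a generator (or otherwise labelled) sample.
#'
#' @param features Feature tibble of the calibration sample.
#' @param is_binucleate Logical vector: ground-truth binucleate labels.
#' @param probs Quantile pair for the box.
#' @param expand Fractional expansion of each interval.
#' @return A [binucleate_gates()] object.
#' @export
calibrate_binucleate_gates <- function(features, is_binucleate,
                                       probs = c(0.002, 0.998),
                                       expand = 0.10) {
  need_cols(features, c("lobe_count", "symmetry2_nuc", "circularity_nuc",
                        "ari_draq5", "compactness_nuc"))
  cand <- !is.na(features$lobe_count) & features$lobe_count == 2 & is_binucleate
  if (sum(cand) < 20) {
    abort("calibration needs at least 20 labelled binucleate candidates")
  }
  box <- function(x) {
    q <- quantile(x[cand], probs, na.rm = TRUE, names = FALSE)
    w <- diff(q)
    c(q[1] - expand * w, q[2] + expand * w)
  }
  binucleate_gates(symmetry2 = box(features$symmetry2_nuc),
                   circularity = box(features$circularity_nuc),
                   ari = box(features$ari_draq5),
                   compactness = box(features$compactness_nuc))
}

#' Detect binucleate ("bilobated") erythroblasts
#'
#' Candidates are erythroid QC-passing events with a DRAQ5 lobe count of
#' exactly 2 (a mixture of real binucleates and abnormally shaped nuclei);
#' confirmation applies the rectangular refinement gates on the nuclear-mask
#' axes. Confirmed is always a subset of candidates.
#'
#' @param features Annotated feature tibble.
#' @param gates A [binucleate_gates()] object.
#' @return Input tibble with logical `binucleate_candidate` and
#'   `binucleate_confirmed` columns.
#' @export
detect_binucleates <- function(features, gates = binucleate_gates()) {
  need_cols(features, c("erythroid", "lobe_count", "symmetry2_nuc",
                        "circularity_nuc", "ari_draq5", "compactness_nuc"))
  inside <- function(x, b) !is.na(x) & x >= b[1] & x <= b[2]
  cand <- features$erythroid & !is.na(features$lobe_count) &
    features$lobe_count == 2
  conf <- cand &
    inside(features$symmetry2_nuc, gates$symmetry2) &
    inside(features$circularity_nuc, gates$circularity) &
    inside(features$ari_draq5, gates$ari) &
    inside(features$compactness_nuc, gates$compactness)
  features$binucleate_candidate <- cand
  features$binucleate_confirmed <- conf
  features
}

#' Fit the DNA-content (ploidy) model from erythroid DRAQ5 totals
#'
#' The G1 peak is the density mode of the total DRAQ5 distribution of the
#' erythroid events; the G1 and G2/M windows are multiplicative intervals
#' around 1x and 2x the peak (G2/M cells carry twice the DNA of euploid
#' cells).
#'
#' @param features Annotated feature tibble with at least 100 erythroid
#'   events.
#' @param g1_window,g2m_window Multiplicative windows on intensity / peak.
#' @return An object of class `ploidy_model`.
#' @export
fit_ploidy <- function(features, g1_window = c(0.75, 1.40),
                       g2m_window = c(1.60, 2.40)) {
  need_cols(features, c("erythroid", "draq5_total"))
  x <- features$draq5_total[features$erythroid & !is.na(features$draq5_total)]
  if (length(x) < 100) {
    abort("ploidy fit requires at least 100 erythroid events")
  }
  if (max(g1_window) > min(g2m_window)) abort("ploidy windows must be disjoint")
  structure(list(g1_peak = density_mode(x),
                 g1_window = g1_window, g2m_window = g2m_window,
                 n_events = length(x)),
            class = "ploidy_model")
}

#' @export
print.ploidy_model <- function(x, ...) {
  cat("<ploidy_model> G1 peak", signif(x$g1_peak, 5), "from", x$n_events,
      "erythroid events\n  G1 window [", paste(x$g1_window, collapse = ", "),
      ") x peak; G2/M window [", paste(x$g2m_window, collapse = ", "),
      "] x peak\n")
  invisible(x)
}

#' @export
tidy.ploidy_model <- function(x, ...) {
  tibble(window = c("G1", "G2M"),
         lower = c(x$g1_window[1], x$g2m_window[1]) * x$g1_peak,
         upper = c(x$g1_window[2], x$g2m_window[2]) * x$g1_peak)
}

#' @export
glance.ploidy_model <- function(x, ...) {
  tibble(g1_peak = x$g1_peak, n_events = x$n_events)
}

#' Classify DNA content against a fitted ploidy model
#'
#' @param draq5_total Numeric vector of total DRAQ5 intensities.
#' @param model A [fit_ploidy()] object.
#' @return Character vector: `"G1"`, `"G2M"` or `"other"` (`NA` in, `NA`
#'   out).
#' @export
classify_ploidy <- function(draq5_total, model) {
  r <- draq5_total / model$g1_peak
  out <- rep(NA_character_, length(r))
  ok <- !is.na(r)
  out[ok] <- "other"
  out[ok & r >= model$g1_window[1] & r < model$g1_window[2]] <- "G1"
  out[ok & r >= model$g2m_window[1] & r <= model$g2m_window[2]] <- "G2M"
  out
}

#' @rdname classify_ploidy
#' @param features Annotated feature tibble.
#' @return `add_ploidy()` returns the tibble with a `ploidy_class` column.
#' @export
add_ploidy <- function(features, model) {
  features$ploidy_class <- classify_ploidy(features$draq5_total, model)
  features
}

#' Flag megaloblasts: enlarged cells relative to the stage reference
#'
#' A cell is flagged when its area strictly exceeds the normal reference
#' mean + 2SD of its own maturation stage. Events whose stage carries no
#' reference get the missing-value marker.
#'
#' @param features Annotated feature tibble with `stage_label`.
#' @param ref An [build_reference()] object.
#' @return Input tibble with logical `megaloblast` column (`NA` where no
#'   reference applies).
#' @export
megaloblast_flags <- function(features, ref) {
  need_cols(features, c("stage_label", "cell_area_um2"))
  cut <- setNames(ref$stages$megaloblast_cutoff, ref$stages$stage_label)
  cutoff <- unname(cut[features$stage_label])
  features$megaloblast <- ifelse(is.na(cutoff), NA,
                                 features$cell_area_um2 > cutoff)
  features
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, na_marker())

#' Per-sample dysplasia metric table
#'
#' Summarises the full annotation set per sample: percentages of abnormal
#' nuclei (excluding confirmed binucleates), confirmed binucleates, euploid
#' (G1) binucleates, and the aberrant CD36-/dim population, all relative to
#' total erythropoiesis; the Mature-stage share of abnormal and binucleate
#' events; per-stage mean cell area, nuclear condensation (overall and
#' megaloblasts only) and nuclear:cytoplasmic ratio; condensation of the
#' aberrant versus mature non-aberrant compartments; and mean cytoplasmic
#' texture. Zero denominators yield missing values with the corresponding
#' count column retained.
#'
#' @param features Fully annotated feature tibble (QC, gating, dysplasia
#'   flags, ploidy classes).
#' @return Tibble with one row per sample.
#' @export
dysplasia_summary <- function(features) {
  need_cols(features, c("sample_id", "erythroid", "stage_label",
                        "abnormal_nucleus", "binucleate_confirmed",
                        "aberrant_cd36_cd71", "mature_non_aberrant",
                        "ploidy_class", "megaloblast", "cell_area_um2",
                        "condensation_ratio", "nc_ratio"))
  grp_cols <- intersect("group", names(features))
  stage_stat <- function(df, s, col) {
    v <- df[[col]][df$erythroid & !is.na(df$stage_label) & df$stage_label == s]
    if (length(v) == 0) na_marker() else mean(v, na.rm = TRUE)
  }
  features %>%
    group_by(across(all_of(c("sample_id", grp_cols)))) %>%
    dplyr::group_modify(function(df, key) {
      ery <- df$erythroid
      n_ery <- sum(ery)
      ab <- df$abnormal_nucleus & !df$binucleate_confirmed
      bi <- df$binucleate_confirmed
      n_bi <- sum(bi)
      bi_g1 <- sum(bi & !is.na(df$ploidy_class) & df$ploidy_class == "G1")
      mega <- !is.na(df$megaloblast) & df$megaloblast
      tibble(
        n_events = nrow(df),
        n_erythroid = n_ery,
        abnormal_pct = pct(sum(ab), n_ery),
        abnormal_mature_share = pct(sum(ab & df$stage_label == "Mature",
                                        na.rm = TRUE), sum(ab)),
        binucleate_pct = pct(n_bi, n_ery),
        binucleate_n = n_bi,
        binuc_mature_share = pct(sum(bi & df$stage_label == "Mature",
                                     na.rm = TRUE), n_bi),
        binuc_euploid_pct = pct(bi_g1, n_bi),
        aberrant_pct = pct(sum(df$aberrant_cd36_cd71), n_ery),
        area_proery = stage_stat(df, "ProEry", "cell_area_um2"),
        area_baso = stage_stat(df, "Baso", "cell_area_um2"),
        area_mature = stage_stat(df, "Mature", "cell_area_um2"),
        cond_proery = stage_stat(df, "ProEry", "condensation_ratio"),
        cond_baso = stage_stat(df, "Baso", "condensation_ratio"),
        cond_mature = stage_stat(df, "Mature", "condensation_ratio"),
        cond_mega_proery = stage_stat(df[mega, ], "ProEry", "condensation_ratio"),
        cond_mega_baso = stage_stat(df[mega, ], "Baso", "condensation_ratio"),
        cond_mega_mature = stage_stat(df[mega, ], "Mature", "condensation_ratio"),
        nc_proery = stage_stat(df, "ProEry", "nc_ratio"),
        nc_baso = stage_stat(df, "Baso", "nc_ratio"),
        nc_mature = stage_stat(df, "Mature", "nc_ratio"),
        cond_aberrant = if (any(df$aberrant_cd36_cd71))
          mean(df$condensation_ratio[df$aberrant_cd36_cd71], na.rm = TRUE)
          else na_marker(),
        cond_mature_nonaberrant = if (any(df$mature_non_aberrant))
          mean(df$condensation_ratio[df$mature_non_aberrant], na.rm = TRUE)
          else na_marker(),
        cyto_contrast_mean = mean(df$cyto_contrast[ery], na.rm = TRUE),
        cyto_variance_mean = mean(df$cyto_variance[ery], na.rm = TRUE)
      )
    }) %>%
    ungroup()
}

#' Long (tidy) form of the per-sample metric table
#'
#' @param summary_tbl Output of [dysplasia_summary()].
#' @return Tibble with columns `sample_id` (and `group` when present),
#'   `metric`, `value`.
#' @export
metrics_long <- function(summary_tbl) {
  id <- intersect(c("sample_id", "group"), names(summary_tbl))
  tidyr::pivot_longer(summary_tbl, -all_of(id),
                      names_to = "metric", values_to = "value")
}
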