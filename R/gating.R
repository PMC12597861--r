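# QC cascade and immunophenotypic gating. All gates are scalar thresholds on
# log10(1 + x)-transformed marker intensity sums: reproducible stand-ins for
# the hand-drawn two-dimensional regions of an interactive analysis. The
# default cutpoints sit in the valleys between the generator's negative and
# positive log-normal populations.

#' log10(1 + x) marker transform used by every gate
#' @param x Non-negative intensities.
#' @return Transformed values.
#' @export
log_intensity <- function(x) log10(1 + x)

#' Gating configuration: QC and immunophenotype cutpoints
#'
#' All marker cutpoints are on the log10(1 + x) scale of the per-event
#' intensity sums. `dim` cutpoints must not exceed the corresponding
#' positivity cutpoints.
#'
#' @param min_gradient_rms Minimum brightfield focus score (QC step a).
#' @param singlet_aspect_min Minimum cell aspect ratio (QC step b).
#' @param singlet_area_range Cell-area window in um^2 (QC step b).
#' @param draq5_min_frac_of_g1 DRAQ5+ cut as a fraction of the provisional
#'   G1 peak, removing apoptotic/low-DNA events (QC step c).
#' @param centroid_margin_px Margin from the frame edge within which the
#'   cell centroid must sit (QC step d, removes cropped cells).
#' @param min_circularity Minimum cell circularity (QC step d).
#' @param cd36_pos,cd71_pos,cd45_pos,cd105_pos,cd117_pos Positivity
#'   cutpoints.
#' @param cd36_dim,cd71_dim Dim cutpoints (aberrant-population gate).
#' @param cd45_dim_interval CD45 "dim" interval of the erythroid gate.
#' @param cd45_gran_interval CD45 interval of the granulocyte control gate.
#' @param lymph_area_max,gran_contrast_min Control-gate cuts: maximum cell
#'   area of lymphocytes (um^2) and minimum cytoplasmic Haralick contrast of
#'   granulocytes.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(min_gradient_rms = 0.055,
                          singlet_aspect_min = 0.7,
                          singlet_area_range = c(25, 500),
                          draq5_min_frac_of_g1 = 0.3,
                          centroid_margin_px = 10,
                          min_circularity = 7,
                          cd36_pos = 2.3, cd71_pos = 2.5,
                          cd45_pos = 4.1, cd105_pos = 2.9, cd117_pos = 2.9,
                          cd36_dim = 3.3, cd71_dim = 3.5,
                          cd45_dim_interval = c(2.6, 3.45),
                          cd45_gran_interval = c(3.45, 4.1),
                          lymph_area_max = 60,
                          gran_contrast_min = 8) {
  cfg <- list(min_gradient_rms = min_gradient_rms,
              singlet_aspect_min = singlet_aspect_min,
              singlet_area_range = singlet_area_range,
              draq5_min_frac_of_g1 = draq5_min_frac_of_g1,
              centroid_margin_px = centroid_margin_px,
              min_circularity = min_circularity,
              cd36_pos = cd36_pos, cd71_pos = cd71_pos, cd45_pos = cd45_pos,
              cd105_pos = cd105_pos, cd117_pos = cd117_pos,
              cd36_dim = cd36_dim, cd71_dim = cd71_dim,
              cd45_dim_interval = cd45_dim_interval,
              cd45_gran_interval = cd45_gran_interval,
              lymph_area_max = lymph_area_max,
              gran_contrast_min = gran_contrast_min)
  if (cd36_dim < 0 || cd71_dim < 0 ||
      diff(cd45_dim_interval) <= 0 || diff(singlet_area_range) <= 0) {
    abort("invalid gating configuration: empty interval")
  }
  structure(cfg, class = "gating_config")
}

need_cols <- function(features, cols) {
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0) {
    abort(paste0("feature table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
}

#' Quality-control cascade: focus, singlets, DRAQ5+, artifact removal
#'
#' Applies, in order: (a) focus (minimum brightfield gradient RMS), (b)
#' singlets (cell aspect ratio and area window), (c) DRAQ5 positivity
#' (total DRAQ5 at least a configured fraction of the provisional G1 peak —
#' the histogram mode among singlets — removing apoptotic and anucleate
#' events), (d) artifact removal (cell centroid away from the frame edge and
#' minimum circularity, removing cropped and grossly irregular cells).
#' Events failing any required feature (`NA`) fail that step.
#'
#' @param features Feature tibble (see [extract_features()]).
#' @param config A [gating_config()].
#' @param frame_width_px Acquisition frame width in pixels (for the centroid
#'   margin test).
#' @return The input tibble with logical columns `qc_focus`, `qc_singlet`,
#'   `qc_draq5`, `qc_artifact` (each cumulative: `TRUE` means the event
#'   survived that step and all before it) and `qc_pass`. Per-step retention
#'   counts are recovered by [qc_retention()].
#' @export
qc_pipeline <- function(features, config = gating_config(),
                        frame_width_px = 64) {
  need_cols(features, c("gradient_rms_bf", "aspect_ratio_cell",
                        "cell_area_um2", "draq5_total", "centroid_x",
                        "circularity_cell"))
  ok <- function(x) !is.na(x) & x
  f <- features
  f$qc_focus <- ok(f$gradient_rms_bf >= config$min_gradient_rms)
  f$qc_singlet <- f$qc_focus &
    ok(f$aspect_ratio_cell >= config$singlet_aspect_min) &
    ok(f$cell_area_um2 >= config$singlet_area_range[1]) &
    ok(f$cell_area_um2 <= config$singlet_area_range[2])
  # provisional G1 peak: DRAQ5 histogram mode among singlets
  dq <- f$draq5_total[f$qc_singlet & !is.na(f$draq5_total)]
  g1 <- if (length(dq) >= 10) density_mode(dq) else stats::median(dq)
  f$qc_draq5 <- f$qc_singlet & ok(f$draq5_total >= config$draq5_min_frac_of_g1 * g1)
  lo <- config$centroid_margin_px
  f$qc_artifact <- f$qc_draq5 &
    ok(f$centroid_x >= lo) & ok(f$centroid_x <= frame_width_px - lo + 1) &
    ok(f$circularity_cell >= config$min_circularity)
  f$qc_pass <- f$qc_artifact
  f
}

#' Per-step QC retention counts
#'
#' @param features Output of [qc_pipeline()].
#' @return Tibble with one row per step (`total`, `focus`, `singlet`,
#'   `draq5`, `artifact`) and the number of events retained after it;
#'   counts are monotone non-increasing.
#' @export
qc_retention <- function(features) {
  need_cols(features, c("qc_focus", "qc_singlet", "qc_draq5", "qc_artifact"))
  tibble(
    step = c("total", "focus", "singlet", "draq5", "artifact"),
    retained = c(nrow(features), sum(features$qc_focus),
                 sum(features$qc_singlet), sum(features$qc_draq5),
                 sum(features$qc_artifact))
  )
}

#' Erythroid gate: CD36+/CD45dim OR CD105+/CD45dim
#'
#' Boolean combination of the two published arms. Only QC-passing events can
#' be flagged.
#'
#' @param features Output of [qc_pipeline()].
#' @param config A [gating_config()].
#' @return Input tibble with a logical `erythroid` column.
#' @export
erythroid_gate <- function(features, config = gating_config()) {
  need_cols(features, c("cd36", "cd105", "cd45", "qc_pass"))
  cd36 <- log_intensity(features$cd36)
  cd105 <- log_intensity(features$cd105)
  cd45 <- log_intensity(features$cd45)
  dim45 <- !is.na(cd45) & cd45 >= config$cd45_dim_interval[1] &
    cd45 <= config$cd45_dim_interval[2]
  arm1 <- !is.na(cd36) & cd36 > config$cd36_pos & dim45
  arm2 <- !is.na(cd105) & cd105 > config$cd105_pos & dim45
  features$erythroid <- features$qc_pass & (arm1 | arm2)
  features
}

#' Split erythroid events into maturation stages
#'
#' CD117+/CD105+ proerythroblasts (`ProEry`), CD117-/CD105+ basophilic
#' erythroblasts (`Baso`) and CD117-/CD105- mature (poly-/orthochromatic)
#' erythroblasts (`Mature`). The combination CD117+/CD105- does not belong
#' to the published scheme and is labelled `"Ambiguous"`; it is excluded
#' from stage statistics. Non-erythroid events get `NA`.
#'
#' @param features Output of [erythroid_gate()].
#' @param config A [gating_config()].
#' @return Input tibble with a character `stage_label` column.
#' @export
maturation_split <- function(features, config = gating_config()) {
  need_cols(features, c("erythroid", "cd105", "cd117"))
  cd105 <- log_intensity(features$cd105) > config$cd105_pos
  cd117 <- log_intensity(features$cd117) > config$cd117_pos
  lab <- case_when(
    cd117 & cd105 ~ "ProEry",
    !cd117 & cd105 ~ "Baso",
    !cd117 & !cd105 ~ "Mature",
    .default = "Ambiguous"
  )
  features$stage_label <- ifelse(features$erythroid, lab, NA_character_)
  features
}

#' Aberrant CD36-/dim (optionally and CD71-/dim) gate within Mature
#'
#' Within the mature erythroid compartment, flags events whose CD36 falls at
#' or below the dim cutpoint (and, when `require_both`, whose CD71 does
#' too). Also derives the complementary mature non-aberrant set by Boolean
#' subtraction, so aberrant and non-aberrant partition Mature.
#'
#' @param features Output of [maturation_split()].
#' @param config A [gating_config()].
#' @param require_both Require CD71 dim in addition to CD36 dim.
#' @return Input tibble with logical `aberrant_cd36_cd71` and
#'   `mature_non_aberrant` columns.
#' @export
aberrant_gate <- function(features, config = gating_config(),
                          require_both = FALSE) {
  need_cols(features, c("stage_label", "cd36", "cd71"))
  mature <- !is.na(features$stage_label) & features$stage_label == "Mature"
  dim36 <- log_intensity(features$cd36) <= config$cd36_dim
  dim71 <- log_intensity(features$cd71) <= config$cd71_dim
  flag <- if (require_both) dim36 & dim71 else dim36
  features$aberrant_cd36_cd71 <- mature & !is.na(flag) & flag
  features$mature_non_aberrant <- mature & !features$aberrant_cd36_cd71
  features
}

#' Control gates: lymphocytes and granulocytes
#'
#' Lymphocytes: CD45 bright, CD36 negative, small cell. Granulocytes: CD45
#' intermediate, CD36 negative, high cytoplasmic texture contrast. Both are
#' disjoint from the erythroid gate by construction (CD45 outside the dim
#' interval).
#'
#' @param features Output of [qc_pipeline()] (erythroid flags not required).
#' @param config A [gating_config()].
#' @return Input tibble with logical `lymphocyte` and `granulocyte` columns.
#' @export
control_gates <- function(features, config = gating_config()) {
  need_cols(features, c("cd45", "cd36", "cell_area_um2", "cyto_contrast",
                        "qc_pass"))
  cd45 <- log_intensity(features$cd45)
  cd36 <- log_intensity(features$cd36)
  features$lymphocyte <- features$qc_pass &
    !is.na(cd45) & cd45 > config$cd45_pos &
    !is.na(cd36) & cd36 <= config$cd36_pos &
    !is.na(features$cell_area_um2) &
    features$cell_area_um2 <= config$lymph_area_max
  features$granulocyte <- features$qc_pass &
    !is.na(cd45) & cd45 > config$cd45_gran_interval[1] &
    cd45 <= config$cd45_gran_interval[2] &
    !is.na(cd36) & cd36 <= config$cd36_pos &
    !is.na(features$cyto_contrast) &
    features$cyto_contrast >= config$gran_contrast_min
  features
}

#' Run the full annotation chain
#'
#' Convenience wrapper: QC, erythroid gate, maturation split, aberrant gate
#' and control gates in one call.
#'
#' @param features Feature tibble.
#' @param config A [gating_config()].
#' @param require_both Passed to [aberrant_gate()].
#' @return Annotated tibble.
#' @export
annotate_events <- function(features, config = gating_config(),
                            require_both = FALSE) {
  features %>%
    qc_pipeline(config) %>%
    erythroid_gate(config) %>%
    maturation_split(config) %>%
    aberrant_gate(config, require_both = require_both) %>%
    control_gates(config)
}
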