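# hand-built feature rows exercising the gate definitions without rendering
gate_row <- function(gradient_rms_bf = 0.08, aspect_ratio_cell = 0.9,
                     cell_area_um2 = 80, draq5_total = 5e5, centroid_x = 32,
                     circularity_cell = 15, cd36 = 10^3.9, cd71 = 10^4.2,
                     cd45 = 10^2.95, cd105 = 10^1.85, cd117 = 10^1.85,
                     cyto_contrast = 12, ari_draq5 = 0.9) {
  tibble::tibble(gradient_rms_bf = gradient_rms_bf,
                 aspect_ratio_cell = aspect_ratio_cell,
                 cell_area_um2 = cell_area_um2, draq5_total = draq5_total,
                 centroid_x = centroid_x, circularity_cell = circularity_cell,
                 cd36 = cd36, cd71 = cd71, cd45 = cd45, cd105 = cd105,
                 cd117 = cd117, cyto_contrast = cyto_contrast,
                 ari_draq5 = ari_draq5)
}

test_that("QC steps fire in order with monotone retention", {
  f <- dplyr::bind_rows(
    gate_row(),                               # clean
    gate_row(gradient_rms_bf = 0.01),         # defocused
    gate_row(aspect_ratio_cell = 0.4),        # doublet
    gate_row(draq5_total = 2e4),              # apoptotic
    gate_row(centroid_x = 3),                 # cropped
    gate_row(circularity_cell = 2)            # irregular
  )
  # anchor the provisional G1 peak with a block of ordinary events
  f <- dplyr::bind_rows(f, dplyr::bind_rows(replicate(30, gate_row(),
                                                      simplify = FALSE)))
  q <- qc_pipeline(f, gating_config())
  ret <- qc_retention(q)
  expect_equal(ret$step, c("total", "focus", "singlet", "draq5", "artifact"))
  expect_true(all(diff(ret$retained) <= 0))
  expect_false(q$qc_focus[2])
  expect_false(q$qc_singlet[3])
  expect_false(q$qc_draq5[4])
  expect_false(q$qc_artifact[5])
  expect_false(q$qc_pass[6])
  expect_true(q$qc_pass[1])
})

test_that("a defocused-only batch loses every event at the focus step", {
  f <- dplyr::bind_rows(replicate(10, gate_row(gradient_rms_bf = 0.02),
                                  simplify = FALSE))
  q <- qc_pipeline(f)
  expect_equal(sum(q$qc_focus), 0)
  expect_equal(sum(q$qc_pass), 0)
})

test_that("missing QC columns are reported by name", {
  expect_error(qc_pipeline(gate_row()[, -1]), "gradient_rms_bf")
})

test_that("erythroid gate implements the two published Boolean arms", {
  f <- dplyr::bind_rows(
    gate_row(cd36 = 10^3.9, cd45 = 10^2.95, cd105 = 10^1.8),  # CD36 arm
    gate_row(cd36 = 10^1.8, cd45 = 10^2.95, cd105 = 10^3.8),  # CD105 arm
    gate_row(cd36 = 10^1.8, cd45 = 10^4.3, cd105 = 10^1.8),   # lymphocyte-like
    gate_row(cd36 = 10^3.9, cd45 = 10^4.3, cd105 = 10^3.8)    # CD45 bright
  )
  g <- erythroid_gate(qc_pipeline(f))
  expect_equal(g$erythroid, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("maturation split assigns the published marker combinations", {
  f <- dplyr::bind_rows(
    gate_row(cd117 = 10^3.8, cd105 = 10^3.8),  # ProEry
    gate_row(cd117 = 10^1.8, cd105 = 10^3.8),  # Baso
    gate_row(cd117 = 10^1.8, cd105 = 10^1.8),  # Mature
    gate_row(cd117 = 10^3.8, cd105 = 10^1.8)   # undefined combination
  )
  f$cd36 <- 10^3.9
  g <- maturation_split(erythroid_gate(qc_pipeline(f)))
  expect_equal(g$stage_label[1:3], c("ProEry", "Baso", "Mature"))
  expect_equal(g$stage_label[4], "Ambiguous")
  # every erythroid event gets exactly one label
  expect_false(any(is.na(g$stage_label[g$erythroid])))
})

test_that("aberrant gate is restricted to Mature and partitions it", {
  f <- dplyr::bind_rows(
    gate_row(cd36 = 10^2.9, cd105 = 10^1.8, cd117 = 10^1.8),   # aberrant mature
    gate_row(cd36 = 10^3.9, cd105 = 10^1.8, cd117 = 10^1.8),   # normal mature
    gate_row(cd36 = 10^2.9, cd105 = 10^3.8, cd117 = 10^3.8)    # dim CD36 ProEry
  )
  g <- aberrant_gate(maturation_split(erythroid_gate(qc_pipeline(f))))
  expect_equal(g$aberrant_cd36_cd71, c(TRUE, FALSE, FALSE))
  mature <- !is.na(g$stage_label) & g$stage_label == "Mature"
  expect_equal(mature, g$aberrant_cd36_cd71 | g$mature_non_aberrant)
  expect_false(any(g$aberrant_cd36_cd71 & g$mature_non_aberrant))
})

test_that("gating recovers generator truth with high recall and precision", {
  fx <- rendered_sample()
  ann <- annotate_events(fx$features)
  truth_ery <- fx$truth$population %in% c("ProEry", "Baso", "Mature")
  qc <- ann$qc_pass
  recall <- sum(ann$erythroid & truth_ery) / sum(truth_ery & qc)
  precision <- sum(ann$erythroid & truth_ery) / sum(ann$erythroid)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # clean (non-artifact) events survive QC almost entirely
  clean <- fx$truth$population %in% c("ProEry", "Baso", "Mature",
                                      "lymphocyte", "granulocyte")
  expect_gte(mean(qc[clean]), 0.95)
  # per-class stage recall
  tab <- table(fx$truth$stage[ann$erythroid], ann$stage_label[ann$erythroid])
  for (s in c("ProEry", "Baso", "Mature")) {
    expect_gte(tab[s, s] / sum(tab[s, ]), 0.9)
  }
})

test_that("control gates capture controls and exclude erythroid events", {
  fx <- rendered_sample()
  ann <- annotate_events(fx$features)
  lymph_truth <- fx$truth$population == "lymphocyte" & ann$qc_pass
  gran_truth <- fx$truth$population == "granulocyte" & ann$qc_pass
  expect_gte(mean(ann$lymphocyte[lymph_truth]), 0.9)
  expect_gte(mean(ann$granulocyte[gran_truth]), 0.9)
  expect_false(any(ann$lymphocyte & ann$erythroid))
  expect_false(any(ann$granulocyte & ann$erythroid))
  expect_false(any(ann$lymphocyte & ann$granulocyte))
})

test_that("DRAQ5-negative events never reach downstream statistics", {
  fx <- rendered_sample()
  ann <- annotate_events(fx$features)
  apopt <- fx$truth$population == "apoptotic"
  expect_equal(sum(ann$erythroid[apopt]), 0)
  expect_equal(sum(ann$qc_pass[apopt]), 0)
})

test_that("QC retention is reproducible across repeated runs", {
  fx <- rendered_sample()
  r1 <- qc_retention(qc_pipeline(fx$features))
  r2 <- qc_retention(qc_pipeline(fx$features))
  expect_identical(r1, r2)
})
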