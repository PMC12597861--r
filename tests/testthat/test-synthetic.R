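test_that("per-sample parameter draws are deterministic and in range", {
  cfg <- simulation_config()
  p1 <- sample_cohort_params(cfg, "MDS", seed = 5)
  p2 <- sample_cohort_params(cfg, "MDS", seed = 5)
  expect_identical(p1, p2)
  g <- cfg$groups$MDS
  expect_true(all(p1$abnormal_frac >= g$abnormal$range[1] &
                    p1$abnormal_frac <= g$abnormal$range[2]))
  expect_true(all(p1$euploid_frac >= g$euploid$range[1] &
                    p1$euploid_frac <= g$euploid$range[2]))
  expect_equal(sum(p1$aberrant_carrier), round(g$aberrant_prevalence * nrow(p1)))
  expect_true(all(p1$aberrant_frac[!p1$aberrant_carrier] == 0))
})

test_that("calibrated truncated normals hit the configured mean", {
  cal <- calibrate_truncnorm(0.115, 0.053, 0.199)
  set.seed(1)
  draws <- draw_truncnorm(1000, cal, stratified = FALSE)
  expect_lt(abs(mean(draws) - 0.115), 3 * sd(draws) / sqrt(1000))
  # stratified draws pin the realised mean much tighter
  set.seed(2)
  d2 <- draw_truncnorm(26, cal, stratified = TRUE)
  expect_lt(abs(mean(d2) - 0.115), 0.004)
  expect_error(calibrate_truncnorm(0.3, 0.05, 0.2), "infeasible")
})

test_that("binucleate euploid events render with lobes and euploid DNA", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "NBM", 3)[1, ]
  pars$binucleate_frac <- 1; pars$euploid_frac <- 1
  set.seed(20)
  tr <- sample_event_truth(80, pars, cfg$groups$NBM, cfg)
  bi <- which(tr$binucleate)[1:10]
  fe <- dplyr::bind_rows(lapply(bi, function(k) {
    extract_features(render_event(tr[k, ], cfg, channel_layout()))
  }))
  expect_true(all(fe$lobe_count == 2))
  # integrated DRAQ5 close to the euploid calibration (within a few CV)
  expect_true(all(abs(fe$draq5_total / cfg$draq5_g1_total - 0.9) < 0.25))
})

test_that("megaloblasts are larger and less condensed than stage-matched cells", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "MDS", 3)[1, ]
  set.seed(21)
  tr <- sample_event_truth(40, pars, cfg$groups$MDS, cfg)
  tr <- tr[tr$population == "Mature" & !tr$binucleate & !tr$abnormal_nucleus &
             !tr$aberrant, ][1, ]
  g <- cfg$groups$MDS
  mk <- function(mega) {
    t2 <- tr
    t2$megaloblast <- mega
    t2$cell_area_true <- if (mega) 70 * 1.5 else 70
    t2$nuclear_area_true <- t2$cell_area_true * 0.35
    t2$clump_amp <- g$clump_amp["Mature"] *
      (if (mega) g$megaloblast_clump_factor else 1)
    dplyr::bind_rows(lapply(1:10, function(i) {
      set.seed(300 + i)
      extract_features(render_event(t2, cfg, channel_layout()))
    }))
  }
  normo <- mk(FALSE); mega <- mk(TRUE)
  expect_gt(mean(mega$cell_area_um2), mean(normo$cell_area_um2))
  expect_lt(mean(mega$condensation_ratio), mean(normo$condensation_ratio))
})

test_that("higher granule density raises extracted cytoplasmic contrast", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "NBM", 3)[1, ]
  set.seed(22)
  tr <- sample_event_truth(40, pars, cfg$groups$NBM, cfg)
  tr <- tr[tr$population == "Mature" & !tr$abnormal_nucleus &
             !tr$binucleate, ][1, ]
  contrast_at <- function(amp) {
    t2 <- tr
    t2$texture_amp <- amp
    mean(vapply(1:10, function(i) {
      set.seed(400 + i)
      extract_features(render_event(t2, cfg, channel_layout()))$cyto_contrast
    }, numeric(1)))
  }
  expect_gt(contrast_at(0.014), contrast_at(0.008))
})

test_that("condensation tracks the clump amplitude monotonically", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "NBM", 3)[1, ]
  set.seed(23)
  tr <- sample_event_truth(40, pars, cfg$groups$NBM, cfg)
  tr <- tr[tr$population == "Mature" & !tr$abnormal_nucleus &
             !tr$binucleate, ][1, ]
  amps <- seq(0.1, 0.6, length.out = 8)
  cond <- vapply(seq_along(amps), function(j) {
    t2 <- tr
    t2$clump_amp <- amps[j]
    mean(vapply(1:6, function(i) {
      set.seed(500 + i)   # same geometry across amplitudes
      extract_features(render_event(t2, cfg, channel_layout()))$condensation_ratio
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(amps, cond, method = "spearman"), 0.9)
})

test_that("extracted cell area tracks the specified size after erosion correction", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "NBM", 3)[1, ]
  set.seed(24)
  tr <- sample_event_truth(200, pars, cfg$groups$NBM, cfg)
  tr <- tr[tr$population %in% c("ProEry", "Baso", "Mature"), ][1:40, ]
  fe <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(k) {
    extract_features(render_event(tr[k, ], cfg, channel_layout()))
  }))
  px <- cfg$pixel_size_um
  r_true <- sqrt(tr$cell_area_true / (pi * px^2))
  pred <- pi * (r_true - feature_config()$erode_cell)^2 * px^2
  bias <- mean(fe$cell_area_um2 / pred) - 1
  expect_lt(abs(bias), 0.05)
})

test_that("cohort simulation is reproducible and accounts for every event", {
  cfg <- simulation_config(n_mds = 1, n_nbm = 1, events_per_sample = 120)
  s1 <- simulate_cohort(cfg, seed = 6, extract = FALSE)
  s2 <- simulate_cohort(cfg, seed = 6, extract = FALSE)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 2 * 120)
  expect_equal(as.integer(table(s1$truth$sample_id)), c(120L, 120L))
})

test_that("with artifact rates at zero, QC keeps essentially everything", {
  g_mds <- group_defaults("MDS")
  g_nbm <- group_defaults("NBM")
  clean_props <- c(erythroid = 0.80, lymphocyte = 0.08, granulocyte = 0.12,
                   defocused = 0, doublet = 0, cropped = 0, apoptotic = 0)
  g_mds$pop_props <- clean_props
  g_nbm$pop_props <- clean_props
  cfg <- simulation_config(n_mds = 1, n_nbm = 1, events_per_sample = 300,
                           groups = list(MDS = g_mds, NBM = g_nbm))
  sim <- simulate_cohort(cfg, seed = 8)
  q <- qc_pipeline(sim$features)
  expect_gte(mean(q$qc_pass), 0.97)
})
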