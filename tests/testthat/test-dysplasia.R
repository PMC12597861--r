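ref_fixture <- function() {
  # two clean reference samples with known area and ARI structure
  set.seed(10)
  n <- 600
  tibble::tibble(
    sample_id = rep(c("N1", "N2"), each = n / 2),
    erythroid = TRUE,
    stage_label = rep(c("ProEry", "Baso", "Mature"), length.out = n),
    cell_area_um2 = rnorm(n, mean = c(160, 110, 70), sd = c(16, 11, 7)),
    ari_draq5 = rnorm(n, 0.9, 0.05)
  )
}

test_that("reference cutoffs follow the mean +/- 2SD construction", {
  ref <- build_reference(ref_fixture())
  expect_equal(ref$abnormal_ari_cutoff, ref$ari_mean - 2 * ref$ari_sd)
  expect_lt(abs(ref$abnormal_ari_cutoff - 0.8), 0.02)
  td <- tidy(ref)
  expect_equal(td$megaloblast_cutoff, td$area_mean + 2 * td$area_sd)
  expect_gt(min(td$megaloblast_cutoff - td$area_mean), 0)
  expect_equal(glance(ref)$n_reference_samples, 2)
})

test_that("the reference is invariant to sample ordering", {
  f <- ref_fixture()
  r1 <- build_reference(f)
  r2 <- build_reference(f[sample(nrow(f)), ])
  expect_equal(glance(r1), glance(r2))
  expect_equal(tidy(r1), tidy(r2))
})

test_that("reference construction fails cleanly on bad input", {
  f <- ref_fixture()
  expect_error(build_reference(f[f$sample_id == "N1", ]), "at least 2")
  f2 <- f
  f2$stage_label[f2$stage_label == "Baso"] <- "Mature"
  expect_error(build_reference(f2), "Baso")
})

test_that("abnormal-nucleus flag uses a strict cutoff and skips binucleates", {
  f <- tibble::tibble(erythroid = c(TRUE, TRUE, TRUE, FALSE),
                      ari_draq5 = c(0.79, 0.8, 0.5, 0.5),
                      binucleate_confirmed = c(FALSE, FALSE, TRUE, FALSE))
  g <- flag_abnormal_nuclei(f, cutoff = 0.8)
  expect_equal(g$abnormal_nucleus, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("binucleate detection: construction fixtures and subset property", {
  cfg <- simulation_config(events_per_sample = 100)
  pars <- sample_cohort_params(cfg, "NBM", 5)[1, ]
  pars$binucleate_frac <- 1
  set.seed(30)
  tr <- sample_event_truth(60, pars, cfg$groups$NBM, cfg)
  tr <- tr[tr$binucleate & tr$population == "Mature", ][1:8, ]
  fe <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(k) {
    extract_features(render_event(tr[k, ], cfg, channel_layout()))
  }))
  fe$erythroid <- TRUE
  det <- detect_binucleates(fe)
  expect_gte(mean(det$binucleate_candidate), 0.9)
  expect_gte(mean(det$binucleate_confirmed), 0.75)
  expect_true(all(!det$binucleate_confirmed | det$binucleate_candidate))
})

test_that("an indented single nucleus is a candidate but not confirmed", {
  # deep asymmetric pinch: passes the lobe-count split, fails the
  # symmetric-bilobed refinement box
  n <- 64
  g <- grid_xy(n)
  big <- (g$X - 26)^2 / 90 + (g$Y - 32)^2 / 70 <= 1
  small <- (g$X - 42)^2 / 28 + (g$Y - 32)^2 / 24 <= 1
  mask <- big | small
  w <- matrix(0, n, n)
  w[big] <- 1
  w[small] <- 0.95
  lc <- lobe_count(mask, w, 0.25, smooth_sigma = 1.8)
  expect_equal(lc, 2L)
  fe <- tibble::tibble(
    erythroid = TRUE, lobe_count = lc,
    symmetry2_nuc = symmetry2(mask, w),
    circularity_nuc = circularity(mask),
    ari_draq5 = aspect_ratio(mask, w),
    compactness_nuc = compactness(mask, w)
  )
  det <- detect_binucleates(fe)
  expect_true(det$binucleate_candidate)
  expect_false(det$binucleate_confirmed)
})

test_that("gate calibration reproduces boxes that capture labelled binucleates", {
  cfg <- simulation_config(events_per_sample = 400)
  cal <- calibration_sample(cfg, seed = 9)
  det <- detect_binucleates(cal$features, cal$gates)
  bi <- cal$truth$binucleate & det$erythroid
  expect_gte(sum(det$binucleate_confirmed[bi]) / sum(bi), 0.9)
  fp <- sum(det$binucleate_confirmed[!cal$truth$binucleate])
  expect_lte(fp / sum(!cal$truth$binucleate), 0.005)
})

test_that("ploidy fit finds the euploid mode and classifies windows", {
  set.seed(12)
  f <- tibble::tibble(erythroid = TRUE,
                      draq5_total = rnorm(2000, 1e5, 8e3))
  m <- fit_ploidy(f)
  expect_lt(abs(m$g1_peak - 1e5) / 1e5, 0.05)
  # 10% 4N contamination leaves the mode at 2N
  f2 <- tibble::tibble(erythroid = TRUE,
                       draq5_total = c(rnorm(1800, 1e5, 8e3),
                                       rnorm(200, 2e5, 1.6e4)))
  m2 <- fit_ploidy(f2)
  expect_lt(abs(m2$g1_peak - 1e5) / 1e5, 0.05)
  # scale equivariance
  f3 <- f
  f3$draq5_total <- f3$draq5_total * 3
  m3 <- fit_ploidy(f3)
  expect_equal(m3$g1_peak, 3 * m$g1_peak, tolerance = 1e-6)

  expect_equal(classify_ploidy(m$g1_peak, m), "G1")
  expect_equal(classify_ploidy(2 * m$g1_peak, m), "G2M")
  expect_equal(classify_ploidy(1.5 * m$g1_peak, m), "other")
  expect_error(fit_ploidy(f[1:50, ]), "100")
})

test_that("megaloblast flags use a strict per-stage cutoff", {
  ref <- build_reference(ref_fixture())
  cuts <- setNames(tidy(ref)$megaloblast_cutoff, tidy(ref)$stage)
  f <- tibble::tibble(stage_label = c("Mature", "Mature", "ProEry", "Odd"),
                      cell_area_um2 = c(cuts["Mature"], cuts["Mature"] + 1,
                                        cuts["ProEry"] + 5, 500))
  g <- megaloblast_flags(f, ref)
  expect_equal(g$megaloblast[1:3], c(FALSE, TRUE, TRUE))
  expect_true(is.na(g$megaloblast[4]))
})

test_that("NBM-at-own-reference flags the expected upper normal tail", {
  # with Gaussian sizes, area > mean + 2SD captures ~2.3% per stage
  set.seed(99)
  n <- 20000
  f <- tibble::tibble(
    sample_id = rep(c("N1", "N2"), each = n / 2),
    erythroid = TRUE,
    stage_label = sample(c("ProEry", "Baso", "Mature"), n, replace = TRUE),
    cell_area_um2 = NA_real_,
    ari_draq5 = rnorm(n, 0.9, 0.04)
  )
  mu <- c(ProEry = 160, Baso = 110, Mature = 70)
  f$cell_area_um2 <- rnorm(n, mu[f$stage_label], 0.13 * mu[f$stage_label])
  ref <- build_reference(f)
  g <- megaloblast_flags(f, ref)
  frac <- mean(g$megaloblast)
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.033)
})

test_that("the per-sample metric table has sane accounting", {
  fx <- rendered_sample()
  ann <- annotate_study(fx$features, binucleate_gates())$features
  ref <- build_reference(ann %>% dplyr::filter(group == "NBM"))
  ann <- megaloblast_flags(ann, ref)
  s <- dysplasia_summary(ann)
  expect_equal(nrow(s), dplyr::n_distinct(fx$features$sample_id))
  expect_true(all(s$n_erythroid > 0))
  expect_true(all(is.na(s$binuc_euploid_pct) | (s$binuc_euploid_pct >= 0 &
                                                  s$binuc_euploid_pct <= 100)))
  # zero-binucleate samples keep the count and blank the percentage
  none <- s$binucleate_n == 0
  expect_true(all(is.na(s$binuc_euploid_pct[none])))
  long <- metrics_long(s)
  expect_setequal(unique(long$sample_id), s$sample_id)
})

test_that("abnormal statistics exclude confirmed binucleates on every run", {
  fx <- rendered_sample()
  ann <- annotate_study(fx$features, binucleate_gates())$features
  expect_equal(sum(ann$abnormal_nucleus & ann$binucleate_confirmed), 0)
})
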