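# Synthetic imaging-flow-cytometry cohort generator.
#
# The generator draws per-sample dysplasia fractions from truncated normal
# distributions calibrated to the published cohort statistics of the two
# groups (MDS-like and normal bone marrow), then renders every event as a
# multi-channel 64x64 image: brightfield (bright background, darker cell with
# sparse dark granules whose density is the cytoplasmic texture
# parameter), DRAQ5 (nucleus with sub-resolution chromatin clumps whose
# amplitude is the condensation parameter and whose integrated intensity is
# proportional to DNA content), and five marker channels with log-normal
# population intensities. Artifact classes (defocused, doublet, cropped,
# apoptotic) are rendered per class so the QC cascade has something to remove.

# ---- truncated normal utilities ------------------------------------------

ptn_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

qtruncnorm <- function(p, mu, sd, lo, hi) {
  pa <- pnorm(lo, mu, sd); pb <- pnorm(hi, mu, sd)
  qnorm(pa + p * (pb - pa), mu, sd)
}

# location parameter such that the truncated mean hits `target` on [lo, hi]
calibrate_truncnorm <- function(target, lo, hi, sd = (hi - lo) / 6) {
  if (target < lo || target > hi) {
    abort(sprintf("infeasible truncation: mean %g outside range [%g, %g]",
                  target, lo, hi))
  }
  if (hi <= lo) abort("empty truncation range")
  f <- function(mu) ptn_mean(mu, sd, lo, hi) - target
  mu <- uniroot(f, lower = lo - 6 * sd, upper = hi + 6 * sd)$root
  list(mu = mu, sd = sd, lo = lo, hi = hi)
}

# n draws; stratified = one draw per equal-probability stratum in random
# order, so the realised cohort mean sits at the calibrated mean instead of
# wandering by O(sd/sqrt(n))
draw_truncnorm <- function(n, cal, stratified = TRUE) {
  p <- if (stratified) (sample(n) - runif(n)) / n else runif(n)
  qtruncnorm(p, cal$mu, cal$sd, cal$lo, cal$hi)
}

round_stoch <- function(x) as.integer(floor(x) + (runif(length(x)) < x - floor(x)))

# ---- configuration --------------------------------------------------------

#' Default per-group generator parameter blocks
#'
#' The MDS-like block enlarges cells by 15%, attenuates megaloblast
#' chromatin clumping, raises cytoplasmic granule density and carries the
#' published MDS distributions of abnormal-nucleus, binucleate, euploid and
#' aberrant-population fractions; the NBM-like block carries the normal
#' cohort values. Override individual entries and pass the blocks to
#' [simulation_config()] to move the simulated biology.
#'
#' @param group `"MDS"` or `"NBM"`.
#' @return Named list of generator parameters.
#' @export
group_defaults <- function(group = c("MDS", "NBM")) {
  group <- match.arg(group)
  common <- list(
    stage_props = c(ProEry = 0.10, Baso = 0.25, Mature = 0.65),
    pop_props = c(erythroid = 0.68, lymphocyte = 0.08, granulocyte = 0.12,
                  defocused = 0.05, doublet = 0.03, cropped = 0.02,
                  apoptotic = 0.02),
    area_mean = c(ProEry = 160, Baso = 110, Mature = 70),  # um^2, NBM scale
    area_sd_frac = 0.13,
    clump_amp = c(ProEry = 0.20, Baso = 0.35, Mature = 0.50),
    aberrant_clump_factor = 1.3,
    texture_amp_lymph = 0.0015,
    texture_amp_gran = 0.025,
    g2m_frac = c(ProEry = 0.15, Baso = 0.08, Mature = 0.02),
    lymph_area = c(mean = 45, sd = 5),
    gran_area = c(mean = 100, sd = 12)
  )
  spec <- if (group == "MDS") {
    list(
      size_factor = 1.15,
      nc_frac = c(ProEry = 0.55, Baso = 0.45, Mature = 0.35),
      megaloblast_clump_factor = 0.6,
      texture_amp_ery = 0.020,
      abnormal = list(mean = 0.115, range = c(0.053, 0.199)),
      abnormal_stage_props = c(ProEry = 0.151, Baso = 0.183, Mature = 0.666),
      binucleate = list(mean = 0.009, range = c(0.0015, 0.020)),
      binucleate_stage_props = c(ProEry = 0.12, Baso = 0.15, Mature = 0.73),
      euploid = list(mean = 0.584, range = c(0.263, 0.928)),
      aberrant_prevalence = 23 / 26,
      aberrant_size = list(mean = 0.070, range = c(0.010, 0.150))
    )
  } else {
    list(
      size_factor = 1.00,
      nc_frac = c(ProEry = 0.55, Baso = 0.45, Mature = 0.38),
      megaloblast_clump_factor = 1.0,
      texture_amp_ery = 0.008,
      abnormal = list(mean = 0.091, range = c(0.061, 0.129)),
      abnormal_stage_props = c(ProEry = 0.228, Baso = 0.212, Mature = 0.560),
      binucleate = list(mean = 0.004, range = c(0.0005, 0.0090)),
      binucleate_stage_props = c(ProEry = 0.21, Baso = 0.22, Mature = 0.57),
      euploid = list(mean = 0.348, range = c(0.000, 0.823)),
      aberrant_prevalence = 3 / 12,
      aberrant_size = list(mean = 0.012, range = c(0.002, 0.025))
    )
  }
  c(common, spec)
}

# log10 mean intensities per population and marker (arbitrary units);
# negatives sit near 2.0, the aberrant population is dim (between the
# erythroid-gate positivity cut and the normal bright level)
marker_table <- function() {
  m <- rbind(
    ProEry      = c(cd36 = 4.2, cd71 = 4.5, cd45 = 3.2, cd105 = 4.0, cd117 = 4.0),
    Baso        = c(cd36 = 4.2, cd71 = 4.5, cd45 = 3.2, cd105 = 4.0, cd117 = 2.0),
    Mature      = c(cd36 = 4.2, cd71 = 4.4, cd45 = 3.1, cd105 = 2.0, cd117 = 2.0),
    aberrant    = c(cd36 = 2.9, cd71 = 3.0, cd45 = 3.1, cd105 = 2.0, cd117 = 2.0),
    lymphocyte  = c(cd36 = 2.0, cd71 = 2.0, cd45 = 4.5, cd105 = 2.0, cd117 = 2.0),
    granulocyte = c(cd36 = 2.0, cd71 = 2.0, cd45 = 3.85, cd105 = 2.0, cd117 = 2.0)
  )
  m
}

#' Configuration of the synthetic cohort generator
#'
#' Default parameter values are the study conditions being emulated: 26
#' MDS-like and 12 normal-bone-marrow-like samples, 2000 events per sample at
#' 64x64 px and 0.33 um/px, per-sample dysplasia fractions drawn from
#' truncated normal distributions whose truncated means equal the published
#' cohort means and whose supports equal the published ranges, and group
#' differences (cell enlargement, cytoplasmic texture amplitude, megaloblast
#' condensation attenuation, aberrant-population prevalence) oriented as
#' reported for the two cohorts.
#'
#' @param n_mds,n_nbm Samples per group.
#' @param events_per_sample Events per sample (>= 100).
#' @param image_size Frame side in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param draq5_cv Coefficient of variation of total DRAQ5 at fixed DNA
#'   content.
#' @param draq5_g1_total Mean integrated DRAQ5 of a euploid (2N) nucleus,
#'   arbitrary intensity units.
#' @param marker_sd Log10 SD of marker intensity draws.
#' @param clump_px Nuclear pixels per chromatin clump (clump density).
#' @param groups Named list of per-group parameter blocks
#'   (see `erymorph:::group_defaults`); override entries to move the
#'   simulated biology.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_mds = 26, n_nbm = 12,
                              events_per_sample = 2000,
                              image_size = 64, pixel_size_um = 0.33,
                              draq5_cv = 0.08, draq5_g1_total = 5e5,
                              marker_sd = 0.12, clump_px = 6,
                              groups = list(MDS = group_defaults("MDS"),
                                            NBM = group_defaults("NBM"))) {
  stopifnot(events_per_sample >= 100)
  structure(list(
    n_samples = c(MDS = n_mds, NBM = n_nbm),
    events_per_sample = events_per_sample,
    image_size = image_size,
    pixel_size_um = pixel_size_um,
    draq5_cv = draq5_cv,
    draq5_g1_total = draq5_g1_total,
    marker_sd = marker_sd,
    clump_px = clump_px,
    marker_mu = marker_table(),
    groups = groups
  ), class = "sim_config")
}

# one RNG stream per sample so samples regenerate independently; kept well
# below 2^31
sample_seed <- function(master_seed, group, index) {
  base <- as.integer(master_seed %% 1000000L)
  off <- if (group == "MDS") 0L else 500L
  base * 1009L + off + as.integer(index)
}

#' Draw per-sample dysplasia parameters for one cohort
#'
#' For each sample the abnormal-nucleus, binucleate and
#' euploid-among-binucleate fractions are drawn from the calibrated truncated
#' normals; a fixed number `round(prevalence * n)` of samples carry an
#' aberrant mature population whose size is drawn likewise. Deterministic
#' given `seed`.
#'
#' @param config A [simulation_config()].
#' @param group `"MDS"` or `"NBM"`.
#' @param seed Integer master seed.
#' @param stratified Use quantile-stratified draws (default) so the finite
#'   cohort realises the calibrated means; set `FALSE` for iid draws (the
#'   correct mode for null-calibration studies).
#' @return Tibble with one row per sample.
#' @export
sample_cohort_params <- function(config, group = c("MDS", "NBM"), seed = 1,
                                 stratified = TRUE) {
  group <- match.arg(group)
  g <- config$groups[[group]]
  n <- config$n_samples[[group]]
  set.seed(sample_seed(seed, group, 0L))
  cal_ab <- calibrate_truncnorm(g$abnormal$mean, g$abnormal$range[1], g$abnormal$range[2])
  cal_bi <- calibrate_truncnorm(g$binucleate$mean, g$binucleate$range[1], g$binucleate$range[2])
  cal_eu <- calibrate_truncnorm(g$euploid$mean, g$euploid$range[1], g$euploid$range[2])
  cal_as <- calibrate_truncnorm(g$aberrant_size$mean, g$aberrant_size$range[1],
                                g$aberrant_size$range[2])
  n_carrier <- as.integer(round(g$aberrant_prevalence * n))
  carrier <- rep(FALSE, n)
  carrier[sample.int(n, n_carrier)] <- TRUE
  aberrant_frac <- numeric(n)
  if (n_carrier > 0) {
    aberrant_frac[carrier] <- draw_truncnorm(n_carrier, cal_as, stratified)
  }
  tibble(
    sample_id = sprintf("%s_%02d", group, seq_len(n)),
    group = group,
    abnormal_frac = draw_truncnorm(n, cal_ab, stratified),
    binucleate_frac = draw_truncnorm(n, cal_bi, stratified),
    euploid_frac = draw_truncnorm(n, cal_eu, stratified),
    aberrant_carrier = carrier,
    aberrant_frac = aberrant_frac,
    # biological between-sample variation of texture and condensation
    texture_mult = exp(rnorm(n, 0, 0.10)),
    cond_mult = exp(rnorm(n, 0, 0.08))
  )
}

# ---- per-event ground truth ----------------------------------------------

stage_names <- function() c("ProEry", "Baso", "Mature")

#' Draw the ground-truth event table for one sample
#'
#' Assigns every event a population (erythroid stage, lymphocyte,
#' granulocyte or an artifact class), dysplasia labels with exact per-sample
#' counts (abnormal nucleus with stage-calibrated placement, binucleate with
#' its euploid fraction, aberrant mature carve-out), DNA content, geometry
#' and rendering parameters. Uses the current RNG stream; [simulate_cohort()]
#' seeds one stream per sample.
#'
#' @param n_events Number of events.
#' @param sparams One row of [sample_cohort_params()].
#' @param g The per-group parameter block (see [group_defaults()]).
#' @param config A [simulation_config()].
#' @return Tibble with one row per event.
#' @export
sample_event_truth <- function(n_events, sparams, g, config) {
  probs <- c(g$pop_props[["erythroid"]] * g$stage_props,
             g$pop_props[c("lymphocyte", "granulocyte", "defocused",
                           "doublet", "cropped", "apoptotic")])
  names(probs) <- c(stage_names(), "lymphocyte", "granulocyte", "defocused",
                    "doublet", "cropped", "apoptotic")
  population <- sample(names(probs), n_events, replace = TRUE, prob = probs)
  stage <- ifelse(population %in% stage_names(), population, NA_character_)
  ery <- !is.na(stage)
  n_ery <- sum(ery)

  aberrant <- abnormal <- binucleate <- logical(n_events)
  abnormal_subtype <- rep(NA_character_, n_events)

  # aberrant mature population (carve-out of Mature, exact count)
  n_aber <- round_stoch(sparams$aberrant_frac * n_ery)
  mature_idx <- which(ery & stage == "Mature")
  n_aber <- min(n_aber, length(mature_idx))
  if (n_aber > 0) aberrant[sample(mature_idx, n_aber)] <- TRUE

  # abnormal nuclei: exact count, stage placement by the calibrated split
  pick_by_stage <- function(n_total, stage_props, excluded) {
    sel <- integer(0)
    if (n_total <= 0) return(sel)
    slots <- sample(stage_names(), n_total, replace = TRUE, prob = stage_props)
    for (s in stage_names()) {
      pool <- which(ery & stage == s & !excluded)
      k <- min(sum(slots == s), length(pool))
      if (k > 0) sel <- c(sel, sample(pool, k))
    }
    sel
  }
  n_ab <- round_stoch(sparams$abnormal_frac * n_ery)
  sel_ab <- pick_by_stage(n_ab, g$abnormal_stage_props, aberrant)
  abnormal[sel_ab] <- TRUE
  abnormal_subtype[sel_ab] <- sample(c("elongated", "indented"), length(sel_ab),
                                     replace = TRUE, prob = c(0.7, 0.3))

  # binucleates: exact count, disjoint from abnormal and aberrant
  n_bi <- round_stoch(sparams$binucleate_frac * n_ery)
  sel_bi <- pick_by_stage(n_bi, g$binucleate_stage_props, aberrant | abnormal)
  binucleate[sel_bi] <- TRUE

  # DNA content: binucleates euploid (2N) per the drawn per-sample fraction
  # (exact count), else 4N; mononuclear cells cycle at the stage-specific
  # G2/M rate; apoptotic events carry sub-G1 signal
  dna <- rep(2, n_events)
  if (length(sel_bi) > 0) {
    n_eu <- round_stoch(sparams$euploid_frac * length(sel_bi))
    eu <- rep(FALSE, length(sel_bi))
    if (n_eu > 0) eu[sample.int(length(sel_bi), min(n_eu, length(sel_bi)))] <- TRUE
    dna[sel_bi] <- ifelse(eu, 2, 4)
  }
  mono <- ery & !binucleate
  g2m_p <- g$g2m_frac[stage[mono]]
  dna[mono] <- ifelse(runif(sum(mono)) < g2m_p, 4, 2)
  dna[population == "apoptotic"] <- 0.5

  # geometry: cell size by stage (artifact classes reuse Mature geometry)
  eff_stage <- ifelse(is.na(stage), "Mature", stage)
  a_mean <- g$area_mean[eff_stage] * g$size_factor
  a_sd <- g$area_sd_frac * a_mean
  cell_area <- qtruncnorm(runif(n_events), a_mean, a_sd,
                          a_mean - 3.5 * a_sd, a_mean + 3.5 * a_sd)
  cell_area[population == "lymphocyte"] <-
    rnorm(sum(population == "lymphocyte"), g$lymph_area["mean"], g$lymph_area["sd"])
  cell_area[population == "granulocyte"] <-
    rnorm(sum(population == "granulocyte"), g$gran_area["mean"], g$gran_area["sd"])
  cell_area[population == "apoptotic"] <- cell_area[population == "apoptotic"] * 0.85
  cell_area <- pmax(cell_area, 20)

  # megaloblast truth: enlarged beyond the normal (NBM-scale) stage mean + 2SD
  nbm_mean <- g$area_mean[eff_stage]
  megaloblast <- ery & cell_area > nbm_mean * (1 + 2 * g$area_sd_frac)

  nc <- g$nc_frac[eff_stage]
  nc[population == "lymphocyte"] <- 0.68
  nc[population == "granulocyte"] <- 0.50
  nuclear_area <- cell_area * nc * (1 + rnorm(n_events, 0, 0.05))

  clump <- g$clump_amp[eff_stage]
  clump[population == "lymphocyte"] <- 0.7
  clump[population == "granulocyte"] <- 0.5
  clump <- clump * ifelse(megaloblast, g$megaloblast_clump_factor, 1) *
    ifelse(aberrant, g$aberrant_clump_factor, 1) *
    sparams$cond_mult * exp(rnorm(n_events, 0, 0.10))

  texture <- rep(g$texture_amp_ery, n_events)
  texture[population == "lymphocyte"] <- g$texture_amp_lymph
  texture[population == "granulocyte"] <- g$texture_amp_gran
  texture <- texture * sparams$texture_mult * exp(rnorm(n_events, 0, 0.15))

  # nuclear shape: minor/major axis ratio of the rendered nucleus
  axis_nuc <- qtruncnorm(runif(n_events), 0.94, 0.03, 0.88, 1.0)
  elong <- abnormal & abnormal_subtype == "elongated"
  axis_nuc[elong] <- runif(sum(elong), 0.40, 0.62)
  axis_cell <- qtruncnorm(runif(n_events), 0.92, 0.04, 0.80, 1.0)

  # marker intensities (log10-normal per population)
  pop_key <- eff_stage
  pop_key[aberrant] <- "aberrant"
  pop_key[population == "lymphocyte"] <- "lymphocyte"
  pop_key[population == "granulocyte"] <- "granulocyte"
  mu <- config$marker_mu[pop_key, , drop = FALSE]
  # the aberrant population is CD36-dim always, CD71-dim in ~60% of cells
  cd71_keep <- aberrant & runif(n_events) >= 0.6
  mu[cd71_keep, "cd71"] <- config$marker_mu["Mature", "cd71"]
  # negatives and dim populations have somewhat broader log-spreads
  sd_mat <- matrix(config$marker_sd, n_events, ncol(mu))
  sd_mat[mu <= 2.1] <- 0.15
  sd_mat[mu > 2.1 & mu <= 3.05 &
           col(mu) %in% which(colnames(mu) %in% c("cd36", "cd71"))] <- 0.20
  draws <- matrix(rnorm(n_events * ncol(mu), as.numeric(mu), as.numeric(sd_mat)),
                  n_events, ncol(mu))
  colnames(draws) <- colnames(mu)

  draq5_total <- (dna / 2) * config$draq5_g1_total *
    (1 + rnorm(n_events, 0, config$draq5_cv))
  draq5_total <- pmax(draq5_total, 0.05 * config$draq5_g1_total)

  tibble(
    event_id = sprintf("e%05d", seq_len(n_events)),
    sample_id = sparams$sample_id,
    group = sparams$group,
    population = population,
    stage = stage,
    aberrant = aberrant,
    abnormal_nucleus = abnormal,
    abnormal_subtype = abnormal_subtype,
    binucleate = binucleate,
    dna_content = dna,
    euploid = ifelse(binucleate | dna > 2, dna <= 2, NA),
    megaloblast = megaloblast,
    cell_area_true = cell_area,
    nuclear_area_true = nuclear_area,
    clump_amp = clump,
    texture_amp = texture,
    axis_ratio_nuc = axis_nuc,
    axis_ratio_cell = axis_cell,
    draq5_total_true = draq5_total,
    cd36_true = 10^draws[, "cd36"],
    cd71_true = 10^draws[, "cd71"],
    cd45_true = 10^draws[, "cd45"],
    cd105_true = 10^draws[, "cd105"],
    cd117_true = 10^draws[, "cd117"]
  )
}

# ---- rendering ------------------------------------------------------------

.grid_cache <- new.env(parent = emptyenv())

coord_grid <- function(n) {
  key <- as.character(n)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    X <- matrix(seq_len(n), n, n)
    g <- list(X = X, Y = t(X))
    .grid_cache[[key]] <- g
  }
  g
}

ellipse_mask <- function(n, cx, cy, area_px, ratio, theta) {
  a <- sqrt(area_px / (pi * ratio))    # semi-major axis, px
  b <- a * ratio
  g <- coord_grid(n)
  dx <- g$X - cx; dy <- g$Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render one synthetic event as a multi-channel image
#'
#' Renders brightfield, DRAQ5 and the five marker channels from one
#' ground-truth row (see [sample_event_truth()] via [simulate_cohort()]).
#' Uses the current RNG stream; callers seed per sample.
#'
#' @param spec One-row tibble of ground truth.
#' @param config A [simulation_config()].
#' @param layout A [channel_layout()].
#' @return An [event_image()].
#' @export
render_event <- function(spec, config, layout = channel_layout()) {
  n <- config$image_size
  px2 <- config$pixel_size_um^2
  pop <- spec$population
  cx <- n / 2 + 0.5 + runif(1, -3, 3)
  cy <- n / 2 + 0.5 + runif(1, -3, 3)
  if (pop == "cropped") {
    cx <- if (runif(1) < 0.5) 1 + runif(1, 0, 2) else n - runif(1, 0, 2)
  }
  theta <- runif(1, 0, pi)
  area_px <- spec$cell_area_true / px2
  cell <- ellipse_mask(n, cx, cy, area_px, spec$axis_ratio_cell, theta)
  r_cell <- sqrt(area_px / pi)

  cells <- cell
  centers <- list(c(cx, cy))
  if (pop == "doublet") {
    phi <- runif(1, 0, 2 * pi)
    cx2 <- cx + 1.7 * r_cell * cos(phi)
    cy2 <- cy + 1.7 * r_cell * sin(phi)
    cx2 <- min(max(cx2, r_cell * 0.8), n - r_cell * 0.8)
    cy2 <- min(max(cy2, r_cell * 0.8), n - r_cell * 0.8)
    cells <- cells | ellipse_mask(n, cx2, cy2, area_px, spec$axis_ratio_cell, theta)
    centers <- list(c(cx, cy), c(cx2, cy2))
  }
  if (!any(cells)) cells[round(cx), round(cy)] <- TRUE

  # brightfield: bright background, darker cell with a fine multiplicative
  # speckle plus sparse dark cytoplasmic granules; the texture parameter is
  # the granule density per cell pixel, so richer texture means more
  # intensity transitions (which per-event min-max quantisation of the
  # co-occurrence matrix cannot normalise away)
  bg <- 200
  bf <- matrix(bg, n, n) * (1 + rnorm(n * n, 0, 0.01))
  depth <- 0.35
  nin <- sum(cells)
  bf[cells] <- bg * (1 - depth) * (1 + 0.02 * rnorm(nin))
  n_gran <- stats::rpois(1, spec$texture_amp * nin)
  if (n_gran > 0) {
    gi <- matrix(0, n, n)
    pos <- which(cells)[sample.int(nin, n_gran, replace = TRUE)]
    amp <- bg * depth * 1.2 * (0.6 + 0.8 * runif(n_gran))
    gi[pos] <- gi[pos] + amp
    bf <- bf - gauss_blur(gi, 0.8)
  }
  bf <- gauss_blur(bf, 0.7)
  if (pop == "defocused") bf <- gauss_blur(bf, 3)
  bf <- pmax(bf, 0)

  # nucleus geometry (possibly two lobes or an indented shape), per cell
  nuc <- matrix(FALSE, n, n)
  for (cc in centers) {
    nuc_px <- max(spec$nuclear_area_true / px2, 9)
    if (isTRUE(spec$binucleate)) {
      # two clearly separated lobes (bilobed cells carry smaller lobes),
      # laid along the cell major axis and sized so the pair plus its gap
      # always fits inside the cell
      r_cell_here <- sqrt(area_px / pi)
      r_l <- min(sqrt(0.30 * nuc_px / pi), 0.37 * r_cell_here)
      d <- 2.9 * r_l
      lobe_area <- pi * r_l^2
      ux <- cos(theta); uy <- sin(theta)
      nuc <- nuc |
        ellipse_mask(n, cc[1] - d / 2 * ux, cc[2] - d / 2 * uy, lobe_area, 0.9, theta) |
        ellipse_mask(n, cc[1] + d / 2 * ux, cc[2] + d / 2 * uy, lobe_area, 0.9, theta)
    } else if (identical(spec$abnormal_subtype, "indented")) {
      a_big <- 0.72 * nuc_px; a_small <- 0.38 * nuc_px
      r_b <- sqrt(a_big / pi)
      ux <- cos(theta); uy <- sin(theta)
      nuc <- nuc |
        ellipse_mask(n, cc[1] - 0.55 * r_b * ux, cc[2] - 0.55 * r_b * uy, a_big, 0.85, theta) |
        ellipse_mask(n, cc[1] + 1.05 * r_b * ux, cc[2] + 1.05 * r_b * uy, a_small, 0.85, theta)
    } else {
      nuc <- nuc | ellipse_mask(n, cc[1], cc[2], nuc_px, spec$axis_ratio_nuc, theta)
    }
  }
  nuc <- nuc & cells
  if (!any(nuc)) nuc[round(cx), round(cy)] <- TRUE

  # DRAQ5: soft nuclear base plus sub-resolution chromatin clumps; total
  # integrated intensity follows DNA content
  base <- gauss_blur(nuc * 1, 0.7)
  nuc_idx <- which(nuc)
  n_clump <- max(4L, as.integer(round(length(nuc_idx) / config$clump_px)))
  imp <- matrix(0, n, n)
  pos <- nuc_idx[sample.int(length(nuc_idx), n_clump, replace = TRUE)]
  imp[pos] <- imp[pos] + spec$clump_amp * sum(base) / n_clump * (0.8 + 0.4 * runif(n_clump))
  dq <- base + gauss_blur(imp, 0.8)
  dq <- dq + abs(rnorm(n * n, 0, 0.003))
  total_mult <- if (pop == "doublet") 2 else 1
  dq <- dq * (total_mult * spec$draq5_total_true / sum(dq))

  # marker channels: uniform over the cell with mild per-pixel variation,
  # scaled to the drawn totals (gating uses the in-mask sums, so background
  # is left dark)
  mk_totals <- c(CD36 = spec$cd36_true, CD71 = spec$cd71_true,
                 CD45 = spec$cd45_true, CD105 = spec$cd105_true,
                 CD117 = spec$cd117_true) * total_mult
  mk <- lapply(mk_totals, function(tt) {
    per_px <- tt / nin
    ch <- matrix(0, n, n)
    ch[cells] <- pmax(per_px * (1 + 0.05 * rnorm(nin)), 0)
    ch * (tt / sum(ch))
  })

  channels <- c(list(bf, dq), mk)
  names(channels) <- c(layout$brightfield, layout$draq5,
                       layout$markers[c("cd36", "cd71", "cd45", "cd105", "cd117")])
  # rendered rasters are valid by construction; skip the constructor checks
  structure(
    list(event_id = spec$event_id, sample_id = spec$sample_id,
         channels = channels, pixel_size_um = config$pixel_size_um,
         width = n, height = n),
    class = "event_image"
  )
}

# ---- cohort simulation ----------------------------------------------------

#' Simulate a cohort of samples, optionally extracting features on the fly
#'
#' Renders every event of every sample (one RNG stream per sample derived
#' from the master seed) and, by default, immediately runs the mask/feature
#' extraction so the images never need to be held in memory. Optionally
#' writes per-sample directories of multi-page TIFF files, a channel-layout
#' sidecar and a `truth.csv`, which is the on-disk event-store layout
#' [load_events()] reads.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed; the run is fully deterministic given
#'   `(config, seed)`.
#' @param groups Which cohorts to generate.
#' @param extract Extract features while rendering (default `TRUE`).
#' @param out_dir Optional event-store directory to write.
#' @param layout A [channel_layout()].
#' @param feat_config A [feature_config()].
#' @param params Optional precomputed [sample_cohort_params()] tables
#'   (named list by group); drawn from `seed` when `NULL`.
#' @param stratified Passed to [sample_cohort_params()].
#' @param progress Print one line per sample.
#' @return List with `truth` (one row per event) and, when `extract`,
#'   `features` (one row per event, see [extract_features()]), plus
#'   `params` (the per-sample parameter draws).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1,
                            groups = c("MDS", "NBM"), extract = TRUE,
                            out_dir = NULL, layout = channel_layout(),
                            feat_config = feature_config(),
                            params = NULL, stratified = TRUE,
                            progress = FALSE) {
  if (!is.null(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) abort(paste0("cannot create output path: ", out_dir))
    write_channel_layout(layout, file.path(out_dir, "channels.yaml"))
  }
  truth_all <- list()
  feats_all <- list()
  par_all <- list()
  for (grp in groups) {
    pars <- if (!is.null(params) && !is.null(params[[grp]])) params[[grp]] else
      sample_cohort_params(config, grp, seed, stratified = stratified)
    par_all[[grp]] <- pars
    for (i in seq_len(nrow(pars))) {
      sp <- pars[i, ]
      set.seed(sample_seed(seed, grp, i))
      truth <- sample_event_truth(config$events_per_sample, sp,
                                  config$groups[[grp]], config)
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, grp, sp$sample_id)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      }
      if (extract || !is.null(out_dir)) {
        rows <- vector("list", nrow(truth))
        for (k in seq_len(nrow(truth))) {
          ev <- render_event(truth[k, ], config, layout)
          if (!is.null(out_dir)) write_event_tiff(ev, file.path(
            out_dir, grp, sp$sample_id, paste0(truth$event_id[k], ".tiff")))
          if (extract) rows[[k]] <- extract_core(ev, layout, feat_config)
        }
        if (extract) {
          mat <- do.call(rbind, rows)
          fe <- as_tibble(as.data.frame(mat))
          fe <- dplyr::bind_cols(
            tibble(event_id = truth$event_id, sample_id = truth$sample_id,
                   group = grp, analyzable = fe$analyzable > 0),
            fe %>% select(-"analyzable"))
          feats_all[[sp$sample_id]] <- fe
        }
      }
      truth_all[[sp$sample_id]] <- truth
      if (progress) message(sp$sample_id, " done")
    }
  }
  truth <- bind_rows(truth_all)
  if (!is.null(out_dir)) {
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  out <- list(truth = truth, params = bind_rows(par_all))
  if (extract) out$features <- bind_rows(feats_all)
  out
}
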