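# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

grid_xy <- function(n) {
  X <- matrix(seq_len(n), n, n)
  list(X = X, Y = t(X))
}

disc_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- grid_xy(n)
  (g$X - cx)^2 + (g$Y - cy)^2 <= r^2
}

rect_mask <- function(n, rows, cols) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

# event with arbitrary named channels, defaulting everything else to zero
make_event <- function(channels, pixel_size_um = 0.33) {
  event_image(channels, event_id = "fix", sample_id = "fixture",
              pixel_size_um = pixel_size_um)
}

# minimal event carrying a single channel under a given name
one_channel_event <- function(x, channel = "CH") {
  make_event(setNames(list(x), channel))
}

# ---- independent oracles --------------------------------------------------

# brute-force co-occurrence: explicit loop over every in-mask pixel and
# offset; deliberately naive and separate from the package implementation
bf_glcm <- function(x, mask, levels, offsets = list(c(1, 0), c(1, 1),
                                                    c(0, 1), c(-1, 1))) {
  v <- x[mask]
  rng <- range(v)
  q <- matrix(0L, nrow(x), ncol(x))
  if (rng[1] == rng[2]) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(levels, 1L + as.integer((x[mask] - rng[1]) /
                                              (rng[2] - rng[1]) * levels))
  }
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      if (!mask[i, j]) next
      for (off in offsets) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 >= 1 && i2 <= nrow(x) && j2 >= 1 && j2 <= ncol(x) &&
            mask[i2, j2]) {
          a <- q[i, j]; b <- q[i2, j2]
          P[a, b] <- P[a, b] + 1
          P[b, a] <- P[b, a] + 1
        }
      }
    }
  }
  P / sum(P)
}

# brute-force Haralick statistics by elementwise loops
bf_haralick <- function(P) {
  g <- nrow(P)
  contrast <- energy <- entropy <- homog <- 0
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(seq_len(g) * pi_m); mu_j <- sum(seq_len(g) * pj_m)
  var_i <- sum((seq_len(g) - mu_i)^2 * pi_m)
  var_j <- sum((seq_len(g) - mu_j)^2 * pj_m)
  corr_num <- 0
  for (i in seq_len(g)) for (j in seq_len(g)) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + (i - j)^2)
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * p
  }
  list(contrast = contrast, energy = energy, entropy = entropy,
       homogeneity = homog, variance = var_i,
       correlation = if (var_i > 0 && var_j > 0)
         corr_num / sqrt(var_i * var_j) else NA_real_)
}

# pooled-variance t statistic from first principles
bf_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

bf_anova_F <- function(groups) {
  y <- unlist(groups)
  k <- length(groups); n <- length(y)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# ---- small rendered sample shared across gating/dysplasia tests -----------

.fixture_env <- new.env(parent = emptyenv())

rendered_sample <- function() {
  if (is.null(.fixture_env$sample)) {
    cfg <- simulation_config(n_mds = 2, n_nbm = 2, events_per_sample = 600)
    sim <- simulate_cohort(cfg, seed = 202, groups = c("MDS", "NBM"))
    .fixture_env$sample <- list(cfg = cfg, features = sim$features,
                                truth = sim$truth, params = sim$params)
  }
  .fixture_env$sample
}
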