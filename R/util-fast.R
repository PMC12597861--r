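# internal numeric helpers shared by the batch extraction path

# bounding box of a mask with `pad` pixels of margin, clipped to the image
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask)
  nr <- nrow(mask)
  x <- ((idx - 1L) %% nr) + 1L
  y <- ((idx - 1L) %/% nr) + 1L
  list(r = max(1L, min(x) - pad):min(nr, max(x) + pad),
       c = max(1L, min(y) - pad):min(ncol(mask), max(y) + pad))
}

# separable truncated-Gaussian blur with edge renormalisation; the band
# matrices are cached per (dimension, sigma) since event frames share a size
.blur_cache <- new.env(parent = emptyenv())

blur_band <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  B <- .blur_cache[[key]]
  if (is.null(B)) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    B <- exp(-d^2 / (2 * sigma^2))
    B[d > ceiling(3 * sigma)] <- 0
    B <- B / rowSums(B)
    .blur_cache[[key]] <- B
  }
  B
}

gauss_blur <- function(x, sigma) {
  blur_band(nrow(x), sigma) %*% x %*% t(blur_band(ncol(x), sigma))
}

# numeric-vector Haralick computation (no tibble overhead); order matches
# c("contrast","correlation","energy","entropy","homogeneity","variance")
haralick_vec <- function(P) {
  g <- nrow(P)
  i <- matrix(seq_len(g), g, g)
  j <- t(i)
  pi_m <- rowSums(P)
  pj_m <- colSums(P)
  mu_i <- sum(seq_len(g) * pi_m)
  mu_j <- sum(seq_len(g) * pj_m)
  sd_i <- sqrt(sum((seq_len(g) - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((seq_len(g) - mu_j)^2 * pj_m))
  nz <- P > 0
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else {
    na_marker()
  }
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    entropy = -sum(P[nz] * log2(P[nz])),
    homogeneity = sum(P / (1 + (i - j)^2)),
    variance = sum((i - mu_i)^2 * P))
}

# co-occurrence accumulation on a pre-quantised integer matrix (0 = outside)
glcm_counts <- function(q, levels, offsets) {
  nr <- nrow(q); nc <- ncol(q)
  counts <- numeric(levels * levels)
  for (off in offsets) {
    dx <- off[1]; dy <- off[2]
    r1 <- max(1, 1 - dx):min(nr, nr - dx)
    c1 <- max(1, 1 - dy):min(nc, nc - dy)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dx, c1 + dy, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    counts <- counts + tabulate((ia - 1L) * levels + ib, nbins = levels * levels)
    counts <- counts + tabulate((ib - 1L) * levels + ia, nbins = levels * levels)
  }
  counts
}
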