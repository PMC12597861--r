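# Shape features of masks, optionally intensity weighted. All of them return
# the missing-value marker (NA) on degenerate input instead of raising, so a
# single bad event never aborts a batch extraction.

# coordinates (row = x, col = y) and weighted first/second moments of a mask
mask_moments <- function(mask, weights = NULL) {
  idx <- which(mask)
  if (length(idx) == 0) return(NULL)
  nr <- nrow(mask)
  x <- ((idx - 1L) %% nr) + 1L
  y <- ((idx - 1L) %/% nr) + 1L
  w <- if (is.null(weights)) rep(1, length(idx)) else as.numeric(weights[idx])
  wt <- sum(w)
  if (wt <= 0) return(NULL)
  cx <- sum(w * x) / wt
  cy <- sum(w * y) / wt
  dx <- x - cx
  dy <- y - cy
  list(x = x, y = y, w = w, wt = wt, cx = cx, cy = cy,
       sxx = sum(w * dx * dx) / wt,
       syy = sum(w * dy * dy) / wt,
       sxy = sum(w * dx * dy) / wt)
}

# eigenvalues of the 2x2 second-moment matrix, largest first
moment_eigen <- function(m) {
  tr <- m$sxx + m$syy
  det <- m$sxx * m$syy - m$sxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  c(tr / 2 + disc, max(0, tr / 2 - disc))
}

#' Aspect ratio of a mask (minor/major axis), optionally intensity weighted
#'
#' Ratio of minor to major axis length derived from the second central
#' moments of the in-mask pixel coordinates. With `weights` this is the
#' Aspect Ratio Intensity (e.g. of DRAQ5 on the nuclear mask): elongated or
#' bilobed nuclei score low, round symmetric nuclei score close to 1.
#'
#' @param mask Logical matrix.
#' @param weights Optional non-negative raster of the same shape.
#' @return Value in (0, 1], or `NA` for an empty mask.
#' @export
aspect_ratio <- function(mask, weights = NULL) {
  m <- mask_moments(mask, weights)
  if (is.null(m)) return(na_marker())
  ev <- moment_eigen(m)
  if (ev[1] <= 0) return(1)   # single pixel: perfectly symmetric by convention
  sqrt(ev[2] / ev[1])
}

#' Focus score: RMS intensity gradient over a mask
#'
#' Root mean square of the central-difference gradient magnitude over in-mask
#' interior pixels, normalised by the mean in-mask intensity. Sharply focused
#' images score high; defocused (blurred) images score low. The QC cascade
#' thresholds this on the brightfield channel.
#'
#' @param image An [event_image()].
#' @param channel Channel name.
#' @param mask Logical matrix.
#' @return Unitless score, `NA` for empty mask or zero mean intensity.
#' @export
gradient_rms <- function(image, channel, mask) {
  x <- get_channel(image, channel)
  if (!any(mask)) return(na_marker())
  nr <- nrow(x); nc <- ncol(x)
  core <- 2:(nr - 1)
  corc <- 2:(nc - 1)
  gx <- (x[3:nr, corc, drop = FALSE] - x[1:(nr - 2), corc, drop = FALSE]) / 2
  gy <- (x[core, 3:nc, drop = FALSE] - x[core, 1:(nc - 2), drop = FALSE]) / 2
  g2 <- gx^2 + gy^2
  inner <- mask[core, corc, drop = FALSE]
  if (!any(inner)) return(na_marker())
  mu <- mean(x[core, corc][inner])
  if (mu <= 0) return(na_marker())
  sqrt(mean(g2[inner])) / mu
}

# 4-neighbour erosion by shifting; used to find boundary pixels
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  up <- pad[1:nr, 2:(nc + 1)]
  dn <- pad[3:(nr + 2), 2:(nc + 1)]
  lf <- pad[2:(nr + 1), 1:nc]
  rt <- pad[2:(nr + 1), 3:(nc + 2)]
  mask & !(up & dn & lf & rt)
}

#' Circularity: mean over SD of boundary-to-centroid distance
#'
#' Distances from every boundary pixel to the mask centroid are collected;
#' the score is their mean divided by their standard deviation, capped at
#' `cap` when the SD is near zero. Rounder masks score higher; cropped or
#' irregular cells score low, which is what the artifact-removal QC step
#' exploits.
#'
#' @param mask Logical matrix with at least 8 boundary pixels.
#' @param cap Maximum returned value (guards the SD -> 0 limit).
#' @return Unitless score, `NA` for a too-small mask.
#' @export
circularity <- function(mask, cap = 100) {
  if (!any(mask)) return(na_marker())
  b <- boundary_pixels(mask)
  m <- mask_moments(mask)
  mb <- mask_moments(b)
  if (is.null(mb) || length(mb$x) < 8) return(na_marker())
  d <- sqrt((mb$x - m$cx)^2 + (mb$y - m$cy)^2)
  s <- stats::sd(d)
  if (!is.finite(s) || s <= mean(d) / cap) return(cap)
  mean(d) / s
}

#' Compactness of an intensity distribution on a mask
#'
#' Ratio of the RMS radius of a uniform disc of equal pixel area to the
#' intensity-weighted RMS radial distance about the intensity centroid.
#' A uniform disc scores 1; split (bilobed) or elongated intensity layouts
#' spread mass away from the centroid and score below 1.
#'
#' @param mask Logical matrix.
#' @param weights Non-negative raster of the same shape.
#' @return Unitless score, `NA` for empty mask or zero total weight.
#' @export
compactness <- function(mask, weights) {
  m <- mask_moments(mask, weights)
  if (is.null(m)) return(na_marker())
  r_eq <- sqrt(sum(mask) / pi)        # radius of the equal-area disc, px
  rms_disc <- r_eq / sqrt(2)          # RMS radius of a uniform disc
  rms_w <- sqrt(m$sxx + m$syy)
  if (rms_w <= 0) return(na_marker())
  rms_disc / rms_w
}

#' Bilobedness score along the major axis (Symmetry 2 surrogate)
#'
#' The mask is split by the line through the intensity centroid
#' perpendicular to the intensity-weighted major axis. The score is the
#' distance between the intensity centroids of the two halves, projected on
#' the major axis, divided by the full projected extent of the mask. Two
#' equal point masses approach 1; a single centred blob scores low.
#'
#' @param mask Logical matrix.
#' @param weights Non-negative raster of the same shape.
#' @return Unitless score in \[0, 1\], `NA` on degenerate input.
#' @export
symmetry2 <- function(mask, weights) {
  m <- mask_moments(mask, weights)
  if (is.null(m)) return(na_marker())
  ev <- moment_eigen(m)
  if (ev[1] <= 0) return(na_marker())
  # principal eigenvector of [[sxx, sxy], [sxy, syy]]
  if (abs(m$sxy) > 1e-12) {
    v <- c(ev[1] - m$syy, m$sxy)
  } else if (m$sxx >= m$syy) {
    v <- c(1, 0)
  } else {
    v <- c(0, 1)
  }
  v <- v / sqrt(sum(v^2))
  proj <- (m$x - m$cx) * v[1] + (m$y - m$cy) * v[2]
  extent <- max(proj) - min(proj)
  if (extent <= 0) return(na_marker())
  plus <- proj >= 0
  wp <- sum(m$w[plus]); wm <- sum(m$w[!plus])
  if (wp <= 0 || wm <= 0) return(0)
  cplus <- sum(m$w[plus] * proj[plus]) / wp
  cminus <- sum(m$w[!plus] * proj[!plus]) / wm
  min(1, (cplus - cminus) / extent)
}

#' Count intensity lobes within a mask
#'
#' Counts regional maxima of the smoothed in-mask intensity whose topographic
#' prominence exceeds `prominence_frac` times the global in-mask maximum.
#' On the DRAQ5 channel restricted to the nuclear mask this is the lobe count
#' used as the first (candidate) step of binucleate detection: a single round
#' nucleus yields 1, two separated nuclear lobes yield 2.
#'
#' @param mask Logical matrix (non-empty).
#' @param weights Non-negative raster of the same shape.
#' @param prominence_frac Fraction of the global in-mask maximum that a
#'   secondary peak's prominence must exceed (0 < f < 1, default 0.2).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @param n_levels Number of threshold levels used in the prominence sweep.
#' @return Integer lobe count (>= 1), `NA` for an empty mask.
#' @export
lobe_count <- function(mask, weights, prominence_frac = 0.2,
                       smooth_sigma = 1.5, n_levels = 24) {
  if (!any(mask)) return(NA_integer_)
  stopifnot(prominence_frac > 0, prominence_frac < 1)
  bb <- mask_bbox(mask, pad = 2L)
  mask <- mask[bb$r, bb$c, drop = FALSE]
  w <- weights[bb$r, bb$c, drop = FALSE]
  w[!mask] <- 0
  sm <- gauss_blur(w, smooth_sigma)
  sm[!mask] <- 0
  # deterministic tie-break so plateaus yield a single maximum
  nr <- nrow(sm); nc <- ncol(sm)
  eps <- max(sm) * 1e-9
  sm <- sm + eps * matrix(seq_len(nr * nc), nr, nc)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  is_max <- mask & sm > 0
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dx):(nr + 1 + dx), (2 + dy):(nc + 1 + dy)]
    is_max <- is_max & (sm >= nb)
  }
  peaks <- which(is_max)
  if (length(peaks) <= 1) return(1L)
  h <- sm[peaks]
  ord <- order(h, decreasing = TRUE)
  peaks <- peaks[ord]; h <- h[ord]
  gmax <- h[1]
  # level sweep: a peak's saddle is the highest level at which its connected
  # component (of the upper level set) also contains a higher peak
  in_vals <- sm[mask]
  levels <- seq(gmax, min(in_vals), length.out = n_levels + 1)[-1]
  saddle <- rep(NA_real_, length(peaks))
  for (L in levels) {
    if (!anyNA(saddle[-1])) break
    lab <- EBImage::bwlabel((sm >= L & mask) * 1)
    lab <- round(as.numeric(EBImage::imageData(lab)))
    pl <- lab[peaks]
    for (k in seq_along(peaks)[-1]) {
      if (!is.na(saddle[k]) || h[k] < L) next
      if (any(pl[seq_len(k - 1)] == pl[k] & h[seq_len(k - 1)] > h[k])) {
        saddle[k] <- L
      }
    }
  }
  saddle[is.na(saddle)] <- min(in_vals)
  prom <- h - saddle
  prom[1] <- gmax   # the global peak always counts
  as.integer(sum(prom > prominence_frac * gmax))
}
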