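#' Gray-level co-occurrence matrix over a mask
#'
#' In-mask intensities are quantised to `levels` equal-width bins between the
#' in-mask minimum and maximum (per event, so texture is contrast-invariant
#' to overall staining intensity). Co-occurrence counts are accumulated
#' symmetrically over all pixel pairs whose both members lie in the mask, for
#' each of the given offsets (default: the four unit offsets at 0, 45, 90 and
#' 135 degrees, averaged into one matrix), and normalised to sum 1.
#'
#' A constant in-mask intensity puts all mass on one diagonal entry; this is
#' valid input for [haralick_features()], not an error.
#'
#' @param image An [event_image()].
#' @param channel Channel name.
#' @param mask Logical matrix with at least 2 pixels.
#' @param levels Number of gray levels (>= 2, default 32).
#' @param offsets List of integer `c(dx, dy)` pixel displacements.
#' @return A `levels` x `levels` matrix summing to 1.
#' @export
glcm <- function(image, channel, mask, levels = 32,
                 offsets = list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))) {
  stopifnot(levels >= 2)
  if (sum(mask) < 2) abort("mask must contain at least 2 pixels")
  x <- get_channel(image, channel)
  v <- x[mask]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    q <- mask * 1L   # constant: everything in the first bin
  } else {
    q <- matrix(0L, nrow(x), ncol(x))
    q[mask] <- pmin(levels, 1L + as.integer((x[mask] - rng[1]) /
                                              (rng[2] - rng[1]) * levels))
  }
  bb <- mask_bbox(mask, pad = 1L)
  counts <- glcm_counts(q[bb$r, bb$c, drop = FALSE], levels, offsets)
  tot <- sum(counts)
  if (tot == 0) abort("no co-occurring in-mask pixel pairs for the given offsets")
  matrix(counts / tot, levels, levels)
}

#' Haralick texture features of a normalised co-occurrence matrix
#'
#' Computes the six second-order texture statistics used for the cytoplasmic
#' compartment: contrast, correlation, energy, entropy (base-2 logarithm),
#' homogeneity and variance. Contrast, energy and variance quantify intensity
#' variation; correlation, entropy and homogeneity quantify uniformity of the
#' granularity.
#'
#' @param P Square non-negative matrix summing to 1 (see [glcm()]).
#' @param tol Tolerance on the normalisation check.
#' @return A tibble with one row and columns `contrast`, `correlation`,
#'   `energy`, `entropy`, `homogeneity`, `variance`. Correlation is the `NA`
#'   marker when either marginal SD is zero (e.g. a constant texture).
#' @export
haralick_features <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0)) {
    abort("P must be a square non-negative matrix")
  }
  if (abs(sum(P) - 1) > tol) {
    abort("P is not normalised: entries must sum to 1")
  }
  as_tibble(as.list(haralick_vec(P)))
}
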