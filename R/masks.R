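#' Default channel mask: global bimodal threshold, largest connected component
#'
#' Reproduces the behaviour of per-channel default masks: a global automatic
#' (Otsu-style) threshold splits the raster into foreground and background and
#' the largest 8-connected foreground component is kept. For brightfield
#' images the cell is *darker* than the illuminated background, so the
#' foreground polarity is selectable.
#'
#' @param image An [event_image()].
#' @param channel Channel name to threshold.
#' @param method Threshold method; only `"otsu"` (automatic bimodal split)
#'   is implemented.
#' @param foreground `"bright"` if the object is brighter than background
#'   (fluorescence), `"dark"` if darker (brightfield).
#' @return A logical matrix (the mask); all `FALSE` when no pixel passes.
#' @export
default_mask <- function(image, channel, method = "otsu",
                         foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  method <- match.arg(method, "otsu")
  largest_component(threshold_mask(image, channel, foreground))
}

# Global bimodal threshold without the largest-component step. The split is
# computed on log intensities: fluorescence images have a near-zero
# background and a bright-tailed object, and the log histogram puts the
# threshold in the background/object valley instead of halfway into the
# object's own bright structures.
threshold_mask <- function(image, channel, foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  x <- get_channel(image, channel)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # constant raster: no bimodal split, nothing exceeds threshold
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  lx <- log1p(x)
  th <- otsu_threshold(lx)
  if (foreground == "bright") lx > th else lx < th
}

# Otsu's between-class variance maximiser on a 256-bin histogram.
otsu_threshold <- function(x) {
  rng <- range(x)
  n_bins <- 256L
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - rng[1]) / (rng[2] - rng[1]) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * (rng[2] - rng[1])
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

# keep the largest 8-connected component of a logical matrix
largest_component <- function(m) {
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  lab <- round(as.numeric(EBImage::imageData(lab)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  matrix(lab == keep, nrow(m), ncol(m))
}

#' Morphological erosion of a mask with a disc structuring element
#'
#' `radius = 0` is the identity. Erosion shrinks the mask so that the eroded
#' region better fits the object interior (the masks used throughout the
#' analysis are the eroded cell mask M01 and eroded nuclear mask M12).
#'
#' @param mask Logical matrix.
#' @param radius Non-negative integer disc radius in pixels.
#' @return Logical matrix of the same shape.
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(is.matrix(mask))
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0) {
    abort("`radius` must be a single non-negative number.")
  }
  radius <- as.integer(radius)
  if (radius == 0L || !any(mask)) return(mask & TRUE)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- EBImage::erode(mask * 1, brush)
  matrix(as.numeric(EBImage::imageData(out)) > 0.5, nrow(mask), ncol(mask))
}

#' Pixelwise Boolean combination of two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @param op One of `"and"`, `"or"`, `"minus"` (pixels of `a` not in `b`)
#'   or `"not_b_and_a"` (alias of `"minus"`, the Boolean form used when
#'   combining gates).
#' @return Logical matrix.
#' @export
mask_algebra <- function(a, b, op = c("and", "or", "minus", "not_b_and_a")) {
  op <- match.arg(op)
  if (!identical(dim(a), dim(b))) {
    abort("mask shapes differ; masks must be aligned to the same event image.")
  }
  switch(op,
    and = a & b,
    or = a | b,
    minus = a & !b,
    not_b_and_a = !b & a
  )
}

#' Physical area of a mask
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Micrometres per pixel side (> 0).
#' @return Area in square micrometres.
#' @export
mask_area <- function(mask, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be positive.")
  }
  sum(mask) * pixel_size_um^2
}

#' Build the per-event mask set (cell, nucleus, cytoplasm)
#'
#' The cell mask is the eroded default brightfield mask (M01), the nuclear
#' mask the eroded default DRAQ5 mask (M12) restricted to the cell, and the
#' cytoplasm mask is cell MINUS nucleus, so the cell area decomposes exactly
#' into nuclear plus cytoplasmic area.
#'
#' @param image An [event_image()].
#' @param layout A [channel_layout()].
#' @param erode_cell,erode_nucleus Disc erosion radii in pixels for the
#'   brightfield and DRAQ5 masks.
#' @return An object of class `mask_set`: list with logical matrices
#'   `cell`, `nucleus`, `cytoplasm`, plus `cell_default` (the un-eroded
#'   brightfield mask, whose sharp boundary carries the focus information
#'   used by the gradient-RMS QC feature).
#' @export
build_masks <- function(image, layout, erode_cell = 2, erode_nucleus = 1) {
  cell_default <- default_mask(image, layout$brightfield, foreground = "dark")
  cell <- erode_mask(cell_default, erode_cell)
  # the nuclear mask keeps every thresholded DRAQ5 component inside the
  # cell (not only the largest), so both lobes of a bilobed/binucleated
  # nucleus stay in the mask
  nucleus <- threshold_mask(image, layout$draq5, foreground = "bright")
  nucleus <- erode_mask(nucleus, erode_nucleus)
  nucleus <- mask_algebra(nucleus, cell, "and")
  cytoplasm <- mask_algebra(cell, nucleus, "minus")
  structure(list(cell = cell, nucleus = nucleus, cytoplasm = cytoplasm,
                 cell_default = cell_default),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat("<mask_set> cell:", sum(x$cell), "px  nucleus:", sum(x$nucleus),
      "px  cytoplasm:", sum(x$cytoplasm), "px\n")
  invisible(x)
}
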