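#' Parameters of mask construction and feature extraction
#'
#' Bundles every tunable of the mask/feature stage. Defaults: 2 px erosion
#' of the brightfield cell mask and 1 px of the nuclear mask (modest
#' shrinkage so eroded masks hug the object), 32 gray levels with the four
#' unit offsets for the co-occurrence matrix, a 3 px disc for bright detail
#' intensity, and a 25% prominence fraction for lobe counting.
#'
#' @param erode_cell,erode_nucleus Disc erosion radii (px).
#' @param glcm_levels Gray levels for the co-occurrence matrix.
#' @param bdi_radius Disc radius (px) of the bright-detail opening.
#' @param lobe_prominence Prominence fraction for [lobe_count()].
#' @param lobe_smooth_sigma Gaussian sigma (px) for lobe-count smoothing.
#' @param circularity_cap Cap for [circularity()].
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(erode_cell = 2, erode_nucleus = 1,
                           glcm_levels = 32, bdi_radius = 3,
                           lobe_prominence = 0.25, lobe_smooth_sigma = 1.8,
                           circularity_cap = 100) {
  structure(list(erode_cell = erode_cell, erode_nucleus = erode_nucleus,
                 glcm_levels = glcm_levels, bdi_radius = bdi_radius,
                 lobe_prominence = lobe_prominence,
                 lobe_smooth_sigma = lobe_smooth_sigma,
                 circularity_cap = circularity_cap),
            class = "feature_config")
}

feature_names <- function() {
  c("cell_area_um2", "nuclear_area_um2", "cyto_area_um2",
    "aspect_ratio_cell", "ari_draq5", "gradient_rms_bf",
    "circularity_cell", "circularity_nuc", "compactness_nuc",
    "symmetry2_nuc", "lobe_count", "bdi_draq5", "draq5_total",
    "cd36", "cd71", "cd45", "cd105", "cd117",
    "cyto_contrast", "cyto_correlation", "cyto_energy", "cyto_entropy",
    "cyto_homogeneity", "cyto_variance",
    "condensation_ratio", "nc_ratio", "centroid_x", "centroid_y")
}

# core numeric extraction; returns a named numeric vector (NA-filled when the
# event is unanalyzable, i.e. no usable cell or nuclear mask)
extract_core <- function(image, layout, config) {
  out <- setNames(rep(na_marker(), length(feature_names()) + 1L),
                  c(feature_names(), "analyzable"))
  out["analyzable"] <- 0
  for (ch in c(layout$brightfield, layout$draq5)) {
    get_channel(image, ch)  # errors early if a required channel is missing
  }
  masks <- build_masks(image, layout,
                       erode_cell = config$erode_cell,
                       erode_nucleus = config$erode_nucleus)
  px <- image$pixel_size_um
  if (!any(masks$cell) || !any(masks$nucleus)) return(out)
  out["analyzable"] <- 1
  bf <- layout$brightfield
  dq <- layout$draq5
  draq <- get_channel(image, dq)

  out["cell_area_um2"] <- mask_area(masks$cell, px)
  out["nuclear_area_um2"] <- mask_area(masks$nucleus, px)
  out["cyto_area_um2"] <- mask_area(masks$cytoplasm, px)
  out["aspect_ratio_cell"] <- aspect_ratio(masks$cell)
  out["ari_draq5"] <- aspect_ratio(masks$nucleus, draq)
  out["gradient_rms_bf"] <- gradient_rms(image, bf, masks$cell_default)
  out["circularity_cell"] <- circularity(masks$cell, cap = config$circularity_cap)
  out["circularity_nuc"] <- circularity(masks$nucleus, cap = config$circularity_cap)
  out["compactness_nuc"] <- compactness(masks$nucleus, draq)
  out["symmetry2_nuc"] <- symmetry2(masks$nucleus, draq)
  out["lobe_count"] <- lobe_count(masks$nucleus, draq,
                                  prominence_frac = config$lobe_prominence,
                                  smooth_sigma = config$lobe_smooth_sigma)
  out["bdi_draq5"] <- bright_detail_intensity(image, dq, masks$nucleus,
                                              radius = config$bdi_radius)
  st <- intensity_stats(image, dq, masks$nucleus)
  out["draq5_total"] <- st$total
  for (mk in names(layout$markers)) {
    ch <- layout$markers[[mk]]
    if (ch %in% names(image$channels)) {
      out[mk] <- sum(image$channels[[ch]][masks$cell])
    }
  }
  if (sum(masks$cytoplasm) >= 8) {
    # a fragmented cytoplasm ring can lack co-occurring pixel pairs; such
    # events keep NA texture instead of aborting the batch
    P <- tryCatch(glcm(image, bf, masks$cytoplasm, levels = config$glcm_levels),
                  error = function(e) NULL)
    if (!is.null(P)) {
    hl <- haralick_vec(P)
    out["cyto_contrast"] <- hl[["contrast"]]
    out["cyto_correlation"] <- hl[["correlation"]]
    out["cyto_energy"] <- hl[["energy"]]
    out["cyto_entropy"] <- hl[["entropy"]]
    out["cyto_homogeneity"] <- hl[["homogeneity"]]
    out["cyto_variance"] <- hl[["variance"]]
    }
  }
  if (out["nuclear_area_um2"] > 0) {
    out["condensation_ratio"] <- out["bdi_draq5"] / out["nuclear_area_um2"]
  }
  if (out["cyto_area_um2"] > 0) {
    out["nc_ratio"] <- out["nuclear_area_um2"] / out["cyto_area_um2"]
  }
  cm <- mask_moments(masks$cell)
  out["centroid_x"] <- cm$cx
  out["centroid_y"] <- cm$cy
  out
}

#' Extract the full morphometric feature vector of one event
#'
#' Builds the mask set (eroded brightfield cell mask, eroded DRAQ5 nuclear
#' mask restricted to the cell, cytoplasm = cell minus nucleus) and computes
#' every feature used downstream: physical areas, cell aspect ratio, DRAQ5
#' aspect ratio intensity, brightfield focus score, nuclear shape scores,
#' lobe count, bright detail intensity and total DRAQ5, marker intensity
#' sums, Haralick texture of the cytoplasmic brightfield, the nuclear
#' condensation ratio (bright detail intensity per square micrometre of
#' nucleus) and the nuclear:cytoplasmic area ratio.
#'
#' Events with no usable cell or nuclear mask (e.g. no DRAQ5 signal) are
#' flagged `analyzable = FALSE` with `NA` features rather than erroring.
#'
#' @param image An [event_image()].
#' @param layout A [channel_layout()].
#' @param config A [feature_config()].
#' @return A one-row tibble.
#' @export
extract_features <- function(image, layout = channel_layout(),
                             config = feature_config()) {
  v <- extract_core(image, layout, config)
  out <- as_tibble(as.list(v[feature_names()]))
  out$lobe_count <- as.integer(out$lobe_count)
  tibble(event_id = image$event_id, sample_id = image$sample_id,
         analyzable = v[["analyzable"]] > 0) %>%
    dplyr::bind_cols(out)
}

#' Extract features for a batch of events
#'
#' @param events List of [event_image()] objects.
#' @param layout A [channel_layout()].
#' @param config A [feature_config()].
#' @return A tibble with one row per event (see [extract_features()]).
#' @export
compute_features <- function(events, layout = channel_layout(),
                             config = feature_config()) {
  rows <- purrr::map(events, function(ev) extract_core(ev, layout, config))
  mat <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(mat))
  out$lobe_count <- as.integer(out$lobe_count)
  dplyr::bind_cols(
    tibble(event_id = purrr::map_chr(events, "event_id"),
           sample_id = purrr::map_chr(events, "sample_id"),
           analyzable = out$analyzable > 0),
    out %>% select(-"analyzable")
  )
}
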