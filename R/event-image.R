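#' Single acquired event: aligned per-channel image rasters
#'
#' An `event_image` holds the aligned 2-D intensity rasters of one imaging
#' flow cytometry event (one cell passing the camera), one raster per
#' acquisition channel, together with the physical pixel scale and
#' identifiers. All rasters must share the same dimensions and contain
#' finite, non-negative intensities.
#'
#' @param channels Named list of numeric matrices, one per channel. All
#'   matrices must have identical dimensions.
#' @param event_id,sample_id Identifier strings.
#' @param pixel_size_um Physical size of one pixel side in micrometres
#'   (default 0.33, the 60x magnification scale).
#' @return An object of class `event_image`.
#' @export
event_image <- function(channels, event_id = "event", sample_id = "sample",
                        pixel_size_um = 0.33) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a named list of matrices.")
  }
  dims <- lapply(channels, dim)
  d1 <- dims[[1]]
  ok <- vapply(channels, function(m) {
    is.matrix(m) && is.numeric(m) && identical(dim(m), d1) &&
      all(is.finite(m)) && all(m >= 0)
  }, logical(1))
  if (!all(ok)) {
    abort(paste0("invalid channel raster(s): ",
                 paste(names(channels)[!ok], collapse = ", "),
                 " (need equal-size finite non-negative matrices)"))
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  structure(
    list(event_id = as.character(event_id),
         sample_id = as.character(sample_id),
         channels = channels,
         pixel_size_um = pixel_size_um,
         width = d1[1], height = d1[2]),
    class = "event_image"
  )
}

#' @export
print.event_image <- function(x, ...) {
  cat("<event_image> ", x$sample_id, "/", x$event_id, "  ",
      x$width, "x", x$height, " px (", x$pixel_size_um, " um/px)\n", sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

get_channel <- function(image, channel) {
  stopifnot(inherits(image, "event_image"))
  if (!channel %in% names(image$channels)) {
    abort(paste0("unknown channel '", channel, "'; available: ",
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

#' Channel layout: map acquisition channels to biological markers
#'
#' Describes which channel raster holds the brightfield image, which holds
#' the DNA dye (DRAQ5), and which hold the immunophenotypic markers, plus
#' the pixel scale. Written/read as a plain YAML sidecar next to an event
#' store.
#'
#' @param brightfield,draq5 Channel names for the brightfield and DNA-dye
#'   images.
#' @param markers Named character vector mapping marker keys
#'   (`cd36`, `cd71`, `cd45`, `cd105`, `cd117`) to channel names.
#' @param pixel_size_um Micrometres per pixel side.
#' @return An object of class `channel_layout`.
#' @export
channel_layout <- function(brightfield = "BF",
                           draq5 = "DRAQ5",
                           markers = c(cd36 = "CD36", cd71 = "CD71",
                                       cd45 = "CD45", cd105 = "CD105",
                                       cd117 = "CD117"),
                           pixel_size_um = 0.33) {
  structure(
    list(brightfield = brightfield, draq5 = draq5,
         markers = markers, pixel_size_um = pixel_size_um),
    class = "channel_layout"
  )
}

#' Read or write a channel-layout sidecar
#'
#' @param layout A [channel_layout()].
#' @param path File path of the YAML sidecar.
#' @return `read_channel_layout()` returns a [channel_layout()];
#'   `write_channel_layout()` returns `path` invisibly.
#' @export
write_channel_layout <- function(layout, path) {
  stopifnot(inherits(layout, "channel_layout"))
  yaml::write_yaml(list(
    brightfield = layout$brightfield,
    draq5 = layout$draq5,
    markers = as.list(layout$markers),
    pixel_size_um = layout$pixel_size_um
  ), path)
  invisible(path)
}

#' @rdname write_channel_layout
#' @export
read_channel_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("channel layout sidecar not found: ", path))
  y <- yaml::read_yaml(path)
  channel_layout(
    brightfield = y$brightfield,
    draq5 = y$draq5,
    markers = unlist(y$markers),
    pixel_size_um = as.numeric(y$pixel_size_um)
  )
}
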