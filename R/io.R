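# Event-store and table IO. One event = one multi-page 32-bit TIFF (one
# page per channel, in canonical layout order); intensities are stored
# divided by a fixed 2^20 scale, so the round-trip is exact to 2^-32 of the
# scale (about 2e-4 intensity units), far below the render noise floor.

store_scale <- function() 2^20

canonical_channels <- function(layout) {
  c(layout$brightfield, layout$draq5,
    layout$markers[c("cd36", "cd71", "cd45", "cd105", "cd117")])
}

write_event_tiff <- function(event, path) {
  chs <- event$channels
  if (any(vapply(chs, max, numeric(1)) > store_scale())) {
    abort("channel intensity exceeds the fixed store scale")
  }
  pages <- lapply(chs, function(m) m / store_scale())
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' Load events from an on-disk event store
#'
#' Reads the store layout written by [simulate_cohort()]:
#' `<store>/<group>/<sample_id>/<event_id>.tiff` multi-page TIFFs plus a
#' `channels.yaml` sidecar. Events are returned in stable order (sample
#' directory, then event file name).
#'
#' @param store Store directory.
#' @param layout Optional [channel_layout()]; read from the sidecar when
#'   `NULL`.
#' @param lenient If `TRUE`, unreadable files are skipped with a warning
#'   instead of aborting the whole load.
#' @return List of [event_image()] objects (empty, with a warning, for an
#'   empty store).
#' @export
load_events <- function(store, layout = NULL, lenient = FALSE) {
  if (!dir.exists(store)) abort(paste0("event store not found: ", store))
  if (is.null(layout)) layout <- read_channel_layout(file.path(store, "channels.yaml"))
  ch_names <- canonical_channels(layout)
  files <- sort(list.files(store, pattern = "\\.tiff?$", recursive = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) {
    warn("event store contains no event files")
    return(list())
  }
  out <- vector("list", length(files))
  keep <- logical(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    pages <- tryCatch(tiff::readTIFF(f, all = TRUE),
                      error = function(e) e)
    if (inherits(pages, "error")) {
      if (lenient) {
        warn(paste0("skipping unreadable event file: ", f))
        next
      }
      abort(paste0("unreadable event file: ", f))
    }
    if (length(pages) != length(ch_names)) {
      abort(paste0("channel count mismatch in ", f, ": expected ",
                   length(ch_names), " pages, found ", length(pages)))
    }
    chans <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      matrix(as.numeric(p), nrow(p), ncol(p)) * store_scale()
    })
    names(chans) <- ch_names
    parts <- strsplit(f, .Platform$file.sep, fixed = TRUE)[[1]]
    out[[i]] <- event_image(
      chans,
      event_id = sub("\\.tiff?$", "", parts[length(parts)]),
      sample_id = parts[length(parts) - 1],
      pixel_size_um = layout$pixel_size_um
    )
    keep[i] <- TRUE
  }
  out[keep]
}

#' Read or write a feature table as CSV
#'
#' Comma-separated, UTF-8, mandatory header; missing values are empty cells.
#'
#' @param features A tibble.
#' @param path File path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns a tibble.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Export a numeric feature table as an FCS 3.1 file
#'
#' Writes one FCS parameter per column (32-bit floats, list mode, little
#' endian) so the feature battery can be inspected in conventional flow
#' cytometry software. Missing values are encoded as the sentinel stored in
#' the custom TEXT keyword `ERYMORPH_NA_SENTINEL`.
#'
#' @param features Tibble/data frame with at least one row; all columns must
#'   be numeric.
#' @param path Output file path.
#' @param na_sentinel Numeric value substituted for missing entries.
#' @return `path`, invisibly.
#' @export
export_fcs <- function(features, path, na_sentinel = -1e6) {
  df <- as.data.frame(features)
  if (ncol(df) == 0 || nrow(df) == 0) {
    abort("FCS export needs at least one parameter and one event")
  }
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    abort(paste0("non-numeric column(s): ",
                 paste(names(df)[!num], collapse = ", ")))
  }
  mat <- as.matrix(df)
  mat[is.na(mat)] <- na_sentinel
  n_par <- ncol(mat); n_tot <- nrow(mat)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
    "$TOT" = as.character(n_tot),
    "ERYMORPH_NA_SENTINEL" = format(na_sentinel, scientific = FALSE)
  )
  for (j in seq_len(n_par)) {
    rng <- max(abs(mat[, j]), 1)
    kw[sprintf("$P%dN", j)] <- colnames(mat)[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(ceiling(rng), scientific = FALSE)
  }
  build_text <- function(kw) {
    paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))
  }
  text_start <- 256L
  # fixed-width data offsets avoid the classic chicken-and-egg with the
  # TEXT segment length
  txt <- build_text(kw)
  text_end <- text_start + nchar(txt) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  txt <- build_text(kw)
  stopifnot(nchar(txt) == text_end - text_start + 1L)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_start, text_end,
                    if (data_end <= 99999999) data_start else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(raw(text_start - nchar(header)), con)
  writeChar(txt, con, eos = NULL)
  # list mode: parameters within event, events consecutive
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
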