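## Disk formats: multi-page TIFF for images (one page per channel, page
## order = channel order, names in a plain-text sidecar since baseline
## TIFF writers do not carry per-page descriptions), label-mask TIFF, and
## CSV truth tables. Counts are stored as 16-bit samples (0..65535);
## integer counts round-trip exactly, sub-integer noise is quantized to
## 1 count.

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel in channel order; channel names are written to a
#' `<path>.channels.txt` sidecar (one name per line) that the reader
#' picks up automatically.
#'
#' @param image a [multichannel_image()].
#' @param path output file.
#' @param max_count full-scale count value mapped to 16-bit white.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(image, path, max_count = 65535) {
  stopifnot(inherits(image, "multichannel_image"))
  pages <- lapply(names(image$channels), function(nm)
    pmin(pmax(image$channels[[nm]], 0), max_count) / max_count)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  writeLines(names(image$channels), paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read a multi-page TIFF as a multi-channel image
#'
#' Channel names come from `channel_names`, else from the
#' `<path>.channels.txt` sidecar when present, else `channel1`,
#' `channel2`, ...
#'
#' @param path TIFF file.
#' @param channel_names optional character vector, one name per page.
#' @param pixel_size micrometers per pixel to record.
#' @param max_count full-scale count value (must match the writer).
#' @return a [multichannel_image()].
#' @export
read_multichannel_tiff <- function(path, channel_names = NULL,
                                   pixel_size = 0.2, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".channels.txt")
  if (is.null(channel_names) && file.exists(sidecar))
    channel_names <- readLines(sidecar)
  if (is.null(channel_names))
    channel_names <- paste0("channel", seq_along(pages))
  if (length(channel_names) != length(pages))
    stop("need one channel name per TIFF page (got ",
         length(channel_names), " names for ", length(pages), " pages)")
  channels <- lapply(pages, function(p) round(p * max_count))
  names(channels) <- channel_names
  multichannel_image(channels, pixel_size = pixel_size,
                     metadata = list(source = path))
}

#' Write / read an integer label mask as TIFF
#'
#' Labels are stored as 16-bit samples, exact up to 65535 cells.
#'
#' @param labels integer label matrix.
#' @param path file path.
#' @return the path (write) or the label matrix (read).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a generated scene to a directory
#'
#' Emits `image.tif` (multi-page, channel names in page metadata),
#' `cell_labels.tif`, `membrane_labels.tif`, `nucleus_labels.tif`, and
#' `truth_cells.csv` / `truth_channels.csv` (one row per cell, resp. per
#' cell x channel, of planted parameters and true geometry).
#'
#' @param scene `list(image, truth)` from [generate_scene()].
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, "image.tif"),
             cells = file.path(dir, "cell_labels.tif"),
             membrane = file.path(dir, "membrane_labels.tif"),
             nucleus = file.path(dir, "nucleus_labels.tif"),
             truth_cells = file.path(dir, "truth_cells.csv"),
             truth_channels = file.path(dir, "truth_channels.csv"))
  write_multichannel_tiff(scene$image, paths["image"])
  write_label_tiff(scene$truth$cell_labels, paths["cells"])
  write_label_tiff(scene$truth$membrane_labels, paths["membrane"])
  write_label_tiff(scene$truth$nucleus_labels, paths["nucleus"])
  utils::write.csv(scene$truth$cells, paths["truth_cells"],
                   row.names = FALSE)
  utils::write.csv(scene$truth$channels, paths["truth_channels"],
                   row.names = FALSE)
  invisible(paths)
}

#' Median filter for figure export only
#'
#' Radius-1 (3x3) median smoothing as conventionally applied to
#' micrographs for presentation. It is deliberately not part of any
#' quantification path: every metric in this package is computed on
#' unfiltered, background-subtracted counts.
#'
#' @param x intensity matrix.
#' @return filtered matrix (edges use the truncated window).
#' @export
presentation_median_filter <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (r in seq_len(nr)) {
    rs <- max(1, r - 1):min(nr, r + 1)
    for (c in seq_len(nc)) {
      cs <- max(1, c - 1):min(nc, c + 1)
      out[r, c] <- stats::median(x[rs, cs])
    }
  }
  out
}
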