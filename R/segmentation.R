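#' Per-cell segmentation into cell, membrane and nucleus masks
#'
#' The coordinate frame for all per-cell metrics: an integer label matrix
#' for whole cells (0 = background, k = cell k) plus per-cell membrane-ring
#' and nucleus masks stored as label matrices with the same labels.
#'
#' Invariants (checked by [validate_segmentation()]): membrane(k) and
#' nucleus(k) are subsets of cell(k); membrane(k) and nucleus(k) are
#' disjoint; cell masks of distinct labels are disjoint.
#'
#' @param cell_labels integer label matrix (0 background).
#' @param membrane_labels,nucleus_labels label matrices using the same
#'   labels as `cell_labels`.
#' @param ring_width membrane ring width in pixels.
#' @param dapi_threshold DAPI count threshold that defined the nuclei.
#' @param element structuring-element shape used for the ring
#'   (`"box"` or `"disc"`).
#' @param provenance how the masks were made (e.g. "truth", "derived",
#'   "manual polygons").
#' @param flags data.frame with columns `cell_id`, `empty_nucleus`
#'   (logical): cells whose nucleus mask came out empty.
#' @return object of class `cell_segmentation`.
#' @export
cell_segmentation <- function(cell_labels, membrane_labels, nucleus_labels,
                              ring_width = NA_integer_,
                              dapi_threshold = NA_real_,
                              element = NA_character_,
                              provenance = "unknown",
                              flags = NULL) {
  stopifnot(is.matrix(cell_labels),
            identical(dim(cell_labels), dim(membrane_labels)),
            identical(dim(cell_labels), dim(nucleus_labels)))
  ids <- cell_ids(cell_labels)
  if (is.null(flags))
    flags <- data.frame(cell_id = ids,
                        empty_nucleus = vapply(ids, function(k)
                          !any(nucleus_labels == k), logical(1)))
  seg <- structure(
    list(cell_labels = cell_labels, membrane_labels = membrane_labels,
         nucleus_labels = nucleus_labels, ring_width = ring_width,
         dapi_threshold = dapi_threshold, element = element,
         provenance = provenance, flags = flags),
    class = "cell_segmentation"
  )
  validate_segmentation(seg)
  seg
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("<cell_segmentation> ", length(cell_ids(x$cell_labels)), " cells, ",
      "ring width ", x$ring_width, " px (", x$element, "), DAPI > ",
      x$dapi_threshold, " cts, provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Labels present in a label matrix
#' @param labels integer label matrix.
#' @return sorted integer vector of nonzero labels.
#' @export
cell_ids <- function(labels) sort(unique(labels[labels > 0]))

#' Assert the mask-algebra invariants of a segmentation
#'
#' Checks, for every cell: membrane subset of cell, nucleus subset of cell,
#' membrane and nucleus disjoint. Called on construction and by the
#' pipeline on every run.
#'
#' @param seg a [cell_segmentation()].
#' @return `seg`, invisibly; stops on violation.
#' @export
validate_segmentation <- function(seg) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cl <- seg$cell_labels; ml <- seg$membrane_labels; nl <- seg$nucleus_labels
  if (any(ml > 0 & ml != cl))
    stop("membrane mask escapes its cell mask")
  if (any(nl > 0 & nl != cl))
    stop("nucleus mask escapes its cell mask")
  if (any(ml > 0 & nl > 0))
    stop("membrane and nucleus masks overlap")
  invisible(seg)
}

## ---- outlines -> label mask -------------------------------------------

# even-odd (ray casting) point-in-polygon via mgcv; x = column coordinate,
# y = row coordinate, both 0-based with pixel centers at half-integers.
rasterize_polygon <- function(xs, ys, dim) {
  h <- dim[1]; w <- dim[2]
  xmin <- max(1L, floor(min(xs)) + 1L); xmax <- min(w, ceiling(max(xs)))
  ymin <- max(1L, floor(min(ys)) + 1L); ymax <- min(h, ceiling(max(ys)))
  if (xmin > xmax || ymin > ymax) return(NULL)
  cols <- xmin:xmax; rows <- ymin:ymax
  centers <- cbind(rep(cols - 0.5, each = length(rows)),
                   rep(rows - 0.5, times = length(cols)))
  inside <- mgcv::in.out(cbind(c(xs, xs[1]), c(ys, ys[1])), centers)
  idx <- which(inside)
  if (length(idx) == 0L) return(NULL)
  cbind(row = rep(rows, times = length(cols))[idx],
        col = rep(cols, each = length(rows))[idx])
}

segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

is_self_intersecting <- function(xs, ys) {
  n <- length(xs)
  p <- cbind(xs, ys)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (segments_cross(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Build a cell label mask from outlines
#'
#' Accepts either a ready-made integer label matrix (passed through after
#' validation) or a polygon table with one vertex per row. Polygons are
#' pixelized by center sampling: a pixel belongs to a cell when its center
#' lies inside the polygon. Coordinates are 0-based pixel units with
#' `x` = column and `y` = row, so the pixel at matrix position (r, c) has
#' its center at (c - 0.5, r - 0.5).
#'
#' @param source integer label matrix, or data.frame with columns
#'   `cell_id`, `x`, `y` (ordered vertices per cell; polygons closed
#'   implicitly).
#' @param dim image dimensions `c(rows, cols)`; required for polygons.
#' @return integer label matrix.
#' @export
load_cell_outlines <- function(source, dim = NULL) {
  if (is.matrix(source)) {
    if (any(source < 0) || any(source != round(source)))
      stop("label mask must contain non-negative integers")
    return(matrix(as.integer(source), nrow(source), ncol(source)))
  }
  if (!is.data.frame(source) ||
      !all(c("cell_id", "x", "y") %in% names(source)))
    stop("'source' must be a label matrix or a data.frame with cell_id, x, y")
  if (is.null(dim) || length(dim) != 2L)
    stop("'dim' (rows, cols) is required when rasterizing polygons")
  labels <- matrix(0L, dim[1], dim[2])
  for (k in sort(unique(source$cell_id))) {
    v <- source[source$cell_id == k, , drop = FALSE]
    if (nrow(v) < 3L) stop("cell ", k, ": polygon needs >= 3 vertices")
    if (is_self_intersecting(v$x, v$y))
      stop("cell ", k, ": polygon is self-intersecting")
    px <- rasterize_polygon(v$x, v$y, dim)
    if (is.null(px)) stop("cell ", k, ": polygon covers no pixel centers")
    idx <- px[, "row"] + (px[, "col"] - 1L) * dim[1]
    if (any(labels[idx] != 0L))
      stop("cell ", k, " overlaps cell ", labels[idx][labels[idx] != 0L][1],
           ": outlined cells must be disjoint")
    labels[idx] <- as.integer(k)
  }
  labels
}

## ---- membrane ring ----------------------------------------------------

#' Derive per-cell membrane-ring masks by erosion
#'
#' The membrane compartment of cell k is defined reproducibly as
#' cell_mask(k) minus its morphological erosion by a structuring element of
#' radius `ring_width` (box by default, disc optional). Cells too thin to
#' survive the erosion become all-membrane; their labels are reported in
#' the `"thin_cells"` attribute so the nucleus mask can be forced empty.
#'
#' @param cell_labels integer label matrix.
#' @param ring_width ring width in pixels (>= 1).
#' @param element structuring element shape: `"box"` or `"disc"`.
#' @return membrane label matrix with attribute `thin_cells`.
#' @export
derive_membrane_ring <- function(cell_labels, ring_width = 3L,
                                 element = c("box", "disc")) {
  element <- match.arg(element)
  if (!is.numeric(ring_width) || ring_width < 1)
    stop("'ring_width' must be >= 1")
  ring_width <- as.integer(ring_width)
  brush <- EBImage::makeBrush(2L * ring_width + 1L, shape = element)
  membrane <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  thin <- integer(0)
  for (k in cell_ids(cell_labels)) {
    bb <- mask_bbox(cell_labels == k, pad = ring_width + 1L,
                    dim = dim(cell_labels))
    sub <- cell_labels[bb$rows, bb$cols] == k
    core <- EBImage::erode(sub * 1, brush) > 0
    ring <- sub & !core
    if (!any(core)) thin <- c(thin, k)
    membrane[bb$rows, bb$cols][ring] <- k
  }
  attr(membrane, "thin_cells") <- thin
  membrane
}

# bounding box of a logical mask, padded and clipped to the image
mask_bbox <- function(mask, pad, dim) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(dim[1], max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(dim[2], max(idx[, 2]) + pad)
  list(rows = r0:r1, cols = c0:c1)
}

## ---- nucleus from DAPI ------------------------------------------------

#' Define per-cell nuclei by thresholding the DAPI channel
#'
#' Within each cell, the nucleus is the set of pixels whose DAPI signal is
#' strictly greater than `threshold` counts, minus any membrane-ring pixels
#' (to keep the compartments disjoint), reduced to its largest connected
#' component (4-connected) so each cell carries at most one nucleus. Cells
#' whose nucleus comes out empty are flagged with a warning, not an error:
#' their nucleus-based metrics are reported missing downstream.
#'
#' @param dapi DAPI intensity matrix (raw or background-subtracted; record
#'   which in the segmentation provenance).
#' @param cell_labels integer label matrix.
#' @param threshold DAPI count threshold; strict `>` comparison. Default 60.
#' @param membrane_labels optional membrane label matrix to subtract.
#' @param exclude_cells labels whose nucleus is forced empty (e.g. cells
#'   that are all-membrane).
#' @return nucleus label matrix with attribute `empty_cells` (labels whose
#'   nucleus mask is empty).
#' @export
threshold_nucleus <- function(dapi, cell_labels, threshold = 60,
                              membrane_labels = NULL,
                              exclude_cells = integer(0)) {
  stopifnot(is.matrix(dapi), identical(dim(dapi), dim(cell_labels)))
  if (threshold < 0) stop("'threshold' must be >= 0")
  nucleus <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  empty <- integer(0)
  for (k in cell_ids(cell_labels)) {
    if (k %in% exclude_cells) { empty <- c(empty, k); next }
    cand <- cell_labels == k & dapi > threshold
    if (!is.null(membrane_labels)) cand <- cand & membrane_labels != k
    if (!any(cand)) { empty <- c(empty, k); next }
    bb <- mask_bbox(cand, pad = 1L, dim = dim(cand))
    comp <- EBImage::bwlabel(cand[bb$rows, bb$cols] * 1)
    sizes <- tabulate(comp[comp > 0])
    keep <- comp == which.max(sizes)
    nucleus[bb$rows, bb$cols][keep] <- k
  }
  if (length(empty) > 0)
    warning("empty nucleus mask for cell(s): ", paste(empty, collapse = ", "),
            " (flagged; nucleus metrics will be missing)")
  attr(nucleus, "empty_cells") <- empty
  nucleus
}

## ---- full segmentation ------------------------------------------------

#' Segment an image into the three per-cell masks
#'
#' Convenience wrapper chaining the individual steps: cell outlines to a
#' label mask, membrane ring by erosion, nucleus by the strict DAPI count
#' threshold (applied to the image as given — subtract the background first
#' if the threshold is meant post-subtraction).
#'
#' @param image a [multichannel_image()].
#' @param outlines label matrix or polygon data.frame
#'   (see [load_cell_outlines()]).
#' @param dapi_channel name of the DAPI channel.
#' @param threshold DAPI nucleus threshold in counts (strict `>`).
#' @param ring_width membrane ring width in pixels.
#' @param element structuring element for the ring.
#' @param provenance free-text provenance tag for the masks.
#' @return a [cell_segmentation()].
#' @export
segment_cells <- function(image, outlines, dapi_channel = "DAPI",
                          threshold = 60, ring_width = 3L,
                          element = c("box", "disc"),
                          provenance = "derived") {
  element <- match.arg(element)
  dapi <- get_channel(image, dapi_channel)
  cells <- load_cell_outlines(outlines, dim = dim(dapi))
  if (!identical(dim(cells), dim(dapi)))
    stop("outline mask dimensions do not match the image")
  membrane <- derive_membrane_ring(cells, ring_width, element)
  nucleus <- threshold_nucleus(dapi, cells, threshold, membrane,
                               exclude_cells = attr(membrane, "thin_cells"))
  ids <- cell_ids(cells)
  flags <- data.frame(cell_id = ids,
                      empty_nucleus = ids %in% attr(nucleus, "empty_cells"))
  cell_segmentation(cells, membrane, nucleus, ring_width = ring_width,
                    dapi_threshold = threshold, element = element,
                    provenance = provenance, flags = flags)
}
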