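#' Per-cell compartment intensity profiles
#'
#' The core distribution statistic: integrated (summed) intensities over
#' the cell, membrane-ring and nucleus masks, the membrane/cell and
#' nucleus/cell ratios, and the size-normalized total intensity
#' (I_total / cell area). Summed — not averaged — intensities are the
#' primitive, and the ratios are "internally calibrated": multiplying a
#' channel by any positive detector gain leaves them unchanged, which is
#' what makes ratios comparable across acquisitions with different
#' amplifier gain or zoom.
#'
#' Cells with zero total intensity get missing ratios (never 0/0);
#' cells flagged with an empty nucleus get a missing nucleus ratio.
#'
#' @param image a background-subtracted [multichannel_image()].
#' @param seg a [cell_segmentation()] (invariants are re-asserted).
#' @param channels channel names to profile; default all marker-like
#'   channels (everything in the image).
#' @return data.frame, one row per cell x channel: `cell_id`, `channel`,
#'   `I_total`, `I_membrane`, `I_nucleus`, `ratio_membrane`,
#'   `ratio_nucleus`, `intensity_per_area`, `cell_area`, `flags`.
#' @export
compartment_profile <- function(image, seg, channels = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  validate_segmentation(seg)
  if (is.null(channels)) channels <- names(image$channels)
  missing_ch <- setdiff(channels, names(image$channels))
  if (length(missing_ch) > 0)
    stop("channel(s) absent from image: ", paste(missing_ch, collapse = ", "))
  if (!identical(dim(seg$cell_labels), dim(image$channels[[1]])))
    stop("segmentation and image dimensions differ")
  ids <- cell_ids(seg$cell_labels)
  empty_nuc <- seg$flags$cell_id[seg$flags$empty_nucleus]
  rows <- list()
  for (ch in channels) {
    img <- image$channels[[ch]]
    for (k in ids) {
      cm <- seg$cell_labels == k
      area <- sum(cm)
      it <- sum(img[cm])
      im <- sum(img[seg$membrane_labels == k])
      inuc <- sum(img[seg$nucleus_labels == k])
      flags <- character(0)
      if (k %in% empty_nuc) flags <- c(flags, "empty_nucleus")
      if (it <= 0) flags <- c(flags, "zero_total")
      rm_ <- if (it > 0) im / it else NA_real_
      rn <- if (it > 0 && !(k %in% empty_nuc)) inuc / it else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = k, channel = ch, I_total = it, I_membrane = im,
        I_nucleus = inuc, ratio_membrane = rm_, ratio_nucleus = rn,
        intensity_per_area = it / area, cell_area = area,
        flags = paste(flags, collapse = ";"))
    }
  }
  out <- do.call(rbind, rows)
  assert_profile_invariants(out)
  out
}

# ratio bounds and additivity, asserted on every run
assert_profile_invariants <- function(profile) {
  ok <- stats::complete.cases(profile[, c("ratio_membrane", "ratio_nucleus")])
  rmem <- profile$ratio_membrane[ok]; rnuc <- profile$ratio_nucleus[ok]
  tol <- 1e-9
  if (any(rmem < -tol | rmem > 1 + tol) || any(rnuc < -tol | rnuc > 1 + tol))
    stop("profile invariant violated: compartment ratio outside [0, 1]")
  if (any(rmem + rnuc > 1 + tol))
    stop("profile invariant violated: ratio_membrane + ratio_nucleus > 1")
  if (any(profile$I_total + tol * pmax(profile$I_total, 1) <
          profile$I_membrane + profile$I_nucleus))
    stop("profile invariant violated: I_total < I_membrane + I_nucleus")
  invisible(profile)
}

#' Check gain invariance of the compartment ratios
#'
#' Recomputes the profile after applying a multiplicative gain to a
#' channel and verifies that both compartment ratios are unchanged within
#' floating tolerance while `intensity_per_area` scales by exactly the
#' gain.
#'
#' @param image a [multichannel_image()].
#' @param seg a [cell_segmentation()].
#' @param channel channel name.
#' @param gain positive scalar.
#' @param tol floating-point tolerance on the ratios (default 1e-9).
#' @return `TRUE` if invariance holds; otherwise `FALSE` (with details in
#'   attribute `"max_discrepancy"`).
#' @export
gain_invariance_check <- function(image, seg, channel, gain, tol = 1e-9) {
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("'gain' must be a single positive number")
  p0 <- compartment_profile(image, seg, channel)
  p1 <- compartment_profile(apply_gain(image, channel, gain), seg, channel)
  dr <- max(abs(p1$ratio_membrane - p0$ratio_membrane),
            abs(p1$ratio_nucleus - p0$ratio_nucleus), na.rm = TRUE)
  rel <- max(abs(p1$intensity_per_area - gain * p0$intensity_per_area) /
               pmax(gain * p0$intensity_per_area, .Machine$double.eps))
  ok <- dr <= tol && rel <= 1e-9
  attr(ok, "max_discrepancy") <- max(dr, rel)
  ok
}
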