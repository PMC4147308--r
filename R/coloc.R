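## Mask-restricted co-localization between two channels: Manders split
## coefficients, product-of-the-differences-from-the-mean (PDM) maps, and
## frequency scatter-plot data. Formulas are the literature-standard ones
## behind the classic intensity-correlation-analysis plugins; the region
## (nucleus, membrane ring, or whole cell) is always an explicit argument,
## never an implicit whole image.

#' Manders split coefficients over a region
#'
#' `M1` is the fraction of channel-A integrated intensity found at pixels
#' where channel B exceeds the co-occurrence threshold; `M2` is the
#' symmetric quantity. Both channels are expected background-subtracted;
#' the default threshold is 0 (strict `>`), i.e. any residual signal
#' counts as co-occurrence.
#'
#' @param a,b intensity matrices (same dimensions).
#' @param mask logical matrix selecting the region; must be nonempty.
#' @param threshold co-occurrence threshold (strict `>`), default 0.
#' @return list: `M1`, `M2` (each in \[0, 1\], or `NA` with a flag when
#'   the corresponding denominator is zero), `n_pixels`, `threshold`,
#'   `flags` (character vector).
#' @export
manders <- function(a, b, mask, threshold = 0) {
  stopifnot(is.matrix(a), identical(dim(a), dim(b)),
            identical(dim(a), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty region mask")
  av <- a[mask]; bv <- b[mask]
  flags <- character(0)
  sa <- sum(av); sb <- sum(bv)
  m1 <- if (sa > 0) sum(av[bv > threshold]) / sa else {
    flags <- c(flags, "zero_A"); NA_real_
  }
  m2 <- if (sb > 0) sum(bv[av > threshold]) / sb else {
    flags <- c(flags, "zero_B"); NA_real_
  }
  for (m in c(m1, m2))
    if (!is.na(m) && (m < 0 || m > 1 + 1e-12))
      stop("Manders coefficient outside [0, 1]")
  list(M1 = m1, M2 = m2, n_pixels = sum(mask), threshold = threshold,
       flags = flags)
}

#' PDM map and frequency scatter histogram over a region
#'
#' The PDM at pixel i is `(A_i - mean(A)) * (B_i - mean(B))`, means taken
#' over the region: positive where the channels co-vary, negative where
#' they anti-vary, and its regional mean is by construction the covariance
#' of A and B over the region. The scatter histogram bins the in-region
#' (A, B) pixel pairs on a linear grid spanning each channel's in-region
#' range.
#'
#' @param a,b intensity matrices.
#' @param mask logical region mask, nonempty.
#' @param bins number of bins per axis for the scatter histogram.
#' @return list: `pdm_map` (matrix, `NA` outside the region),
#'   `mean_pdm` (= regional covariance), `positive_fraction` (share of
#'   region pixels with PDM > 0), `scatter_hist` (bins x bins counts,
#'   A on rows, B on columns), `breaks_a`, `breaks_b`, `n_pixels`.
#' @export
pdm <- function(a, b, mask, bins = 64L) {
  stopifnot(is.matrix(a), identical(dim(a), dim(b)),
            identical(dim(a), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty region mask")
  av <- a[mask]; bv <- b[mask]
  map <- matrix(NA_real_, nrow(a), ncol(a))
  map[mask] <- (av - mean(av)) * (bv - mean(bv))
  breaks_a <- seq(min(av), max(av), length.out = bins + 1L)
  breaks_b <- seq(min(bv), max(bv), length.out = bins + 1L)
  # degenerate constant channels still need a valid binning
  if (breaks_a[1] == breaks_a[bins + 1L])
    breaks_a <- breaks_a + seq(-0.5, 0.5, length.out = bins + 1L)
  if (breaks_b[1] == breaks_b[bins + 1L])
    breaks_b <- breaks_b + seq(-0.5, 0.5, length.out = bins + 1L)
  ia <- findInterval(av, breaks_a, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ib <- findInterval(bv, breaks_b, rightmost.closed = TRUE,
                     all.inside = TRUE)
  hist <- matrix(0L, bins, bins)
  for (i in seq_along(ia)) hist[ia[i], ib[i]] <- hist[ia[i], ib[i]] + 1L
  stopifnot(sum(hist) == sum(mask))
  list(pdm_map = map,
       mean_pdm = mean(map[mask]),
       positive_fraction = mean(map[mask] > 0),
       scatter_hist = hist, breaks_a = breaks_a, breaks_b = breaks_b,
       n_pixels = sum(mask))
}

#' Per-cell co-localization table for a segmented image
#'
#' Runs [manders()] and [pdm()] for every cell, restricted to the chosen
#' compartment of that cell.
#'
#' @param image a background-subtracted [multichannel_image()].
#' @param seg a [cell_segmentation()].
#' @param channels length-2 character: the A and B channel names.
#' @param region `"nucleus"`, `"membrane"` or `"cell"`.
#' @param threshold Manders co-occurrence threshold.
#' @param bins scatter histogram bins.
#' @return data.frame, one row per cell: `cell_id`, `region`, `M1`, `M2`,
#'   `mean_pdm`, `positive_pdm_fraction`, `n_pixels`, `flags`. Cells whose
#'   region mask is empty are reported with `NA`s and flag
#'   `"empty_region"`.
#' @export
coloc_profile <- function(image, seg, channels, region = c("nucleus",
                          "membrane", "cell"), threshold = 0, bins = 64L) {
  region <- match.arg(region)
  stopifnot(length(channels) == 2L)
  validate_segmentation(seg)
  a <- get_channel(image, channels[1])
  b <- get_channel(image, channels[2])
  labels <- switch(region, nucleus = seg$nucleus_labels,
                   membrane = seg$membrane_labels, cell = seg$cell_labels)
  rows <- lapply(cell_ids(seg$cell_labels), function(k) {
    mask <- labels == k
    if (!any(mask))
      return(data.frame(cell_id = k, region = region, M1 = NA_real_,
                        M2 = NA_real_, mean_pdm = NA_real_,
                        positive_pdm_fraction = NA_real_, n_pixels = 0L,
                        flags = "empty_region"))
    mm <- manders(a, b, mask, threshold)
    pp <- pdm(a, b, mask, bins)
    data.frame(cell_id = k, region = region, M1 = mm$M1, M2 = mm$M2,
               mean_pdm = pp$mean_pdm,
               positive_pdm_fraction = pp$positive_fraction,
               n_pixels = mm$n_pixels,
               flags = paste(mm$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Condition-level summary of membrane/total and nucleus/total ratios
#'
#' Aggregates per-cell compartment profiles of two markers across
#' experimental conditions: group means and standard errors of the
#' membrane/cell and nucleus/cell ratios, the input for membrane-to-nucleus
#' redistribution comparisons. Pure aggregation — no new arithmetic beyond
#' the profiles themselves.
#'
#' @param profiles a [compartment_profile()] table (any number of
#'   channels), with cells from all conditions.
#' @param conditions data.frame mapping `cell_id` to `condition`.
#' @return data.frame: `condition`, `channel`, `n_cells`,
#'   `mean_ratio_membrane`, `sem_ratio_membrane`, `mean_ratio_nucleus`,
#'   `sem_ratio_nucleus`. Conditions with fewer than 2 usable cells are
#'   flagged in column `flags` and a warning is raised; with a single
#'   condition the summary is still emitted (comparison left to the
#'   caller).
#' @export
nuclear_membrane_shift <- function(profiles, conditions) {
  stopifnot(all(c("cell_id", "condition") %in% names(conditions)))
  profiles$condition <- NULL  # the map, not the table, assigns conditions
  df <- merge(profiles, conditions, by = "cell_id")
  if (nrow(df) == 0L) stop("no cells match the condition map")
  if (length(unique(df$condition)) < 2L)
    warning("single condition: summary emitted, no comparison possible")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(df, list(df$condition, df$channel),
                                     drop = TRUE), function(g) {
    rmem <- g$ratio_membrane[is.finite(g$ratio_membrane)]
    rnuc <- g$ratio_nucleus[is.finite(g$ratio_nucleus)]
    data.frame(condition = g$condition[1], channel = g$channel[1],
               n_cells = length(rmem),
               mean_ratio_membrane = mean(rmem),
               sem_ratio_membrane = sem(rmem),
               mean_ratio_nucleus = if (length(rnuc)) mean(rnuc) else NA_real_,
               sem_ratio_nucleus = if (length(rnuc) > 1) sem(rnuc) else NA_real_,
               flags = if (length(rmem) < 2) "too_few_cells" else "")
  }))
  rownames(out) <- NULL
  if (any(out$flags == "too_few_cells"))
    warning("condition(s) with < 2 usable cells flagged and unfit for tests")
  out[order(out$channel, out$condition), ]
}
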