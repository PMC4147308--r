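#' Multi-channel fluorescence image
#'
#' Bundles named 2D intensity grids (detector counts) that share one pixel
#' geometry, together with the physical pixel size and free-form provenance
#' metadata. This is the raw input to every downstream stage.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions; values are detector counts ("cts"), finite and >= 0.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param metadata free-form list recording provenance (e.g. the background
#'   scalar subtracted per channel).
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size = 0.2, metadata = list()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1))))
    stop("every channel must be a numeric matrix")
  d0 <- dims[[1]]
  if (any(vapply(dims, function(d) !identical(d, d0), logical(1))))
    stop("all channels must share identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(!is.finite(ch))) stop("channel '", nm, "' contains non-finite values")
    if (any(ch < 0)) stop("channel '", nm, "' contains negative intensities")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size, metadata = metadata),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<multichannel_image> ", d[1], "x", d[2], " px, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "),
      " | pixel size ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

#' Retrieve one channel as a matrix
#'
#' @param image a [multichannel_image()].
#' @param channel channel name.
#' @return numeric matrix of intensities.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!channel %in% names(image$channels))
    stop("channel '", channel, "' not present (have: ",
         paste(names(image$channels), collapse = ", "), ")")
  image$channels[[channel]]
}

#' Subtract a scalar background from each channel
#'
#' Estimates one background scalar per channel (whole-frame median by
#' default, mode of the integer-rounded histogram, or a user-fixed value)
#' and subtracts it, clipping negative results at zero. The scalar used is
#' recorded in `metadata$background` so the provenance of every downstream
#' ratio is auditable.
#'
#' @param image a [multichannel_image()].
#' @param stat one of `"median"`, `"mode"`, `"fixed"`.
#' @param values for `stat = "fixed"`: named numeric vector of non-negative
#'   backgrounds, one per channel to correct (channels not named are left
#'   untouched).
#' @return a new `multichannel_image`, background-subtracted, with the
#'   scalars used stored under `metadata$background`.
#' @export
subtract_background <- function(image, stat = c("median", "mode", "fixed"),
                                values = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  stat <- match.arg(stat)
  bg <- numeric(0)
  out <- image$channels
  for (nm in names(out)) {
    ch <- out[[nm]]
    if (length(ch) == 0L) stop("channel '", nm, "' is empty")
    b <- switch(stat,
      median = stats::median(ch),
      mode = {
        tb <- table(round(ch))
        as.numeric(names(tb)[which.max(tb)])
      },
      fixed = {
        if (is.null(values) || is.null(names(values)))
          stop("stat = 'fixed' requires a named 'values' vector")
        if (!nm %in% names(values)) NA_real_ else values[[nm]]
      }
    )
    if (stat == "fixed" && is.na(b)) next
    if (b < 0) stop("background for channel '", nm, "' must be >= 0")
    out[[nm]] <- pmax(ch - b, 0)
    bg[nm] <- b
  }
  meta <- image$metadata
  meta$background <- as.list(bg)
  meta$background_stat <- stat
  multichannel_image(out, pixel_size = image$pixel_size, metadata = meta)
}

#' Apply a multiplicative detector gain to a channel
#'
#' Utility for the internal-calibration contract: compartment intensity
#' ratios must be invariant under any positive gain. See
#' [gain_invariance_check()].
#'
#' @param image a [multichannel_image()].
#' @param channel channel name.
#' @param gain positive scalar.
#' @return the image with that channel scaled by `gain`.
#' @export
apply_gain <- function(image, channel, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("'gain' must be a single positive number")
  ch <- get_channel(image, channel)
  image$channels[[channel]] <- ch * gain
  image
}
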