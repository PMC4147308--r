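## Synthetic confocal scenes with planted ground truth.
##
## The generator emulates the statistical structure the downstream metrics
## assume — sparse adherent cells with elliptical nuclei, a thin membrane
## ring, a controllable split of marker intensity between membrane ring,
## nucleus and cytoplasm, controllable channel-channel co-localization,
## controllable cell adjacency, uniform background plus shot and read
## noise — not optical realism (no PSF, no organelle texture, no 3D).

#' Specification of a synthetic multi-channel scene
#'
#' All downstream recovery tests run against scenes built from this spec.
#' The planted per-channel compartment fractions `membrane_fraction` (f_m)
#' and `nucleus_fraction` (f_n) are exact on the clean image: within each
#' cell the generator distributes `cell_amplitude * cell_area` total counts
#' so that exactly f_m of them fall in the membrane ring and f_n in the
#' nucleus (per-compartment texture is renormalized to make this hold to
#' floating precision, not just in expectation).
#'
#' @param image_size `c(rows, cols)` in pixels; chosen automatically for
#'   chained/clustered modes when `NULL`.
#' @param pixel_size micrometers per pixel (default 0.2, a typical 60x
#'   confocal sampling; a config default, not load-bearing).
#' @param n_cells number of cells.
#' @param adjacency_mode `"isolated"` (no touching cells), `"chained"`
#'   (one row of rectangular cells sharing full vertical edges) or
#'   `"clustered"` (a two-row block of rectangles sharing edges).
#' @param target_contact_fraction for chained scenes: the fraction of an
#'   interior cell's boundary shared with neighbors, in \[0, 1); sets the
#'   cell aspect ratio (shared/total = height/(width+height)). Ignored for
#'   isolated scenes (contact is 0 by construction).
#' @param cell_shape `"elongated"` (ellipses with `axis_ratio`) or
#'   `"cuboidal"` (rectangles); chained/clustered modes always use
#'   rectangles so shared edges coincide exactly.
#' @param axis_ratio major/minor axis ratio for elongated cells.
#' @param cell_diameter nominal cell minor diameter in pixels.
#' @param nucleus_axis_fraction nucleus axes as a fraction of cell axes.
#' @param membrane_ring_width ring width in pixels.
#' @param channel_params named list per channel:
#'   `list(background, cell_amplitude, membrane_fraction, nucleus_fraction)`
#'   with `membrane_fraction + nucleus_fraction <= 1`. Channels named in
#'   `nuclear_stain` / `outline_channel` are rendered specially (flat
#'   amplitude inside the nucleus; cell outline sketch) and ignore the
#'   fraction fields.
#' @param nuclear_stain channel rendered as a nuclear stain (DAPI).
#' @param outline_channel optional channel rendered as a transmitted-light
#'   proxy sketching cell outlines (DIC stand-in); `NULL` to omit.
#' @param coloc_channels the two marker channels whose in-cell textures are
#'   co-localized at level `coloc_rho`.
#' @param coloc_rho co-localization level in \[0, 1\]: each pixel of the
#'   second marker copies the first marker's texture with probability
#'   `coloc_rho` and draws an independent same-marginal value otherwise,
#'   so 0 gives independent fields, 1 gives exact pixelwise
#'   proportionality, and thresholded overlap grows monotonically.
#' @param texture_density fraction of in-cell pixels with nonzero marker
#'   texture (sparse granularity; gives Manders coefficients room below 1).
#' @param texture_shape gamma shape of the positive texture component.
#' @param noise list `list(poisson = TRUE/FALSE, gaussian_sd = counts)`:
#'   shot noise and additive read noise (clipped at zero).
#' @param seed integer; fixing it fixes the emitted scene bit-for-bit.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = NULL,
                       pixel_size = 0.2,
                       n_cells = 8L,
                       adjacency_mode = c("isolated", "chained", "clustered"),
                       target_contact_fraction = 0,
                       cell_shape = c("elongated", "cuboidal"),
                       axis_ratio = 1.6,
                       cell_diameter = 34L,
                       nucleus_axis_fraction = 0.42,
                       membrane_ring_width = 3L,
                       channel_params = NULL,
                       nuclear_stain = "DAPI",
                       outline_channel = "DIC",
                       coloc_channels = c("markerA", "markerB"),
                       coloc_rho = 0,
                       texture_density = 0.7,
                       texture_shape = 4,
                       noise = list(poisson = TRUE, gaussian_sd = 2),
                       seed = 1L) {
  adjacency_mode <- match.arg(adjacency_mode)
  cell_shape <- match.arg(cell_shape)
  if (is.null(channel_params)) {
    channel_params <- list(
      DAPI    = list(background = 5, cell_amplitude = 200,
                     membrane_fraction = 0, nucleus_fraction = 1),
      markerA = list(background = 8, cell_amplitude = 50,
                     membrane_fraction = 0.5, nucleus_fraction = 0.2),
      markerB = list(background = 8, cell_amplitude = 40,
                     membrane_fraction = 0.5, nucleus_fraction = 0.2),
      DIC     = list(background = 20, cell_amplitude = 120)
    )
  }
  for (nm in names(channel_params)) {
    p <- channel_params[[nm]]
    fm <- p$membrane_fraction %||% 0
    fn <- p$nucleus_fraction %||% 0
    if (fm < 0 || fm > 1 || fn < 0 || fn > 1)
      stop("channel '", nm, "': fractions must lie in [0, 1]")
    if (fm + fn > 1 + 1e-12)
      stop("channel '", nm, "': membrane_fraction + nucleus_fraction > 1")
    if ((p$background %||% 0) < 0 || (p$cell_amplitude %||% 0) < 0)
      stop("channel '", nm, "': background and amplitude must be >= 0")
  }
  if (coloc_rho < 0 || coloc_rho > 1) stop("'coloc_rho' must lie in [0, 1]")
  if (target_contact_fraction < 0 || target_contact_fraction >= 1)
    stop("'target_contact_fraction' must lie in [0, 1)")
  if (texture_density <= 0 || texture_density > 1)
    stop("'texture_density' must lie in (0, 1]")
  structure(
    list(image_size = image_size, pixel_size = pixel_size,
         n_cells = as.integer(n_cells), adjacency_mode = adjacency_mode,
         target_contact_fraction = target_contact_fraction,
         cell_shape = cell_shape, axis_ratio = axis_ratio,
         cell_diameter = as.integer(cell_diameter),
         nucleus_axis_fraction = nucleus_axis_fraction,
         membrane_ring_width = as.integer(membrane_ring_width),
         channel_params = channel_params, nuclear_stain = nuclear_stain,
         outline_channel = outline_channel, coloc_channels = coloc_channels,
         coloc_rho = coloc_rho, texture_density = texture_density,
         texture_shape = texture_shape, noise = noise,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed seed, restoring the caller's RNG state
with_scene_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## ---- geometry placement ----------------------------------------------

# each cell: list(kind = "ellipse"/"rect", center, a, b (semi-axes, px),
# theta, or x0/x1/y0/y1 integer rect bounds [x0,x1) in 0-based px coords)
place_cells <- function(spec) {
  n <- spec$n_cells
  d <- spec$cell_diameter
  if (spec$adjacency_mode == "isolated") {
    long <- if (spec$cell_shape == "elongated") d * spec$axis_ratio else d
    pitch <- ceiling(long + 8)
    ncol_grid <- ceiling(sqrt(n))
    nrow_grid <- ceiling(n / ncol_grid)
    size <- spec$image_size %||%
      c(nrow_grid * pitch + 8, ncol_grid * pitch + 8)
    if (size[1] < nrow_grid * pitch || size[2] < ncol_grid * pitch)
      stop("placement error: image_size too small for ", n,
           " non-overlapping cells of diameter ", d,
           " (need >= ", nrow_grid * pitch, " x ", ncol_grid * pitch, ")")
    cells <- vector("list", n)
    for (k in seq_len(n)) {
      gi <- (k - 1L) %/% ncol_grid; gj <- (k - 1L) %% ncol_grid
      cy <- 4 + gi * pitch + pitch / 2 + stats::runif(1, -2, 2)
      cx <- 4 + gj * pitch + pitch / 2 + stats::runif(1, -2, 2)
      if (spec$cell_shape == "elongated") {
        cells[[k]] <- list(kind = "ellipse", cx = cx, cy = cy,
                           a = d * spec$axis_ratio / 2, b = d / 2,
                           theta = stats::runif(1, 0, pi))
      } else {
        half <- d / 2
        cells[[k]] <- list(kind = "rect",
                           x0 = round(cx - half), x1 = round(cx + half),
                           y0 = round(cy - half), y1 = round(cy + half))
      }
    }
    return(list(cells = cells, size = size))
  }
  # chained / clustered: rectangles with coincident edges
  t <- spec$target_contact_fraction
  h <- d
  w <- if (t > 0) max(4L, round(h * (1 - t) / t)) else h
  if (spec$adjacency_mode == "chained") {
    if (t == 0) {  # degenerate chain: spaced squares, no contact
      return(place_cells(modifyList(spec, list(adjacency_mode = "isolated",
                                               cell_shape = "cuboidal"))))
    }
    size <- spec$image_size %||% c(h + 16, n * w + 16)
    if (size[2] < n * w + 8 || size[1] < h + 8)
      stop("placement error: image_size too small for a chain of ", n,
           " cells ", w, " x ", h, " px")
    cells <- lapply(seq_len(n), function(k)
      list(kind = "rect", x0 = 8 + (k - 1L) * w, x1 = 8 + k * w,
           y0 = 8, y1 = 8 + h))
    return(list(cells = cells, size = size, cell_w = w, cell_h = h))
  }
  # clustered: two rows sharing horizontal and vertical edges
  ncol_grid <- ceiling(n / 2)
  size <- spec$image_size %||% c(2 * h + 16, ncol_grid * w + 16)
  cells <- lapply(seq_len(n), function(k) {
    gi <- (k - 1L) %% 2L; gj <- (k - 1L) %/% 2L
    list(kind = "rect", x0 = 8 + gj * w, x1 = 8 + (gj + 1L) * w,
         y0 = 8 + gi * h, y1 = 8 + (gi + 1L) * h)
  })
  list(cells = cells, size = size, cell_w = w, cell_h = h)
}

# center-sampled rasterization of one placed cell
rasterize_cell <- function(cell, size, shrink = 0) {
  h <- size[1]; w <- size[2]
  if (cell$kind == "rect") {
    x0 <- cell$x0 + shrink; x1 <- cell$x1 - shrink
    y0 <- cell$y0 + shrink; y1 <- cell$y1 - shrink
    cols <- which(seq_len(w) - 0.5 > x0 & seq_len(w) - 0.5 < x1)
    rows <- which(seq_len(h) - 0.5 > y0 & seq_len(h) - 0.5 < y1)
    if (length(cols) == 0L || length(rows) == 0L) return(NULL)
    cbind(row = rep(rows, times = length(cols)),
          col = rep(cols, each = length(rows)))
  } else {
    a <- cell$a - shrink; b <- cell$b - shrink
    if (a <= 0 || b <= 0) return(NULL)
    m <- max(a, b)
    rr <- floor(max(1, cell$cy - m)):ceiling(min(h, cell$cy + m))
    cc <- floor(max(1, cell$cx - m)):ceiling(min(w, cell$cx + m))
    x <- rep(cc - 0.5, each = length(rr)) - cell$cx
    y <- rep(rr - 0.5, times = length(cc)) - cell$cy
    u <- x * cos(cell$theta) + y * sin(cell$theta)
    v <- -x * sin(cell$theta) + y * cos(cell$theta)
    inside <- (u / a)^2 + (v / b)^2 < 1
    if (!any(inside)) return(NULL)
    cbind(row = rep(rr, times = length(cc))[inside],
          col = rep(cc, each = length(rr))[inside])
  }
}

# analytic boundary length of the placed (continuous) cell shape
true_cell_perimeter <- function(cell) {
  if (cell$kind == "rect")
    2 * (cell$x1 - cell$x0) + 2 * (cell$y1 - cell$y0)
  else {  # Ramanujan's ellipse perimeter approximation
    a <- cell$a; b <- cell$b
    hh <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * hh / (10 + sqrt(4 - 3 * hh)))
  }
}

# shared polygon-edge length between two placed rectangles (0 otherwise)
true_shared_edge <- function(ci, cj) {
  if (ci$kind != "rect" || cj$kind != "rect") return(0)
  len <- 0
  if (ci$x1 == cj$x0 || ci$x0 == cj$x1)  # vertical edge coincides
    len <- len + max(0, min(ci$y1, cj$y1) - max(ci$y0, cj$y0))
  if (ci$y1 == cj$y0 || ci$y0 == cj$y1)  # horizontal edge coincides
    len <- len + max(0, min(ci$x1, cj$x1) - max(ci$x0, cj$x0))
  len
}

## ---- scene generation -------------------------------------------------

#' Generate a synthetic scene with planted ground truth
#'
#' Renders the clean multi-channel image (exact planted compartment
#' fractions), applies the configured noise, and returns the noisy image
#' together with a `scene_truth` object holding the true masks and the
#' per-cell planted parameters. Running twice with the same spec yields
#' bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @param clean if `TRUE`, skip the noise stage (useful for oracle tests).
#' @return list with elements `image` (a [multichannel_image()]) and
#'   `truth` (class `scene_truth`: `cell_labels`, `membrane_labels`,
#'   `nucleus_labels` matrices; `cells` data.frame of per-cell geometry
#'   truth; `channels` data.frame of per-cell x channel planted fractions;
#'   `clean` list of noise-free channel matrices; `spec`).
#' @export
generate_scene <- function(spec, clean = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    placed <- place_cells(spec)
    size <- as.integer(placed$size)
    n <- spec$n_cells
    rw <- spec$membrane_ring_width

    cell_labels <- matrix(0L, size[1], size[2])
    for (k in seq_len(n)) {
      px <- rasterize_cell(placed$cells[[k]], size)
      if (is.null(px))
        stop("placement error: cell ", k, " rasterizes to zero pixels")
      idx <- px[, 1] + (px[, 2] - 1L) * size[1]
      if (any(cell_labels[idx] != 0L))
        stop("placement error: cell ", k, " overlaps an earlier cell")
      cell_labels[idx] <- k
    }

    membrane_labels <- derive_membrane_ring(cell_labels, rw, "box")
    if (length(attr(membrane_labels, "thin_cells")) > 0)
      stop("placement error: cell(s) thinner than twice the ring width: ",
           paste(attr(membrane_labels, "thin_cells"), collapse = ", "))

    # nuclei: ellipses scaled from the cell shape, kept strictly inside
    # the eroded interior so they never touch the membrane ring
    nucleus_labels <- matrix(0L, size[1], size[2])
    for (k in seq_len(n)) {
      cell <- placed$cells[[k]]
      nf <- spec$nucleus_axis_fraction
      nuc <- if (cell$kind == "rect") {
        list(kind = "ellipse", cx = (cell$x0 + cell$x1) / 2,
             cy = (cell$y0 + cell$y1) / 2,
             a = nf * (cell$x1 - cell$x0) / 2,
             b = nf * (cell$y1 - cell$y0) / 2, theta = 0)
      } else {
        modifyList(cell, list(a = nf * cell$a, b = nf * cell$b))
      }
      px <- rasterize_cell(nuc, size)
      if (is.null(px))
        stop("cell ", k, ": nucleus rasterizes to zero pixels; ",
             "increase nucleus_axis_fraction or cell_diameter")
      idx <- px[, 1] + (px[, 2] - 1L) * size[1]
      bad <- cell_labels[idx] != k | membrane_labels[idx] == k
      if (any(bad))
        stop("cell ", k, ": nucleus intersects the membrane ring; ",
             "reduce nucleus_axis_fraction or membrane_ring_width")
      nucleus_labels[idx] <- k
    }

    # clean channels
    chans <- names(spec$channel_params)
    clean_im <- list()
    textures <- plant_textures(spec, cell_labels)
    for (nm in chans) {
      p <- spec$channel_params[[nm]]
      bg <- p$background %||% 0
      img <- matrix(bg, size[1], size[2])
      if (identical(nm, spec$nuclear_stain)) {
        img[nucleus_labels > 0] <- img[nucleus_labels > 0] + p$cell_amplitude
      } else if (identical(nm, spec$outline_channel)) {
        edge <- cell_labels > 0 & membrane_labels > 0
        img[edge] <- img[edge] + p$cell_amplitude
      } else {
        img <- img + render_marker(spec, nm, cell_labels, membrane_labels,
                                   nucleus_labels, textures[[nm]])
      }
      clean_im[[nm]] <- img
    }

    channels_truth <- do.call(rbind, lapply(chans, function(nm) {
      p <- spec$channel_params[[nm]]
      special <- identical(nm, spec$nuclear_stain) ||
        identical(nm, spec$outline_channel)
      data.frame(cell_id = seq_len(n), channel = nm,
                 f_membrane = if (special) NA_real_ else p$membrane_fraction,
                 f_nucleus = if (special) NA_real_ else p$nucleus_fraction,
                 cell_amplitude = p$cell_amplitude,
                 background = p$background %||% 0)
    }))

    cells_truth <- do.call(rbind, lapply(seq_len(n), function(k) {
      cell <- placed$cells[[k]]
      peri <- true_cell_perimeter(cell)
      shared <- sum(vapply(seq_len(n)[-k], function(j)
        true_shared_edge(cell, placed$cells[[j]]), numeric(1)))
      if (cell$kind == "rect") {
        longi <- max(cell$x1 - cell$x0, cell$y1 - cell$y0)
        horiz <- min(cell$x1 - cell$x0, cell$y1 - cell$y0)
      } else {
        longi <- 2 * cell$a; horiz <- 2 * cell$b
      }
      data.frame(cell_id = k, shape = cell$kind,
                 area_px = sum(cell_labels == k),
                 membrane_px = sum(membrane_labels == k),
                 nucleus_px = sum(nucleus_labels == k),
                 true_perimeter = peri, true_shared = shared,
                 true_contact_fraction = shared / peri,
                 true_longitudinal = longi, true_horizontal = horiz,
                 coloc_rho = spec$coloc_rho)
    }))

    noisy <- if (clean) clean_im else add_noise(clean_im, spec$noise)

    image <- multichannel_image(noisy, pixel_size = spec$pixel_size,
                                metadata = list(synthetic = TRUE,
                                                seed = spec$seed))
    truth <- structure(
      list(cell_labels = cell_labels, membrane_labels = membrane_labels,
           nucleus_labels = nucleus_labels, cells = cells_truth,
           channels = channels_truth, clean = clean_im, spec = spec),
      class = "scene_truth"
    )
    list(image = image, truth = truth)
  })
}

# sparse gamma textures for the two co-localized markers: the second
# marker copies the first marker's pixel texture with probability rho,
# otherwise draws an independent value from the same marginal
plant_textures <- function(spec, cell_labels) {
  inside <- which(cell_labels > 0)
  m <- length(inside)
  q <- spec$texture_density; sh <- spec$texture_shape
  draw <- function() stats::rbinom(m, 1L, q) *
    stats::rgamma(m, shape = sh, rate = sh)
  tA <- draw()
  tI <- draw()
  pick <- stats::runif(m) < spec$coloc_rho
  tB <- ifelse(pick, tA, tI)
  markers <- setdiff(names(spec$channel_params),
                     c(spec$nuclear_stain, spec$outline_channel))
  out <- list()
  for (nm in markers) {
    t <- if (nm == spec$coloc_channels[1]) tA
         else if (nm == spec$coloc_channels[2]) tB
         else draw()
    tex <- matrix(0, nrow(cell_labels), ncol(cell_labels))
    tex[inside] <- t
    out[[nm]] <- tex
  }
  out
}

# distribute cell_amplitude * area counts per cell so that exactly f_m of
# them lie in the ring and f_n in the nucleus: texture is renormalized to
# unit mean within each compartment of each cell
render_marker <- function(spec, nm, cell_labels, membrane_labels,
                          nucleus_labels, texture) {
  p <- spec$channel_params[[nm]]
  fm <- p$membrane_fraction; fn <- p$nucleus_fraction
  fc <- 1 - fm - fn
  img <- matrix(0, nrow(cell_labels), ncol(cell_labels))
  for (k in cell_ids(cell_labels)) {
    total <- p$cell_amplitude * sum(cell_labels == k)
    comps <- list(
      membrane = list(mask = membrane_labels == k, frac = fm),
      nucleus = list(mask = nucleus_labels == k, frac = fn),
      cytoplasm = list(mask = cell_labels == k & membrane_labels != k &
                         nucleus_labels != k, frac = fc)
    )
    for (cmp in comps) {
      if (cmp$frac <= 0) next
      idx <- which(cmp$mask)
      if (length(idx) == 0L)
        stop("channel '", nm, "', cell ", k,
             ": planted fraction > 0 in an empty compartment")
      t <- texture[idx]
      if (sum(t) <= 0)
        stop("channel '", nm, "', cell ", k,
             ": all-zero texture in a compartment; raise texture_density")
      img[idx] <- cmp$frac * total * t / sum(t)
    }
  }
  img
}

add_noise <- function(channels, noise) {
  pois <- isTRUE(noise$poisson)
  sd <- noise$gaussian_sd %||% 0
  lapply(channels, function(ch) {
    x <- ch
    if (pois) x[] <- stats::rpois(length(x), lambda = as.vector(x))
    if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
    pmax(x, 0)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", nrow(x$cells), " cells (",
      x$spec$adjacency_mode, "), planted rho = ", x$spec$coloc_rho,
      ", seed = ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Turn a scene truth into a truth-based segmentation
#'
#' Wraps the generator's true masks in a [cell_segmentation()] (provenance
#' `"truth"`), the reference frame for recovery tests.
#'
#' @param truth a `scene_truth`.
#' @return a [cell_segmentation()].
#' @export
truth_segmentation <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cell_segmentation(truth$cell_labels, truth$membrane_labels,
                    truth$nucleus_labels,
                    ring_width = truth$spec$membrane_ring_width,
                    dapi_threshold = NA_real_, element = "box",
                    provenance = "truth")
}
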