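#' Run the full quantification pipeline on one scene
#'
#' Chains the stages exactly as they run on real data: median background
#' subtraction, segmentation into the three masks (cell outlines plus the
#' strict DAPI count threshold for nuclei and the erosion ring for the
#' membrane), per-cell compartment profiles, contact/morphology table, and
#' nuclear co-localization of the two marker channels. All outputs are
#' plain data.frames; with `out_dir` set they are also written as CSV
#' (deterministically, so a seeded scene yields byte-identical files
#' across runs).
#'
#' @param scene a `list(image, truth)` from [generate_scene()], or a
#'   [multichannel_image()] when `outlines` is supplied.
#' @param outlines cell outlines for real images (label matrix or polygon
#'   table); defaults to the scene truth's cell label mask.
#' @param dapi_channel,dapi_threshold nucleus rule (strict `>` threshold,
#'   applied after background subtraction).
#' @param ring_width,element membrane ring definition.
#' @param coloc_channels the marker pair for co-localization.
#' @param coloc_region compartment for the co-localization table.
#' @param contact_distance Chebyshev contact tolerance in pixels.
#' @param out_dir optional directory for CSV outputs.
#' @return list: `image` (background-subtracted), `seg`, `profiles`,
#'   `morphology`, `coloc`, and `paths` (if written).
#' @export
run_scene_pipeline <- function(scene, outlines = NULL,
                               dapi_channel = "DAPI", dapi_threshold = 60,
                               ring_width = 3L, element = "box",
                               coloc_channels = c("markerA", "markerB"),
                               coloc_region = "nucleus",
                               contact_distance = 2L,
                               out_dir = NULL) {
  if (inherits(scene, "multichannel_image")) {
    image <- scene
    if (is.null(outlines))
      stop("'outlines' is required when passing a bare image")
  } else {
    image <- scene$image
    if (is.null(outlines)) outlines <- scene$truth$cell_labels
  }
  image <- subtract_background(image, "median")
  seg <- segment_cells(image, outlines, dapi_channel = dapi_channel,
                       threshold = dapi_threshold, ring_width = ring_width,
                       element = element, provenance = "pipeline")
  marker_channels <- setdiff(names(image$channels),
                             c(dapi_channel, "DIC"))
  profiles <- compartment_profile(image, seg, marker_channels)
  morphology <- contact_morphology(seg, contact_distance = contact_distance)
  coloc <- coloc_profile(image, seg, coloc_channels, region = coloc_region)
  out <- list(image = image, seg = seg, profiles = profiles,
              morphology = morphology, coloc = coloc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(profiles = file.path(out_dir, "profiles.csv"),
               morphology = file.path(out_dir, "morphology.csv"),
               coloc = file.path(out_dir, "coloc.csv"))
    utils::write.csv(profiles, paths["profiles"], row.names = FALSE)
    utils::write.csv(morphology, paths["morphology"], row.names = FALSE)
    utils::write.csv(coloc, paths["coloc"], row.names = FALSE)
    out$paths <- paths
  }
  out
}
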