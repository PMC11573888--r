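# Nuclei segmentation on the deconvolved hematoxylin channel and the
# patch-selection features: nucleus count, staining density and nuclear
# dimension (major/minor axis) ratios, plus the accept/reject rule.

#' Patch-selection filter configuration
#'
#' Inclusive thresholds on the patch features; a patch is accepted iff it
#' passes every rule.
#'
#' @param min_nucleus_count Minimum nuclei per 512x512 tile.
#' @param h_density_range Allowed `[lo, hi]` mean hematoxylin OD of nuclei.
#' @param max_axis_ratio_mean Maximum mean major/minor axis ratio.
#' @param min_tissue_fraction Minimum usable-tissue fraction of the tile.
#' @param nucleus_area_range Component area bounds `[min, max]` in pixels;
#'   components outside are discarded during segmentation.
#' @return A `wsi_patch_filter` list.
#' @export
patch_filter_config <- function(min_nucleus_count = 20,
                                h_density_range = c(0.15, 1.2),
                                max_axis_ratio_mean = 4,
                                min_tissue_fraction = 0.5,
                                nucleus_area_range = c(40, 3000)) {
  stopifnot(
    h_density_range[1] < h_density_range[2],
    nucleus_area_range[1] <= nucleus_area_range[2],
    min_nucleus_count >= 0
  )
  structure(
    list(
      min_nucleus_count = min_nucleus_count,
      h_density_range = h_density_range,
      max_axis_ratio_mean = max_axis_ratio_mean,
      min_tissue_fraction = min_tissue_fraction,
      nucleus_area_range = nucleus_area_range
    ),
    class = "wsi_patch_filter"
  )
}

#' Segment nuclei in a hematoxylin density map
#'
#' Thresholds the map (Otsu over positive densities, fixed fallback when
#' the histogram collapses), fills holes, splits touching nuclei by
#' distance-transform watershed, and drops components outside the
#' configured area range. Ellipse axes come from second image moments.
#'
#' @param h_map Matrix of hematoxylin densities from [deconvolve()].
#' @param cfg A [patch_filter_config()].
#' @return Tibble with one row per nucleus: `x`, `y` (0-based pixel
#'   centroid), `area_px`, `major_axis_px`, `minor_axis_px`, `axis_ratio`,
#'   `mean_h_density`. Zero rows is a valid result.
#' @export
#' @examples
#' tl <- synthetic_tile(n_nuclei = 10, min_separation = 50, seed = 2)
#' nrow(segment_nuclei(deconvolve(tl$tile)$h))
segment_nuclei <- function(h_map, cfg = patch_filter_config()) {
  thr <- otsu_threshold(clamp(h_map, 0, 1))
  if (is.na(thr) || thr < 0.1) thr <- 0.15  # fallback on collapsed histograms
  mask <- h_map > thr
  empty <- tibble(
    x = numeric(0), y = numeric(0), area_px = numeric(0),
    major_axis_px = numeric(0), minor_axis_px = numeric(0),
    axis_ratio = numeric(0), mean_h_density = numeric(0)
  )
  if (!any(mask)) return(empty)
  img <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(img)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 3)
  labm <- matrix(as.integer(lab), nrow(h_map), ncol(h_map))
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas >= cfg$nucleus_area_range[1] & areas <= cfg$nucleus_area_range[2])
  if (length(keep) == 0) return(empty)

  mom <- EBImage::computeFeatures.moment(lab)
  idx <- labm > 0 & labm %in% keep
  hsum <- tapply(h_map[labm > 0], labm[labm > 0], mean)
  major <- mom[keep, "m.majoraxis"]
  ecc <- mom[keep, "m.eccentricity"]
  minor <- major * sqrt(pmax(1 - ecc^2, 1e-9))
  tibble(
    # computeFeatures.moment reports centroids in the first/second array
    # dimension; dim 1 is the image row (our y), dim 2 the column (x)
    x = unname(mom[keep, "m.cy"]) - 1,
    y = unname(mom[keep, "m.cx"]) - 1,
    area_px = as.numeric(areas[keep]),
    major_axis_px = unname(major),
    minor_axis_px = unname(minor),
    axis_ratio = unname(major / pmax(minor, 1e-9)),
    mean_h_density = as.numeric(hsum[as.character(keep)])
  )
}

#' Compute patch-selection features for a tile
#'
#' Runs stain deconvolution and nuclei segmentation and aggregates the
#' per-nucleus measurements into the patch feature set used by
#' [accept_patch()]. Deterministic for fixed input bytes.
#'
#' @param tile RGB array (512x512x3 in the standard pipeline).
#' @param usable_fraction Usable-tissue fraction of this tile's footprint
#'   from [tile_usable_fraction()].
#' @param cfg A [patch_filter_config()].
#' @param stain Stain matrix for deconvolution.
#' @return One-row tibble: `nucleus_count`, `staining_density`,
#'   `axis_ratio_mean`, `axis_ratio_max`, `tissue_fraction`. Density and
#'   ratio aggregates are 0 when no nucleus is found.
#' @export
compute_patch_features <- function(tile, usable_fraction = 1,
                                   cfg = patch_filter_config(),
                                   stain = stain_matrix_he()) {
  assert_rgb(tile, "tile")
  nuc <- segment_nuclei(deconvolve(tile, stain)$h, cfg)
  tibble(
    nucleus_count = nrow(nuc),
    staining_density = if (nrow(nuc)) mean(nuc$mean_h_density) else 0,
    axis_ratio_mean = if (nrow(nuc)) mean(nuc$axis_ratio) else 0,
    axis_ratio_max = if (nrow(nuc)) max(nuc$axis_ratio) else 0,
    tissue_fraction = usable_fraction
  )
}

#' Accept or reject patches on their features
#'
#' The conjunction of the four inclusive threshold rules; `reason` names
#' the first failed criterion in the fixed order tissue, nuclei count,
#' staining density, axis ratio (or `"ok"`).
#'
#' @param features Tibble of patch features (rows from
#'   [compute_patch_features()]).
#' @param cfg A [patch_filter_config()].
#' @return `features` with logical `accepted` and character `reason`
#'   columns appended.
#' @export
accept_patch <- function(features, cfg = patch_filter_config()) {
  features %>%
    mutate(
      reason = case_when(
        .data$tissue_fraction < cfg$min_tissue_fraction ~ "insufficient_tissue",
        .data$nucleus_count < cfg$min_nucleus_count ~ "insufficient_nuclei",
        .data$staining_density < cfg$h_density_range[1] |
          .data$staining_density > cfg$h_density_range[2] ~ "staining_density_out_of_range",
        .data$axis_ratio_mean > cfg$max_axis_ratio_mean ~ "axis_ratio_too_high",
        TRUE ~ "ok"
      ),
      accepted = .data$reason == "ok"
    )
}
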