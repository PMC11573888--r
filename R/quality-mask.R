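# Slide-level quality control: tissue detection on a thumbnail and masking
# of blood, bubbles, blurred regions and pen marks.

#' Quality-control configuration
#'
#' Thresholds for the tissue and artifact detectors. The tissue detector
#' thresholds the HSV saturation channel (Otsu-refined with a fixed
#' fallback when the histogram is unimodal) inside a non-white luminance
#' band; artifact detectors are rule-based per kind.
#'
#' @param saturation_threshold Fallback saturation floor for tissue.
#' @param white_luminance Luminance at or above which a pixel counts as
#'   bare glass.
#' @param blur_variance_threshold Local Laplacian-variance floor (computed
#'   at `blur_downsample`); tissue below it is flagged blurred.
#' @param blur_window Odd window (pixels) for the local variance.
#' @param pen_hue_ranges List of `[lo, hi]` hue intervals (0-1) for ink.
#' @param pen_saturation Minimum saturation for pen ink.
#' @param pen_residual_min Minimum H&E-reconstruction error for pen ink:
#'   marker colours are not nonnegative hematoxylin+eosin mixtures, so
#'   their optical density reconstructs poorly after clipped
#'   deconvolution, unlike any stained tissue pixel.
#' @param blood_redness_threshold Minimum red dominance `r - max(g, b)`.
#' @param min_tissue_fraction_per_tile Usable fraction a tile needs to be
#'   QC-eligible.
#' @param thumbnail_downsample Downsample factor of the QC thumbnail.
#' @param blur_downsample Finer downsample at which blur is measured.
#' @param speck_min_area Connected components (thumbnail px) smaller than
#'   this are removed from tissue and artifact masks.
#' @return A `wsi_qc_config` list.
#' @export
qc_config <- function(saturation_threshold = 0.08,
                      white_luminance = 0.94,
                      blur_variance_threshold = 2e-4,
                      blur_window = 9L,
                      pen_hue_ranges = list(c(0.22, 0.45), c(0.5, 0.75)),
                      pen_saturation = 0.3,
                      pen_residual_min = 0.05,
                      blood_redness_threshold = 0.25,
                      min_tissue_fraction_per_tile = 0.5,
                      thumbnail_downsample = 32L,
                      blur_downsample = 4L,
                      speck_min_area = 12L) {
  stopifnot(
    saturation_threshold >= 0, saturation_threshold <= 1,
    min_tissue_fraction_per_tile >= 0, min_tissue_fraction_per_tile <= 1,
    blur_variance_threshold >= 0, blood_redness_threshold >= 0
  )
  structure(
    list(
      saturation_threshold = saturation_threshold,
      white_luminance = white_luminance,
      blur_variance_threshold = blur_variance_threshold,
      blur_window = as.integer(blur_window),
      pen_hue_ranges = pen_hue_ranges,
      pen_saturation = pen_saturation,
      pen_residual_min = pen_residual_min,
      blood_redness_threshold = blood_redness_threshold,
      min_tissue_fraction_per_tile = min_tissue_fraction_per_tile,
      thumbnail_downsample = as.integer(thumbnail_downsample),
      blur_downsample = as.integer(blur_downsample),
      speck_min_area = as.integer(speck_min_area)
    ),
    class = "wsi_qc_config"
  )
}

# drop connected components smaller than min_area
remove_specks <- function(mask, min_area) {
  if (!any(mask) || min_area <= 1) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab))
  keep <- which(tab >= min_area)
  matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
}

# per-pixel L2 error of the optical density against its clipped
# (nonnegative) H&E decomposition; near zero for genuinely stained pixels
he_residual_error <- function(rgb, stain = stain_matrix_he()) {
  d <- deconvolve(rgb, stain)
  err2 <- matrix(0, nrow(d$h), ncol(d$h))
  for (c in 1:3) {
    od_hat <- stain[c, 1] * d$h + stain[c, 2] * d$e + stain[c, 3] * d$res
    err2 <- err2 + (rgb_to_od(rgb[, , c]) - od_hat)^2
  }
  sqrt(err2)
}

otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2 || sd(v) < 1e-6) return(NA_real_)
  EBImage::otsu(EBImage::Image(matrix(clamp(v, 0, 1), ncol = 1)), range = c(0, 1))
}

#' Tissue mask from an RGB thumbnail
#'
#' A pixel is tissue iff its saturation exceeds an Otsu-refined threshold
#' (fixed fallback when the saturation histogram is unimodal, e.g. a blank
#' or uniformly stained slide) and its luminance lies below the bare-glass
#' band. Holes are filled and small specks removed.
#'
#' @param thumbnail RGB array in `[0, 1]`.
#' @param cfg A [qc_config()].
#' @return Logical matrix of the thumbnail's shape.
#' @export
compute_tissue_mask <- function(thumbnail, cfg = qc_config()) {
  assert_rgb(thumbnail, "thumbnail")
  hsv <- rgb_to_hsv_maps(thumbnail)
  lum <- luminance(thumbnail)
  thr <- otsu_threshold(hsv$s)
  # Otsu collapses on (near-)unimodal histograms: all-glass or all-tissue
  if (is.na(thr) || thr < cfg$saturation_threshold / 2 || thr > 0.9) {
    thr <- cfg$saturation_threshold
  } else {
    # the refinement is only valid when the low-saturation class really is
    # glass; on a slide with full tissue coverage Otsu splits within
    # tissue, so fall back to the fixed floor
    low <- hsv$s <= thr
    if (!any(low) || mean(lum[low] >= cfg$white_luminance) < 0.5) {
      thr <- cfg$saturation_threshold
    }
  }
  mask <- hsv$s > thr & lum < cfg$white_luminance
  if (any(mask)) {
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
    mask <- remove_specks(mask, cfg$speck_min_area)
  }
  mask
}

local_variance <- function(m, window) {
  k <- matrix(1 / window^2, window, window)
  mu <- as.matrix(EBImage::filter2(EBImage::Image(m), k, boundary = "replicate"))
  mu2 <- as.matrix(EBImage::filter2(EBImage::Image(m * m), k, boundary = "replicate"))
  pmax(mu2 - mu * mu, 0)
}

#' Detect artifact regions on a thumbnail
#'
#' Pen marks via hue windows on saturated ink pixels, blood via red-channel
#' dominance, blurred regions via local Laplacian variance below a floor
#' within tissue, and bubbles as bright low-texture blobs enclosed by
#' tissue. All detectors are threshold rules from [qc_config()]; empty
#' masks are valid outputs.
#'
#' @param thumbnail RGB array in `[0, 1]`; for scale-sensitive blur
#'   detection pass an image at `cfg$blur_downsample` (as
#'   [quality_mask()] does) rather than the coarse QC thumbnail.
#' @param cfg A [qc_config()].
#' @param tissue Optional precomputed tissue mask for this thumbnail.
#' @return Named list of logical masks: `pen`, `blood`, `blur`, `bubble`.
#' @export
detect_artifacts <- function(thumbnail, cfg = qc_config(), tissue = NULL) {
  assert_rgb(thumbnail, "thumbnail")
  if (is.null(tissue)) tissue <- compute_tissue_mask(thumbnail, cfg)
  hsv <- rgb_to_hsv_maps(thumbnail)
  lum <- luminance(thumbnail)
  r <- thumbnail[, , 1]; g <- thumbnail[, , 2]; b <- thumbnail[, , 3]

  pen <- matrix(FALSE, nrow(lum), ncol(lum))
  for (rg in cfg$pen_hue_ranges) {
    pen <- pen | (hsv$h >= rg[1] & hsv$h <= rg[2])
  }
  pen <- pen & hsv$s > cfg$pen_saturation & lum < cfg$white_luminance &
    (r - pmax(g, b)) < cfg$blood_redness_threshold &
    he_residual_error(thumbnail) > cfg$pen_residual_min

  blood <- (r - pmax(g, b)) > cfg$blood_redness_threshold & r > 0.3 & hsv$s > 0.5

  lap <- as.matrix(EBImage::filter2(
    EBImage::Image(lum),
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
    boundary = "replicate"
  ))
  lv <- local_variance(lap, cfg$blur_window)
  blur <- tissue & !pen & !blood & lv < cfg$blur_variance_threshold

  # bubbles: bright blobs enclosed by tissue (not border-connected glass);
  # dilation + hull fill absorbs the dark rim around the bright core
  bright <- lum >= cfg$white_luminance
  bubble <- matrix(FALSE, nrow(lum), ncol(lum))
  if (any(bright)) {
    lab <- EBImage::bwlabel(EBImage::Image(bright * 1))
    labm <- matrix(as.integer(lab), nrow(lum), ncol(lum))
    border_ids <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1], labm[, ncol(labm)]))
    core <- labm > 0 & !(labm %in% border_ids)
    core <- remove_specks(core, cfg$speck_min_area)
    if (any(core)) {
      grown <- EBImage::dilate(EBImage::Image(core * 1),
                               EBImage::makeBrush(11, "disc"))
      bubble <- as.matrix(EBImage::fillHull(grown)) > 0
    }
  }

  lapply(
    list(pen = pen, blood = blood, blur = blur, bubble = bubble),
    remove_specks, min_area = cfg$speck_min_area
  )
}

#' Compute the full quality mask for a slide
#'
#' Runs tissue detection and the artifact detectors on a thumbnail
#' (default 32x downsample). Blur, which is scale-sensitive, is measured
#' on a finer thumbnail (`cfg$blur_downsample`) and pooled onto the QC
#' grid. The usable mask is tissue minus the union of artifacts, exactly.
#'
#' @param slide A `wsi_pyramid`.
#' @param cfg A [qc_config()].
#' @return A `wsi_quality_mask`: thumbnail, `tissue`, per-kind
#'   `artifact_masks`, `usable`, and the thumbnail downsample factor.
#' @export
quality_mask <- function(slide, cfg = qc_config()) {
  # detect at fine resolution (boundaries thin, blur measurable), report on
  # the coarse QC grid
  fine <- slide_thumbnail(slide, cfg$blur_downsample)
  fine_tissue <- compute_tissue_mask(fine, cfg)
  fine_art <- detect_artifacts(fine, cfg, tissue = fine_tissue)

  f <- as.integer(cfg$thumbnail_downsample / cfg$blur_downsample)
  thumb <- pool_array(fine, f)
  tissue <- pool_matrix(fine_tissue * 1, f) > 0.5
  art <- lapply(fine_art, function(m) {
    pooled <- pool_matrix(m * 1, f) > 0.25
    h <- min(nrow(pooled), nrow(tissue)); w <- min(ncol(pooled), ncol(tissue))
    out <- matrix(FALSE, nrow(tissue), ncol(tissue))
    out[seq_len(h), seq_len(w)] <- pooled[seq_len(h), seq_len(w)]
    out
  })
  art$blur <- art$blur & tissue

  usable <- tissue
  for (m in art) usable <- usable & !m
  structure(
    list(
      thumbnail = thumb,
      tissue = tissue,
      artifact_masks = art,
      usable = usable,
      thumbnail_downsample = cfg$thumbnail_downsample,
      cfg = cfg
    ),
    class = "wsi_quality_mask"
  )
}

#' @export
print.wsi_quality_mask <- function(x, ...) {
  fr <- function(m) mean(m)
  cat(sprintf(
    "<wsi_quality_mask> %dx%d @ 1/%d | tissue %.1f%% usable %.1f%% | artifacts: %s\n",
    nrow(x$tissue), ncol(x$tissue), x$thumbnail_downsample,
    100 * fr(x$tissue), 100 * fr(x$usable),
    paste(sprintf("%s %.1f%%", names(x$artifact_masks),
                  100 * vapply(x$artifact_masks, fr, numeric(1))), collapse = ", ")
  ))
  invisible(x)
}

#' Usable fraction of a tile footprint
#'
#' Maps a level-0 tile onto the thumbnail-resolution usable mask and
#' returns the covered usable fraction.
#'
#' @param qmask A [quality_mask()] result.
#' @param x,y Tile top-left at level 0 (0-based).
#' @param size Tile edge at level 0.
#' @return Fraction in `[0, 1]`.
#' @export
tile_usable_fraction <- function(qmask, x, y, size = 512L) {
  ds <- qmask$thumbnail_downsample
  r1 <- floor(y / ds) + 1L
  r2 <- ceiling((y + size) / ds)
  c1 <- floor(x / ds) + 1L
  c2 <- ceiling((x + size) / ds)
  if (r1 < 1 || c1 < 1 || r2 > nrow(qmask$usable) || c2 > ncol(qmask$usable)) {
    abort("tile footprint outside quality-mask extent")
  }
  mean(qmask$usable[r1:r2, c1:c2])
}

#' Per-slide QC summary
#'
#' @param qmask A [quality_mask()].
#' @return One-row tibble of tissue/usable/artifact pixel fractions.
#' @export
qc_summary <- function(qmask) {
  tibble(
    tissue_fraction = mean(qmask$tissue),
    usable_fraction = mean(qmask$usable),
    pen_fraction = mean(qmask$artifact_masks$pen),
    blood_fraction = mean(qmask$artifact_masks$blood),
    blur_fraction = mean(qmask$artifact_masks$blur),
    bubble_fraction = mean(qmask$artifact_masks$bubble)
  )
}
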