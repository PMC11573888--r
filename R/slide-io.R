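# Pyramidal slide I/O: multi-page TIFF reading/writing, magnification
# arithmetic, and candidate tile enumeration. Coordinates are 0-based,
# half-open and level-local; `x` runs along columns, `y` along rows.

new_pyramid <- function(levels, base_magnification, slide_id = NULL, path = NULL) {
  stopifnot(length(levels) >= 1)
  levels <- lapply(levels, to_raw_img) # 1 byte/px/channel in memory
  dims <- t(vapply(levels, function(l) dim(l)[1:2], integer(2)))
  downsample <- round(dims[1, 1] / dims[, 1])
  if (is.unsorted(downsample, strictly = TRUE)) {
    abort("pyramid downsample factors must be strictly increasing")
  }
  structure(
    list(
      levels = levels,
      meta = tibble(
        level = seq_along(levels) - 1L,
        width = as.integer(dims[, 2]),
        height = as.integer(dims[, 1]),
        downsample = downsample
      ),
      base_magnification = base_magnification,
      slide_id = slide_id %||% "slide",
      path = path
    ),
    class = "wsi_pyramid"
  )
}

#' @export
print.wsi_pyramid <- function(x, ...) {
  cat(sprintf(
    "<wsi_pyramid> %s: %d level(s), base %dx%d @ %gx\n",
    x$slide_id, nrow(x$meta), x$meta$width[1], x$meta$height[1],
    x$base_magnification
  ))
  print(x$meta)
  invisible(x)
}

#' Write a slide pyramid as a multi-page TIFF
#'
#' One page per pyramid level, largest first. The nominal magnification
#' and slide id are recorded in a small JSON sidecar (`<path>.meta.json`)
#' so [open_slide()] can recover them; slides lacking the sidecar fall
#' back to a configured default magnification with a warning.
#'
#' @param slide A `wsi_pyramid` (e.g. from [generate_slide()]).
#' @param path Output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  tiff::writeTIFF(lapply(slide$levels, to_double_img), path,
                  bits.per.sample = 8L, compression = "LZW")
  jsonlite::write_json(
    list(magnification = slide$base_magnification, slide_id = slide$slide_id),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Open a pyramidal slide
#'
#' Reads every page of a multi-page TIFF into an in-memory pyramid, sorted
#' largest-first. The nominal magnification is parsed from the
#' ImageDescription tag; when absent, a configurable default is assumed
#' with a warning.
#'
#' @param path Path to a multi-page TIFF.
#' @param default_magnification Fallback objective power when the file
#'   carries no magnification tag.
#' @return A `wsi_pyramid`.
#' @export
open_slide <- function(path, default_magnification = 20) {
  if (!file.exists(path)) abort(sprintf("cannot open slide: '%s' does not exist", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) abort(sprintf("cannot read slide '%s': %s", path, conditionMessage(e)))
  )
  if (length(pages) == 0) abort(sprintf("cannot read slide '%s': no pages", path))
  pages <- pages[order(vapply(pages, function(p) -prod(dim(p)[1:2]), numeric(1)))]
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 2L) p <- array(rep(p, 3), c(dim(p), 3))
    if (dim(p)[3] > 3L) p <- p[, , 1:3, drop = FALSE]
    p
  })
  mag <- default_magnification
  slide_id <- sub("\\.tiff?$", "", basename(path))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    mag <- meta$magnification %||% default_magnification
    slide_id <- meta$slide_id %||% slide_id
  } else {
    warn(sprintf("no magnification metadata for '%s'; assuming %gx", path, default_magnification))
  }
  pages <- lapply(pages, function(p) { attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL; p })
  new_pyramid(pages, mag, slide_id = slide_id, path = path)
}

#' Map a target magnification to a pyramid level
#'
#' Chooses the smallest stored level whose effective magnification
#' (base magnification / downsample) is at least the target; the residual
#' scale (`>= 1`) is applied by downscaling read regions.
#'
#' @param slide A `wsi_pyramid`.
#' @param target_mag Requested objective power.
#' @return A list with `level` (0-based) and `residual_scale`.
#' @export
magnification_to_level <- function(slide, target_mag) {
  eff <- slide$base_magnification / slide$meta$downsample
  ok <- which(eff >= target_mag - 1e-9)
  if (length(ok) == 0) abort("upsampling refused: target magnification above base")
  lev <- max(ok) # smallest level still at or above the target power
  list(level = slide$meta$level[lev], residual_scale = eff[lev] / target_mag)
}

#' Enumerate candidate tile coordinates
#'
#' Row-major scan over a pyramid level; partial tiles at the right/bottom
#' edges are dropped.
#'
#' @param slide A `wsi_pyramid`.
#' @param tile_size Tile edge length in pixels at the chosen level.
#' @param stride Scan stride in pixels (default non-overlapping).
#' @param level Pyramid level (0-based).
#' @return A tibble with columns `level`, `x`, `y`, `size` (0-based,
#'   half-open tile footprints).
#' @export
#' @examples
#' sl <- generate_slide(slide_spec(1024, 1024, seed = 1))$slide
#' enumerate_candidates(sl)
enumerate_candidates <- function(slide, tile_size = 512L, stride = 512L, level = 0L) {
  if (stride <= 0) abort("stride must be positive")
  m <- slide$meta[slide$meta$level == level, ]
  if (nrow(m) == 0) abort("no such pyramid level")
  if (tile_size > min(m$width, m$height)) abort("tile_size exceeds level dimensions")
  xs <- seq(0L, m$width - tile_size, by = stride)
  ys <- seq(0L, m$height - tile_size, by = stride)
  tidyr::expand_grid(y = as.integer(ys), x = as.integer(xs)) %>%
    mutate(level = as.integer(level), size = as.integer(tile_size)) %>%
    select("level", "x", "y", "size")
}

#' Read a tile from a slide
#'
#' @param slide A `wsi_pyramid`.
#' @param x,y Top-left corner at the given level, 0-based.
#' @param size Edge length in pixels at the given level.
#' @param level Pyramid level (0-based).
#' @param residual_scale Optional extra downscale factor (from
#'   [magnification_to_level()]); the region read is `size * scale` wide
#'   and is mean-pooled (integer factors) or resized back to `size`.
#' @return A `size x size x 3` RGB array in `[0, 1]`.
#' @export
read_region <- function(slide, x, y, size = 512L, level = 0L, residual_scale = 1) {
  m <- slide$meta[slide$meta$level == level, ]
  if (nrow(m) == 0) abort("no such pyramid level")
  span <- round(size * residual_scale)
  if (x < 0 || y < 0 || x + span > m$width || y + span > m$height) {
    abort(sprintf("region (%d,%d)+%d out of bounds for level %d (%dx%d)",
                  x, y, span, level, m$width, m$height))
  }
  arr <- slide$levels[[which(slide$meta$level == level)]]
  block <- to_double_img(arr[(y + 1):(y + span), (x + 1):(x + span), , drop = FALSE])
  if (residual_scale == 1) return(block)
  if (abs(residual_scale - round(residual_scale)) < 1e-9) {
    return(pool_array(block, as.integer(round(residual_scale))))
  }
  out <- array(0, c(size, size, 3))
  for (c in 1:3) {
    out[, , c] <- as.matrix(EBImage::resize(EBImage::Image(block[, , c]), w = size, h = size))
  }
  out
}

#' Low-resolution thumbnail of a slide
#'
#' Mean-pools the most suitable pyramid level down to the requested
#' downsample factor relative to level 0.
#'
#' @param slide A `wsi_pyramid`.
#' @param downsample Total downsample factor vs level 0.
#' @return An RGB array.
#' @export
slide_thumbnail <- function(slide, downsample = 32L) {
  ds <- slide$meta$downsample
  usable <- which(ds <= downsample & downsample %% ds == 0)
  lev <- if (length(usable)) max(usable) else 1L
  arr <- slide$levels[[lev]]
  f <- as.integer(downsample / ds[lev])
  pool_array(arr, f)
}
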