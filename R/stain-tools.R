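# Colour-space machinery: Beer-Lambert optical density, H&E stain
# deconvolution, and Reinhard-style colour normalization of tissue pixels.

#' Standard H&E stain matrix
#'
#' Columns are unit optical-density vectors for hematoxylin, eosin and a
#' residual channel (the normalized cross product of the first two), using
#' the widely published H&E absorption constants.
#'
#' @return A 3x3 numeric matrix with columns `h`, `e`, `res` and rows
#'   `r`, `g`, `b`; every column has unit Euclidean norm.
#' @export
#' @examples
#' stain_matrix_he()
stain_matrix_he <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(
    h[2] * e[3] - h[3] * e[2],
    h[3] * e[1] - h[1] * e[3],
    h[1] * e[2] - h[2] * e[1]
  )
  m <- cbind(
    h / sqrt(sum(h^2)),
    e / sqrt(sum(e^2)),
    r / sqrt(sum(r^2))
  )
  dimnames(m) <- list(c("r", "g", "b"), c("h", "e", "res"))
  m
}

validate_stain_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3))) {
    abort("stain matrix must be 3x3 (columns = stain OD vectors)")
  }
  if (abs(det(m)) < 1e-8) abort("stain matrix is singular")
  norms <- sqrt(colSums(m^2))
  if (any(abs(norms - 1) > 1e-6)) abort("stain matrix columns must have unit norm")
  invisible(m)
}

#' Convert RGB intensities to optical density
#'
#' Applies the Beer-Lambert transform `od = -log10((i + 1) / 256)` where
#' `i` is the 8-bit intensity. Inputs are RGB values in `[0, 1]` (the
#' convention used throughout the package); full transmission (white) maps
#' to zero density.
#'
#' @param rgb Numeric array/matrix/vector of RGB intensities in `[0, 1]`.
#' @return Optical densities with the same shape, all `>= 0`.
#' @export
rgb_to_od <- function(rgb) {
  -log10((clamp(rgb, 0, 1) * 255 + 1) / 256)
}

#' Inverse of [rgb_to_od()]
#' @param od Nonnegative optical densities.
#' @return RGB intensities in `[0, 1]`.
#' @export
od_to_rgb <- function(od) {
  clamp((256 * 10^(-od) - 1) / 255, 0, 1)
}

#' Render RGB from per-pixel stain densities
#'
#' Forward Beer-Lambert model: given hematoxylin and eosin density maps the
#' per-channel OD is the stain matrix times the density vector, and
#' intensity follows from [od_to_rgb()]. Used by the synthetic-slide
#' generator, and in tests as the oracle that [deconvolve()] must invert.
#'
#' @param d_h,d_e Matrices of nonnegative hematoxylin / eosin densities.
#' @param stain 3x3 stain matrix, see [stain_matrix_he()].
#' @param d_res Optional residual-channel density map (default zero).
#' @return An H x W x 3 RGB array in `[0, 1]`.
#' @export
forward_render <- function(d_h, d_e, stain = stain_matrix_he(), d_res = NULL) {
  validate_stain_matrix(stain)
  out <- array(0, c(dim(d_h), 3))
  # row strips keep temporaries small even for slide-sized density fields
  strip <- 1024L
  for (r0 in seq(1L, nrow(d_h), by = strip)) {
    rows <- r0:min(nrow(d_h), r0 + strip - 1L)
    for (c in 1:3) {
      od <- stain[c, 1] * d_h[rows, , drop = FALSE] +
        stain[c, 2] * d_e[rows, , drop = FALSE]
      if (!is.null(d_res)) od <- od + stain[c, 3] * d_res[rows, , drop = FALSE]
      out[rows, , c] <- od_to_rgb(od)
    }
  }
  out
}

#' Deconvolve an RGB tile into per-stain density maps
#'
#' Unmixes optical densities through the inverse of the stain matrix;
#' negative densities (noise outside the stain simplex) are clipped to 0.
#'
#' @param tile H x W x 3 RGB array in `[0, 1]`.
#' @param stain 3x3 stain matrix (columns hematoxylin, eosin, residual).
#' @return A named list of H x W density matrices: `h`, `e`, `res`.
#' @export
#' @examples
#' tile <- forward_render(matrix(0.6, 8, 8), matrix(0.2, 8, 8))
#' d <- deconvolve(tile)
#' range(d$h)
deconvolve <- function(tile, stain = stain_matrix_he()) {
  assert_rgb(tile, "tile")
  validate_stain_matrix(stain)
  d <- dim(tile)
  od <- cbind(
    as.vector(rgb_to_od(tile[, , 1])),
    as.vector(rgb_to_od(tile[, , 2])),
    as.vector(rgb_to_od(tile[, , 3]))
  )
  dens <- od %*% t(solve(stain))
  dens[dens < 0] <- 0
  list(
    h = matrix(dens[, 1], d[1], d[2]),
    e = matrix(dens[, 2], d[1], d[2]),
    res = matrix(dens[, 3], d[1], d[2])
  )
}

#' Per-channel Lab statistics of tissue pixels
#'
#' Computes the mean and standard deviation of each CIELAB channel over the
#' masked pixels of a reference image. These statistics are the target of
#' [reinhard_normalize()].
#'
#' @param tile H x W x 3 RGB array in `[0, 1]`.
#' @param tissue_mask Logical H x W matrix marking tissue pixels.
#' @return A tibble with columns `channel`, `mean`, `sd` (3 rows: L, a, b).
#' @export
reference_stats <- function(tile, tissue_mask) {
  assert_rgb(tile, "tile")
  if (!any(tissue_mask)) abort("tissue_mask selects no pixels")
  px <- cbind(
    tile[, , 1][tissue_mask],
    tile[, , 2][tissue_mask],
    tile[, , 3][tissue_mask]
  )
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  sds <- apply(lab, 2, sd)
  sds[sds <= 0] <- 1e-6
  tibble(
    channel = c("L", "a", "b"),
    mean = colMeans(lab),
    sd = sds
  )
}

#' Reinhard-style colour normalization of tissue pixels
#'
#' Shifts and rescales each Lab channel of the masked (tissue) pixels so
#' their mean and standard deviation match the reference statistics;
#' non-tissue pixels are left untouched and the result is clipped to valid
#' RGB. The transform is deterministic and idempotent.
#'
#' @param tile H x W x 3 RGB array in `[0, 1]`.
#' @param tissue_mask Logical H x W matrix; if it selects no pixels the
#'   tile is returned unchanged with a warning.
#' @param ref Reference statistics from [reference_stats()].
#' @return The normalized tile, same shape as the input.
#' @export
reinhard_normalize <- function(tile, tissue_mask, ref) {
  assert_rgb(tile, "tile")
  if (!any(tissue_mask)) {
    warn("tissue_mask selects no pixels; tile returned unchanged")
    return(tile)
  }
  px <- cbind(
    tile[, , 1][tissue_mask],
    tile[, , 2][tissue_mask],
    tile[, , 3][tissue_mask]
  )
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  mu <- colMeans(lab)
  sds <- apply(lab, 2, sd)
  sds[sds <= 0] <- 1e-6
  for (c in 1:3) {
    lab[, c] <- (lab[, c] - mu[c]) / sds[c] * ref$sd[c] + ref$mean[c]
  }
  out_px <- clamp(grDevices::convertColor(lab, from = "Lab", to = "sRGB"), 0, 1)
  out <- tile
  for (c in 1:3) {
    ch <- out[, , c]
    ch[tissue_mask] <- out_px[, c]
    out[, , c] <- ch
  }
  out
}
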