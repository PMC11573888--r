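# Seeded synthetic H&E-like slide generator with ground-truth masks.
# Slides are rendered through the Beer-Lambert forward model from
# hematoxylin/eosin density fields, so stain deconvolution downstream is
# exactly invertible up to 8-bit quantization.

#' Rectangular polygon helper
#'
#' @param x,y Top-left corner in base-level pixels (0-based).
#' @param w,h Width and height in pixels.
#' @return An `n x 2` matrix of `(x, y)` vertices.
#' @export
poly_rect <- function(x, y, w, h) {
  cbind(x = c(x, x + w, x + w, x), y = c(y, y, y + h, y + h))
}

#' Artifact region descriptor
#'
#' @param kind One of `"blur"`, `"pen"`, `"blood"`, `"bubble"`.
#' @param x,y,w,h Axis-aligned region in base-level pixels (0-based).
#' @param color Optional ink colour for pen marks (`"green"` or `"blue"`).
#' @export
artifact_region <- function(kind = c("blur", "pen", "blood", "bubble"),
                            x, y, w, h, color = "green") {
  kind <- match.arg(kind)
  list(kind = kind, x = x, y = y, w = w, h = h, color = color)
}

#' Synthetic slide specification
#'
#' @param width_px,height_px Base-level dimensions (each `>= 1024`).
#' @param base_magnification Nominal objective power of level 0.
#' @param tissue_polygons List of `n x 2` vertex matrices in base pixels;
#'   the default is a single square covering the slide minus a margin.
#' @param artifacts List of [artifact_region()] descriptors.
#' @param phenotype A [phenotype_spec()] controlling nuclei rendering.
#' @param background_eosin Faint eosin density of the glass background.
#' @param tissue_eosin Mean eosin density of cytoplasm.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `wsi_slide_spec` list.
#' @export
slide_spec <- function(width_px = 4096, height_px = 4096,
                       base_magnification = 20,
                       tissue_polygons = NULL,
                       artifacts = list(),
                       phenotype = phenotype_preset("BRAF"),
                       background_eosin = 0.012,
                       tissue_eosin = 0.35,
                       seed = 1L) {
  if (is.null(tissue_polygons)) {
    m <- round(min(width_px, height_px) * 0.06)
    tissue_polygons <- list(poly_rect(m, m, width_px - 2 * m, height_px - 2 * m))
  }
  spec <- structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      base_magnification = base_magnification,
      tissue_polygons = tissue_polygons,
      artifacts = artifacts,
      phenotype = phenotype,
      background_eosin = background_eosin,
      tissue_eosin = tissue_eosin,
      seed = as.integer(seed)
    ),
    class = "wsi_slide_spec"
  )
  validate_slide_spec(spec)
  spec
}

validate_slide_spec <- function(spec) {
  if (min(spec$width_px, spec$height_px) < 1024) abort("slide too small for tiling")
  for (a in spec$artifacts) {
    if (a$x < 0 || a$y < 0 || a$x + a$w > spec$width_px || a$y + a$h > spec$height_px) {
      abort(sprintf("artifact '%s' region exceeds image bounds", a$kind))
    }
  }
  if (!inherits(spec$phenotype, "wsi_phenotype")) abort("phenotype must be a wsi_phenotype")
  invisible(spec)
}

# even-odd scanline polygon fill at pixel centers (0-based coordinates)
rasterize_polygon <- function(poly, width, height) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  mask <- matrix(FALSE, height, width)
  rmin <- max(1L, floor(min(ys)) + 1L)
  rmax <- min(height, ceiling(max(ys)) + 1L)
  if (rmin > rmax) return(mask)
  for (row in rmin:rmax) {
    yc <- row - 1
    cross <- ((ys <= yc) & (y2 > yc)) | ((y2 <= yc) & (ys > yc))
    if (!any(cross)) next
    xint <- sort(xs[cross] + (yc - ys[cross]) / (y2[cross] - ys[cross]) *
                   (x2[cross] - xs[cross]))
    for (k in seq(1, length(xint) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xint[k]) + 1L)
      c2 <- min(width, floor(xint[k + 1]) + 1L)
      if (c1 <= c2) mask[row, c1:c2] <- TRUE
    }
  }
  mask
}

rasterize_polygons <- function(polys, width, height) {
  mask <- matrix(FALSE, height, width)
  for (p in polys) mask <- mask | rasterize_polygon(p, width, height)
  mask
}

rect_mask <- function(a, width, height) {
  m <- matrix(FALSE, height, width)
  rows <- (max(0, a$y):min(height - 1, a$y + a$h - 1)) + 1L
  cols <- (max(0, a$x):min(width - 1, a$x + a$w - 1)) + 1L
  m[rows, cols] <- TRUE
  m
}

# sample nuclei centroids (0-based x, y) within the allowed mask
place_nuclei <- function(n, domain_idx, width, height, phen) {
  if (n == 0L || length(domain_idx) == 0L) {
    return(tibble(x = numeric(0), y = numeric(0)))
  }
  pick_uniform <- function(k) {
    idx <- domain_idx[sample.int(length(domain_idx), k, replace = TRUE)]
    tibble(x = ((idx - 1) %/% height), y = ((idx - 1) %% height))
  }
  s <- phen$arrangement_strength
  arranged <- if (phen$arrangement == "uniform") 0L else rbinom(1, n, s)
  uniform_part <- pick_uniform(n - arranged)
  if (arranged == 0L) return(uniform_part)

  x <- y <- numeric(0)
  remaining <- arranged
  if (phen$arrangement == "papillary_clusters") {
    # uniform-disk clusters, ~420 px^2 per nucleus so neighbours rarely merge
    while (remaining > 0) {
      ctr <- pick_uniform(1)
      k <- min(remaining, 15L)
      rr <- 45 * sqrt(runif(k))
      ang <- runif(k, 0, 2 * pi)
      x <- c(x, ctr$x + rr * cos(ang))
      y <- c(y, ctr$y + rr * sin(ang))
      remaining <- remaining - k
    }
  } else { # follicular_rings: evenly spaced nuclei along ring perimeters
    while (remaining > 0) {
      ctr <- pick_uniform(1)
      r <- runif(1, 25, 45)
      cap <- max(6L, round(2 * pi * r / 13))
      k <- min(remaining, cap)
      ang <- runif(1, 0, 2 * pi) + (seq_len(k) - 1) / cap * 2 * pi + rnorm(k, 0, 0.03)
      rr <- r + rnorm(k, 0, 2)
      x <- c(x, ctr$x + rr * cos(ang))
      y <- c(y, ctr$y + rr * sin(ang))
      remaining <- remaining - k
    }
  }
  # keep arranged points that fall in the allowed domain, resample the rest
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & xi < width & yi >= 0 & yi < height
  idx <- yi[ok] + 1 + xi[ok] * height
  inside <- logical(length(x))
  dom <- logical(width * height)
  dom[domain_idx] <- TRUE
  inside[ok] <- dom[idx]
  kept <- tibble(x = x[inside], y = y[inside])
  bind_rows(kept, uniform_part, pick_uniform(arranged - nrow(kept)))
}

# draw per-nucleus geometry and additively render hematoxylin densities
sample_nucleus_geometry <- function(centroids, phen) {
  n <- nrow(centroids)
  centroids %>%
    mutate(
      radius = clamp(rnorm(n, phen$nucleus_radius_px, 0.15 * phen$nucleus_radius_px),
                     3, 3 * phen$nucleus_radius_px),
      axis_ratio = pmax(1, rnorm(n, phen$nucleus_axis_ratio, 0.08 * phen$nucleus_axis_ratio)),
      theta = runif(n, 0, pi),
      h_density = clamp(rnorm(n, 0.85, 0.08), 0.3, 1.4)
    )
}

render_nuclei <- function(dh, nuclei) {
  H <- nrow(dh); W <- ncol(dh)
  for (i in seq_len(nrow(nuclei))) {
    r <- nuclei$radius[i]; a <- nuclei$axis_ratio[i]
    major <- r * sqrt(a); minor <- r / sqrt(a)
    ext <- ceiling(major) + 1
    cx <- nuclei$x[i]; cy <- nuclei$y[i]
    rows <- max(1, floor(cy + 1 - ext)):min(H, ceiling(cy + 1 + ext))
    cols <- max(1, floor(cx + 1 - ext)):min(W, ceiling(cx + 1 + ext))
    dxv <- (cols - 1) - cx
    dyv <- (rows - 1) - cy
    DX <- matrix(dxv, length(rows), length(cols), byrow = TRUE)
    DY <- matrix(dyv, length(rows), length(cols))
    th <- nuclei$theta[i]
    u <- (DX * cos(th) + DY * sin(th)) / major
    v <- (-DX * sin(th) + DY * cos(th)) / minor
    q <- u * u + v * v
    f <- clamp((1 - q) / 0.35, 0, 1)  # soft-edged ellipse profile
    dh[rows, cols] <- pmax(dh[rows, cols], nuclei$h_density[i] * f)
  }
  dh
}

pen_colors <- list(green = c(0.13, 0.46, 0.18), blue = c(0.12, 0.22, 0.62))

# stamp artifacts into the raw-byte base image, region-locally so memory
# stays proportional to the artifact area, not the slide
apply_artifacts <- function(base, spec) {
  H <- dim(base)[1]; W <- dim(base)[2]
  masks <- list()
  for (a in spec$artifacts) {
    rows <- (max(0, a$y):min(H - 1, a$y + a$h - 1)) + 1L
    cols <- (max(0, a$x):min(W - 1, a$x + a$w - 1)) + 1L
    sub <- to_double_img(base[rows, cols, , drop = FALSE])
    nr <- length(rows); nc <- length(cols)
    local_mask <- matrix(TRUE, nr, nc)
    if (a$kind == "pen") {
      ink <- pen_colors[[a$color]] %||% pen_colors$green
      for (c in 1:3) sub[, , c] <- 0.15 * sub[, , c] + 0.85 * ink[c]
    } else if (a$kind == "blood") {
      blob <- matrix(FALSE, nr, nc)
      n_blob <- max(3L, round(a$w * a$h / 80000))
      bx <- runif(n_blob, 0.15, 0.85) * nc
      by <- runif(n_blob, 0.15, 0.85) * nr
      br <- runif(n_blob, 0.12, 0.3) * min(a$w, a$h)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      rr <- matrix(seq_len(nr), nr, nc)
      for (b in seq_len(n_blob)) {
        blob <- blob | ((cc - bx[b])^2 + (rr - by[b])^2 <= br[b]^2)
      }
      red <- c(0.55, 0.05, 0.08)
      for (c in 1:3) {
        ch <- sub[, , c]
        ch[blob] <- 0.1 * ch[blob] + 0.9 * red[c]
        sub[, , c] <- ch
      }
      local_mask <- blob
    } else if (a$kind == "blur") {
      for (c in 1:3) {
        sub[, , c] <- as.matrix(EBImage::gblur(EBImage::Image(sub[, , c]), sigma = 8))
      }
    } else if (a$kind == "bubble") {
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      rr <- matrix(seq_len(nr), nr, nc)
      q <- ((cc - nc / 2) / (nc / 2))^2 + ((rr - nr / 2) / (nr / 2))^2
      inside <- q <= 1
      rim <- q > 0.82 & q <= 1
      for (c in 1:3) {
        ch <- sub[, , c]
        ch[inside] <- 0.96
        ch[rim] <- 0.75
        sub[, , c] <- ch
      }
      local_mask <- inside
    }
    base[rows, cols, ] <- to_raw_img(sub)
    m <- matrix(FALSE, H, W)
    m[rows, cols] <- local_mask
    key <- a$kind
    masks[[key]] <- if (is.null(masks[[key]])) m else masks[[key]] | m
  }
  list(rgb = base, masks = masks)
}

#' Generate a synthetic H&E-like pyramidal slide with ground truth
#'
#' Renders eosin-pink tissue with hematoxylin-dark elliptical nuclei over a
#' near-white glass background through the Beer-Lambert forward model,
#' stamps the requested artifacts, and assembles a two-level image pyramid
#' (base plus 4x downsample). All randomness is governed by `spec$seed`;
#' the same spec yields bit-identical output.
#'
#' @param spec A [slide_spec()].
#' @return A list with elements `slide` (a `wsi_pyramid`, see
#'   [open_slide()]) and `truth` (tissue mask, per-kind artifact masks and
#'   the nuclei centroid table).
#' @export
#' @examples
#' sl <- generate_slide(slide_spec(1024, 1024, seed = 7))
#' sl$slide
#' nrow(sl$truth$nuclei)
generate_slide <- function(spec) {
  validate_slide_spec(spec)
  W <- spec$width_px; H <- spec$height_px
  phen <- spec$phenotype
  with_seed(spec$seed, {
    tissue <- rasterize_polygons(spec$tissue_polygons, W, H)
    art_union <- matrix(FALSE, H, W)
    for (a in spec$artifacts) art_union <- art_union | rect_mask(a, W, H)
    domain <- which(tissue & !art_union)

    n_total <- rpois(1, phen$nucleus_density * sum(tissue) / 512^2)
    centroids <- place_nuclei(n_total, domain, W, H, phen)
    nuclei <- sample_nucleus_geometry(centroids, phen)
    rm(domain)

    # density fields with per-slide stain jitter
    jh <- exp(rnorm(1, 0, phen$stain_jitter))
    je <- exp(rnorm(1, 0, phen$stain_jitter))
    de <- matrix(rnorm(H * W, spec$background_eosin, 0.004), H, W)
    de[tissue] <- spec$tissue_eosin + rnorm(sum(tissue), 0, 0.04)
    de <- pmax(de, 0) * je
    dh <- render_nuclei(matrix(0, H, W), nuclei) * jh

    # render in row strips straight into 8-bit storage; slide-sized double
    # temporaries never exist
    base <- array(as.raw(0), c(H, W, 3))
    strip <- 1024L
    for (r0 in seq(1L, H, by = strip)) {
      rows <- r0:min(H, r0 + strip - 1L)
      base[rows, , ] <- to_raw_img(
        forward_render(dh[rows, , drop = FALSE], de[rows, , drop = FALSE])
      )
    }
    rm(dh, de)

    art <- apply_artifacts(base, spec)
    rm(base)
    lev1 <- to_raw_img(pool_array(art$rgb, 4L))

    slide <- new_pyramid(list(art$rgb, lev1), spec$base_magnification,
                         slide_id = paste0("synthetic_", spec$seed))
    truth <- structure(
      list(
        tissue = tissue,
        artifacts = art$masks,
        nuclei = nuclei,
        spec = spec
      ),
      class = "wsi_truth"
    )
    list(slide = slide, truth = truth)
  })
}

#' Ground-truth nuclei counts per tile
#'
#' Counts rendered nuclei centroids falling in each tile of the default
#' non-overlapping grid; the generator's bookkeeping oracle for
#' segmentation and extraction tests.
#'
#' @param truth Ground truth from [generate_slide()].
#' @param tile_size Tile edge in base pixels.
#' @return A tibble with `x`, `y` (tile top-left, 0-based) and `n_nuclei`.
#' @export
truth_patch_counts <- function(truth, tile_size = 512) {
  spec <- truth$spec
  nx <- spec$width_px %/% tile_size
  ny <- spec$height_px %/% tile_size
  grid <- tidyr::expand_grid(
    y = (seq_len(ny) - 1L) * tile_size,
    x = (seq_len(nx) - 1L) * tile_size
  )
  nuc <- truth$nuclei %>%
    mutate(
      tx = (floor(.data$x) %/% tile_size) * tile_size,
      ty = (floor(.data$y) %/% tile_size) * tile_size
    ) %>%
    count(.data$tx, .data$ty)
  grid %>%
    left_join(nuc, by = c(x = "tx", y = "ty")) %>%
    mutate(n_nuclei = coalesce(.data$n, 0L)) %>%
    select("x", "y", "n_nuclei")
}

#' Render a single synthetic 512x512 H&E tile
#'
#' Small-scale companion to [generate_slide()] used for unit fixtures:
#' renders `n_nuclei` elliptical nuclei over uniform eosin cytoplasm, with
#' optional enforced minimum separation (rejection sampling) so counts are
#' unambiguous.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param size Tile edge in pixels.
#' @param radius,axis_ratio,h_density Nucleus geometry/staining parameters.
#' @param eosin Cytoplasm eosin density (`0` for bare glass).
#' @param noise_sd Pixelwise eosin noise standard deviation.
#' @param min_separation Minimum centroid distance in pixels, or `NULL`.
#' @param margin Keep centroids at least this far from the tile border.
#' @param seed Integer seed.
#' @return List with `tile` (RGB array) and `nuclei` (centroid tibble).
#' @export
#' @examples
#' tl <- synthetic_tile(n_nuclei = 12, min_separation = 40, seed = 3)
#' nrow(tl$nuclei)
synthetic_tile <- function(n_nuclei = 30, size = 512, radius = 7,
                           axis_ratio = 1.2, h_density = 0.85,
                           eosin = 0.35, noise_sd = 0.03,
                           min_separation = NULL, margin = 24, seed = 1L) {
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_nuclei && tries < 20000L) {
      tries <- tries + 1L
      px <- runif(1, margin, size - 1 - margin)
      py <- runif(1, margin, size - 1 - margin)
      if (!is.null(min_separation) && length(xs) > 0 &&
          min(sqrt((xs - px)^2 + (ys - py)^2)) < min_separation) next
      xs <- c(xs, px); ys <- c(ys, py)
    }
    if (length(xs) < n_nuclei) abort("could not place nuclei at requested separation")
    n <- length(xs)
    nuclei <- tibble(
      x = xs, y = ys,
      radius = clamp(rnorm(n, radius, 0.1 * radius), 3, 3 * radius),
      axis_ratio = pmax(1, rnorm(n, axis_ratio, 0.05 * axis_ratio)),
      theta = runif(n, 0, pi),
      h_density = clamp(rnorm(n, h_density, 0.05), 0.2, 1.4)
    )
    de <- pmax(matrix(rnorm(size * size, eosin, noise_sd), size, size), 0)
    dh <- render_nuclei(matrix(0, size, size), nuclei)
    list(tile = quantize8(forward_render(dh, de)), nuclei = nuclei)
  })
}
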