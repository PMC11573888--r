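# Per-slide patch extraction (cap 300), per-sample sampling for the three
# roles (200 for training), and the dihedral-8 training augmentation with
# 2 variants selected per patch.

#' Sampler configuration
#'
#' @param per_slide_cap Maximum accepted patches extracted per slide.
#' @param per_sample_train Patches sampled per sample for training (and
#'   the per-sample quota for validation/test).
#' @param augment_select Augmented variants kept per training patch.
#' @param seed Integer seed; per-slide RNG streams are derived from it so
#'   results do not depend on processing order.
#' @export
sampler_config <- function(per_slide_cap = 300L, per_sample_train = 200L,
                           augment_select = 2L, seed = 1L) {
  stopifnot(augment_select <= 8L, per_sample_train <= per_slide_cap)
  structure(
    list(
      per_slide_cap = as.integer(per_slide_cap),
      per_sample_train = as.integer(per_sample_train),
      augment_select = as.integer(augment_select),
      seed = as.integer(seed)
    ),
    class = "wsi_sampler_config"
  )
}

dihedral_tags <- c("identity", "rot90", "rot180", "rot270",
                   "flip_h", "flip_v", "transpose", "anti_transpose")

rot90_mat <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_dihedral_mat <- function(m, tag) {
  switch(tag,
    identity = m,
    rot90 = rot90_mat(m),
    rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    rot270 = rot90_mat(rot90_mat(rot90_mat(m))),
    flip_h = m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v = m[rev(seq_len(nrow(m))), , drop = FALSE],
    transpose = t(m),
    anti_transpose = rot90_mat(rot90_mat(t(m))),
    abort(sprintf("unknown dihedral tag '%s'", tag))
  )
}

#' Apply one dihedral symmetry to a tile
#'
#' @param tile Square RGB array (or matrix).
#' @param tag One of `identity`, `rot90`, `rot180`, `rot270`, `flip_h`,
#'   `flip_v`, `transpose`, `anti_transpose`. `rot90` is a counter-
#'   clockwise quarter turn; `flip_h` mirrors left-right, `flip_v`
#'   top-bottom.
#' @return The transformed tile.
#' @export
apply_dihedral <- function(tile, tag) {
  if (is.matrix(tile)) {
    if (nrow(tile) != ncol(tile)) abort("dihedral variants require a square tile")
    return(apply_dihedral_mat(tile, tag))
  }
  assert_rgb(tile, "tile")
  if (dim(tile)[1] != dim(tile)[2]) abort("dihedral variants require a square tile")
  out <- array(0, dim(tile))
  for (c in seq_len(dim(tile)[3])) out[, , c] <- apply_dihedral_mat(tile[, , c], tag)
  out
}

#' All 8 dihedral variants of a square tile
#'
#' The elements of the dihedral group D4 (4 rotations x optional flip) in
#' the fixed tag order used throughout the package.
#'
#' @param tile Square RGB array.
#' @return Named list of 8 tiles.
#' @export
#' @examples
#' v <- dihedral_variants(array(runif(4 * 4 * 3), c(4, 4, 3)))
#' names(v)
dihedral_variants <- function(tile) {
  setNames(lapply(dihedral_tags, function(tg) apply_dihedral(tile, tg)), dihedral_tags)
}

#' Extract accepted patches from one slide
#'
#' Iterates [enumerate_candidates()] in scan order, skips tiles whose
#' usable fraction is below the filter's minimum, computes patch features
#' for the rest and applies [accept_patch()], stopping once
#' `per_slide_cap` acceptances have been collected. With `cap_random =
#' TRUE` all qualifying tiles are gathered first and the cap is drawn as
#' a seeded random subset instead of scan order.
#'
#' @param slide A `wsi_pyramid`.
#' @param qmask Quality mask from [quality_mask()] (computed when `NULL`).
#' @param filter_cfg A [patch_filter_config()].
#' @param sampler_cfg A [sampler_config()] (only `per_slide_cap`, `seed`
#'   are used here).
#' @param target_mag Magnification at which tiles are read.
#' @param stain Stain matrix for feature deconvolution.
#' @param normalizer Optional [reference_stats()] tibble; when supplied,
#'   every tile is Reinhard-normalized before feature computation.
#' @param cap_random Cap by seeded random draw instead of scan order.
#' @return Tibble of accepted patch records: `slide_id`, `level`, `x`,
#'   `y`, `size` plus the feature columns; `<= per_slide_cap` rows. Zero
#'   acceptances yield an empty tibble with a warning.
#' @export
extract_patches <- function(slide, qmask = NULL,
                            filter_cfg = patch_filter_config(),
                            sampler_cfg = sampler_config(),
                            target_mag = 20,
                            stain = stain_matrix_he(),
                            normalizer = NULL,
                            cap_random = FALSE) {
  if (is.null(qmask)) qmask <- quality_mask(slide)
  sel <- magnification_to_level(slide, target_mag)
  cand <- enumerate_candidates(slide,
    tile_size = 512L, stride = 512L, level = sel$level
  )
  cap <- sampler_cfg$per_slide_cap
  records <- vector("list", nrow(cand))
  n_acc <- 0L
  for (i in seq_len(nrow(cand))) {
    if (!cap_random && n_acc >= cap) break
    x <- cand$x[i]; y <- cand$y[i]
    # usable fraction is defined on the level-0 footprint
    ds <- slide$meta$downsample[slide$meta$level == sel$level]
    uf <- tile_usable_fraction(qmask, x * ds, y * ds, 512L * ds * sel$residual_scale)
    if (uf < filter_cfg$min_tissue_fraction) next
    tile <- read_region(slide, x, y, 512L, sel$level, sel$residual_scale)
    if (!is.null(normalizer)) {
      tmask <- luminance(tile) < qmask$cfg$white_luminance
      if (any(tmask)) tile <- reinhard_normalize(tile, tmask, normalizer)
    }
    feats <- accept_patch(
      compute_patch_features(tile, uf, filter_cfg, stain), filter_cfg
    )
    if (!feats$accepted) next
    n_acc <- n_acc + 1L
    records[[i]] <- bind_cols(
      tibble(slide_id = slide$slide_id, level = cand$level[i], x = x, y = y, size = 512L),
      feats
    )
  }
  out <- bind_rows(records)
  if (nrow(out) == 0) {
    warn(sprintf("no patches accepted for slide '%s'", slide$slide_id))
    return(tibble(
      slide_id = character(0), level = integer(0), x = integer(0),
      y = integer(0), size = integer(0), nucleus_count = integer(0),
      staining_density = numeric(0), axis_ratio_mean = numeric(0),
      axis_ratio_max = numeric(0), tissue_fraction = numeric(0),
      reason = character(0), accepted = logical(0)
    ))
  }
  if (cap_random && nrow(out) > cap) {
    keep <- with_seed(derive_seed(sampler_cfg$seed, slide$slide_id, "cap"),
                      sort(sample.int(nrow(out), cap)))
    out <- out[keep, ]
  }
  out
}

#' Sample a sample's patches for a split role
#'
#' Seeded uniform sampling without replacement of up to
#' `per_sample_train` patches. For the training role each selected patch
#' additionally receives `augment_select` dihedral tags drawn without
#' replacement from the 8 (identity eligible), one output row per
#' variant; validation and test patches are returned unaugmented
#' (`augmentation_tag` is `NA`).
#'
#' @param patches Patch records of one sample (from [extract_patches()]).
#' @param role `"train"`, `"validation"` or `"test"`.
#' @param cfg A [sampler_config()].
#' @return Tibble of patch records with an `augmentation_tag` column.
#' @export
sample_for_split <- function(patches, role = c("train", "validation", "test"),
                             cfg = sampler_config()) {
  role <- match.arg(role)
  if (nrow(patches) == 0) return(mutate(patches, augmentation_tag = character(0)))
  sid <- patches$slide_id[1]
  n_pick <- min(cfg$per_sample_train, nrow(patches))
  with_seed(derive_seed(cfg$seed, sid, "sample", role), {
    picked <- patches[sort(sample.int(nrow(patches), n_pick)), ]
    if (role == "train") {
      tags <- lapply(seq_len(n_pick), function(i) {
        sample(dihedral_tags, cfg$augment_select, replace = FALSE)
      })
      picked <- picked %>%
        mutate(augmentation_tag = tags) %>%
        tidyr::unnest("augmentation_tag")
    } else {
      picked <- mutate(picked, augmentation_tag = NA_character_)
    }
    picked
  })
}
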