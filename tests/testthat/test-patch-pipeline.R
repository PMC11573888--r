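test_that("dihedral variants realize the 8-element group", {
  withr::with_seed(7, x <- array(runif(16 * 16 * 3), c(16, 16, 3)))
  v <- dihedral_variants(x)
  expect_named(v, c("identity", "rot90", "rot180", "rot270",
                    "flip_h", "flip_v", "transpose", "anti_transpose"))
  # four quarter turns are the identity
  r <- x
  for (i in 1:4) r <- apply_dihedral(r, "rot90")
  expect_identical(r, x)
  # two flips are the identity
  expect_identical(apply_dihedral(apply_dihedral(x, "flip_h"), "flip_h"), x)
  # an asymmetric pattern gives 8 pairwise distinct outputs
  expect_equal(length(unique(lapply(v, as.vector))), 8)
  # a uniform tile is invariant under all 8
  u <- array(0.3, c(8, 8, 3))
  expect_true(all(vapply(dihedral_variants(u), identical, logical(1), u)))
  expect_error(apply_dihedral(array(0, c(4, 8, 3)), "rot90"), "square")
})

test_that("training selection yields 2 variants per patch; evaluation roles stay unaugmented", {
  cfg <- sampler_config(seed = 11)
  p300 <- fake_patches(300)
  tr <- sample_for_split(p300, "train", cfg)
  expect_equal(nrow(tr), 400) # 200 patches x 2 variants
  expect_equal(dplyr::n_distinct(paste(tr$x, tr$y)), 200)
  expect_true(all(table(paste(tr$x, tr$y)) == 2))
  expect_false(any(is.na(tr$augmentation_tag)))
  # the two tags per patch are drawn without replacement
  expect_true(all(tapply(tr$augmentation_tag, paste(tr$x, tr$y),
                         function(t) length(unique(t))) == 2))

  va <- sample_for_split(fake_patches(150), "validation", cfg)
  expect_equal(nrow(va), 150)
  expect_true(all(is.na(va$augmentation_tag)))
  te <- sample_for_split(fake_patches(250), "test", cfg)
  expect_equal(nrow(te), 200)
  expect_true(all(is.na(te$augmentation_tag)))

  # seeded determinism
  expect_identical(tr, sample_for_split(p300, "train", cfg))
})

extraction_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_slide(slide_spec(1536, 1536, seed = 55))
    cache
  }
})

test_that("extraction equals a brute-force sweep of the same predicates", {
  sl <- extraction_slide()
  qm <- quality_mask(sl$slide)
  fcfg <- patch_filter_config()
  got <- extract_patches(sl$slide, qm, fcfg, sampler_config())

  cand <- enumerate_candidates(sl$slide)
  want <- list()
  for (i in seq_len(nrow(cand))) {
    uf <- tile_usable_fraction(qm, cand$x[i], cand$y[i])
    f <- compute_patch_features(read_region(sl$slide, cand$x[i], cand$y[i]), uf, fcfg)
    if (accept_patch(f, fcfg)$accepted) want[[i]] <- c(cand$x[i], cand$y[i])
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(got), nrow(want))
  expect_equal(cbind(got$x, got$y), unname(want))
  expect_true(all(got$accepted))
})

test_that("the per-slide cap truncates in scan order (or by seeded draw)", {
  sl <- extraction_slide()
  qm <- quality_mask(sl$slide)
  all_p <- extract_patches(sl$slide, qm, sampler_cfg = sampler_config(per_slide_cap = 300))
  expect_gte(nrow(all_p), 4)
  cap <- 3L
  capped <- extract_patches(sl$slide, qm,
    sampler_cfg = sampler_config(per_slide_cap = cap, per_sample_train = 2)
  )
  expect_equal(nrow(capped), cap)
  expect_equal(capped[, c("x", "y")], all_p[seq_len(cap), c("x", "y")])
  rnd1 <- extract_patches(sl$slide, qm,
    sampler_cfg = sampler_config(per_slide_cap = cap, per_sample_train = 2, seed = 4),
    cap_random = TRUE
  )
  rnd2 <- extract_patches(sl$slide, qm,
    sampler_cfg = sampler_config(per_slide_cap = cap, per_sample_train = 2, seed = 4),
    cap_random = TRUE
  )
  expect_equal(nrow(rnd1), cap)
  expect_identical(rnd1, rnd2)
})

test_that("an all-glass slide yields zero patches with a warning", {
  sl <- generate_slide(slide_spec(1024, 1024, tissue_polygons = list(), seed = 2))
  qm <- quality_mask(sl$slide)
  expect_warning(out <- extract_patches(sl$slide, qm), "no patches accepted")
  expect_equal(nrow(out), 0)
})

test_that("extraction is deterministic given slide bytes and configs", {
  sl <- extraction_slide()
  a <- extract_patches(sl$slide, quality_mask(sl$slide))
  b <- extract_patches(sl$slide, quality_mask(sl$slide))
  expect_identical(a, b)
})
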