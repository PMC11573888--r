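test_that("a blank tile has no nuclei and zero aggregates", {
  blank <- synthetic_tile(n_nuclei = 0, seed = 1)$tile
  expect_equal(nrow(segment_nuclei(deconvolve(blank)$h)), 0)
  f <- compute_patch_features(blank, 0)
  expect_equal(f$nucleus_count, 0)
  expect_equal(f$staining_density, 0)
})

test_that("non-overlapping nuclei are recovered exactly with accurate centroids", {
  tl <- synthetic_tile(n_nuclei = 12, min_separation = 45, seed = 3)
  nuc <- segment_nuclei(deconvolve(tl$tile)$h)
  expect_equal(nrow(nuc), 12)
  err <- vapply(seq_len(12), function(i) {
    min(sqrt((nuc$x - tl$nuclei$x[i])^2 + (nuc$y - tl$nuclei$y[i])^2))
  }, numeric(1))
  expect_lt(max(err), 3)
})

test_that("moment-based axis ratios are near 1 for circular nuclei", {
  tl <- synthetic_tile(n_nuclei = 5, axis_ratio = 1, min_separation = 80, seed = 4)
  nuc <- segment_nuclei(deconvolve(tl$tile)$h)
  expect_true(all(nuc$axis_ratio >= 1 & nuc$axis_ratio <= 1.15))
})

test_that("patch features recover the rendered parameters", {
  tl <- synthetic_tile(n_nuclei = 30, h_density = 0.8, min_separation = 30, seed = 6)
  f <- compute_patch_features(tl$tile, 1)
  expect_lte(abs(f$nucleus_count - 30), 1)
  expect_gte(f$staining_density, 0.7)
  expect_lte(f$staining_density, 0.9)
  # determinism: identical tile bytes, identical features
  expect_identical(f, compute_patch_features(tl$tile, 1))
})

test_that("count recovery within 1 on at least 95% of non-overlapping tiles", {
  n_tiles <- 40
  ok <- 0
  withr::with_seed(99, ns <- sample(10:35, n_tiles, replace = TRUE))
  for (i in seq_len(n_tiles)) {
    tl <- synthetic_tile(n_nuclei = ns[i], min_separation = 30, seed = 1000 + i)
    det <- nrow(segment_nuclei(deconvolve(tl$tile)$h))
    if (abs(det - ns[i]) <= 1) ok <- ok + 1
  }
  expect_gte(ok / n_tiles, 0.95)
})

test_that("RAS-phenotype tiles show higher axis ratios than BRAF tiles", {
  ratio_of <- function(cls, seed) {
    sl <- generate_slide(slide_spec(1024, 1024, phenotype = phenotype_preset(cls), seed = seed))
    f <- compute_patch_features(read_region(sl$slide, 256, 256), 1)
    f$axis_ratio_mean
  }
  braf <- vapply(1:4, function(s) ratio_of("BRAF", s), numeric(1))
  ras <- vapply(1:4, function(s) ratio_of("RAS", s), numeric(1))
  expect_gt(median(ras), median(braf))
})

test_that("the acceptance rule is an inclusive conjunction with ordered reasons", {
  cfg <- patch_filter_config()
  blank <- tibble::tibble(
    nucleus_count = 0L, staining_density = 0, axis_ratio_mean = 0,
    axis_ratio_max = 0, tissue_fraction = 1
  )
  r <- accept_patch(blank, cfg)
  expect_false(r$accepted)
  expect_equal(r$reason, "insufficient_nuclei")

  # exactly at every boundary: inclusive thresholds accept
  edge <- tibble::tibble(
    nucleus_count = cfg$min_nucleus_count,
    staining_density = cfg$h_density_range[1],
    axis_ratio_mean = cfg$max_axis_ratio_mean,
    axis_ratio_max = cfg$max_axis_ratio_mean,
    tissue_fraction = cfg$min_tissue_fraction
  )
  expect_true(accept_patch(edge, cfg)$accepted)
  edge2 <- dplyr::mutate(edge, staining_density = cfg$h_density_range[2])
  expect_true(accept_patch(edge2, cfg)$accepted)
})

test_that("accept_patch agrees with an independent restatement on a random sweep", {
  cfg <- patch_filter_config()
  withr::with_seed(42, {
    sweep <- tibble::tibble(
      nucleus_count = sample(0:60, 100, replace = TRUE),
      staining_density = runif(100, 0, 1.5),
      axis_ratio_mean = runif(100, 1, 6),
      axis_ratio_max = runif(100, 1, 8),
      tissue_fraction = runif(100)
    )
  })
  got <- accept_patch(sweep, cfg)$accepted
  want <- with(sweep,
    tissue_fraction >= cfg$min_tissue_fraction &
      nucleus_count >= cfg$min_nucleus_count &
      staining_density >= cfg$h_density_range[1] &
      staining_density <= cfg$h_density_range[2] &
      axis_ratio_mean <= cfg$max_axis_ratio_mean
  )
  expect_identical(got, want)
  # monotone in nucleus_count, all else fixed
  more <- dplyr::mutate(sweep, nucleus_count = nucleus_count + 10L)
  expect_true(all(accept_patch(more, cfg)$accepted >= got))
})
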