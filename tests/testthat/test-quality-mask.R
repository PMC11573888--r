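test_that("tissue masking handles the degenerate all-glass and all-tissue cases", {
  white <- array(0.99, c(64, 64, 3))
  expect_false(any(compute_tissue_mask(white)))
  pink <- array(0, c(64, 64, 3))
  pink[, , 1] <- 0.91; pink[, , 2] <- 0.55; pink[, , 3] <- 0.85
  expect_true(all(compute_tissue_mask(pink)))
  expect_error(compute_tissue_mask(matrix(0.5, 8, 8)), "RGB")
})

test_that("tissue mask agrees with generator ground truth", {
  sl <- generate_slide(slide_spec(2048, 2048, seed = 11))
  qm <- quality_mask(sl$slide)
  truth <- wsidriver:::pool_matrix(sl$truth$tissue * 1, qm$thumbnail_downsample) > 0.5
  jacc <- sum(qm$tissue & truth) / sum(qm$tissue | truth)
  expect_gte(jacc, 0.9)
})

artifact_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arts <- list(
        artifact_region("pen", 200, 200, 400, 300, color = "green"),
        artifact_region("blood", 1200, 300, 400, 400),
        artifact_region("blur", 300, 1200, 500, 500),
        artifact_region("bubble", 1300, 1300, 400, 400)
      )
      cache <<- generate_slide(slide_spec(2048, 2048, artifacts = arts, seed = 5))
    }
    cache
  }
})

test_that("artifact detectors recover the rendered artifacts with few false positives", {
  sl <- artifact_slide()
  qm <- quality_mask(sl$slide)
  ds <- qm$thumbnail_downsample
  clean <- wsidriver:::pool_matrix(sl$truth$tissue * 1, ds) > 0.5
  for (k in names(sl$truth$artifacts)) {
    clean <- clean & !(wsidriver:::pool_matrix(sl$truth$artifacts[[k]] * 1, ds) > 0.05)
  }
  for (k in c("pen", "blur")) {
    truth_k <- wsidriver:::pool_matrix(sl$truth$artifacts[[k]] * 1, ds) > 0.5
    recall <- sum(qm$artifact_masks[[k]] & truth_k) / sum(truth_k)
    fp <- sum(qm$artifact_masks[[k]] & clean) / sum(clean)
    expect_gte(recall, 0.8)
    expect_lt(fp, 0.05)
  }
  for (k in c("blood", "bubble")) {
    truth_k <- wsidriver:::pool_matrix(sl$truth$artifacts[[k]] * 1, ds) > 0.5
    expect_gte(sum(qm$artifact_masks[[k]] & truth_k) / sum(truth_k), 0.8)
  }
})

test_that("an artifact-free slide yields empty artifact masks", {
  sl <- generate_slide(slide_spec(1536, 1536, seed = 23))
  qm <- quality_mask(sl$slide)
  expect_true(all(vapply(qm$artifact_masks, function(m) !any(m), logical(1))))
})

test_that("mask algebra holds exactly", {
  qm <- quality_mask(artifact_slide()$slide)
  expect_true(all(qm$tissue[qm$usable])) # usable subset of tissue
  for (m in qm$artifact_masks) expect_false(any(qm$usable & m))
  union_art <- Reduce(`|`, qm$artifact_masks)
  expect_identical(qm$usable, qm$tissue & !union_art)
})

test_that("raising the blur variance floor never shrinks the blur mask", {
  sl <- artifact_slide()
  fine <- slide_thumbnail(sl$slide, 4)
  lo <- detect_artifacts(fine, qc_config(blur_variance_threshold = 1e-4))$blur
  hi <- detect_artifacts(fine, qc_config(blur_variance_threshold = 8e-4))$blur
  expect_true(all(hi[lo])) # lo mask contained in hi mask
})

test_that("tile usable fractions match the constructed footprints", {
  # pen stroke covering exactly the left half of tile (512, 512)
  sl <- generate_slide(slide_spec(
    2048, 2048,
    tissue_polygons = list(poly_rect(0, 0, 2048, 2048)),
    artifacts = list(artifact_region("pen", 512, 512, 256, 512)),
    seed = 14
  ))
  qm <- quality_mask(sl$slide)
  expect_equal(tile_usable_fraction(qm, 0, 0), 1.0, tolerance = 0.02)
  expect_equal(tile_usable_fraction(qm, 512, 512), 0.5, tolerance = 0.05)
  # glass tile on an empty-cornered slide
  sl2 <- generate_slide(slide_spec(
    2048, 2048,
    tissue_polygons = list(poly_rect(1024, 1024, 1024, 1024)), seed = 15
  ))
  qm2 <- quality_mask(sl2$slide)
  expect_equal(tile_usable_fraction(qm2, 0, 0), 0.0)
  expect_error(tile_usable_fraction(qm2, 2000, 2000, 512), "outside")
})

test_that("usable mask agrees with ground truth at default configuration", {
  sl <- artifact_slide()
  qm <- quality_mask(sl$slide)
  ds <- qm$thumbnail_downsample
  truth_usable <- wsidriver:::pool_matrix(sl$truth$tissue * 1, ds) > 0.5
  for (m in sl$truth$artifacts) {
    truth_usable <- truth_usable & !(wsidriver:::pool_matrix(m * 1, ds) > 0.5)
  }
  jacc <- sum(qm$usable & truth_usable) / sum(qm$usable | truth_usable)
  expect_gte(jacc, 0.85)
})
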