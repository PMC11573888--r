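paper_scale_manifest <- function() {
  # 234 single-mutant BRAF + 51 single-mutant RAS + 1 dual mutant
  tibble::tibble(
    patient_id = sprintf("T%03d", 1:286),
    mutation = c(rep("BRAF_V600E", 234), rep("RAS", 51), "both"),
    histology = c(
      rep(c("classical", "follicular_variant", "tall_cell", "other"),
          c(179, 12, 27, 16)),
      rep(c("classical", "follicular_variant", "other"), c(20, 29, 2)),
      "classical"
    )
  )
}

test_that("dual mutants are excluded and both classes retained", {
  m <- paper_scale_manifest()
  f <- filter_cohort(m)
  expect_equal(nrow(f$ras), 51)
  expect_equal(nrow(f$braf_pool), 234)
  expect_equal(f$excluded$patient_id, "T286")
  # no dual mutants -> empty exclusion log
  f2 <- filter_cohort(dplyr::filter(m, mutation != "both"))
  expect_equal(nrow(f2$excluded), 0)
  # degenerate cohorts
  expect_error(filter_cohort(dplyr::mutate(m, mutation = "both")), "empty|unknown")
  expect_error(
    filter_cohort(tibble::tibble(patient_id = c("a", "a"), mutation = c("RAS", "RAS"))),
    "one record per patient"
  )
})

test_that("the matched BRAF subsample has the stated size and histology balance", {
  f <- filter_cohort(paper_scale_manifest())
  # a pool rich enough to match every RAS stratum
  pool <- tibble::tibble(
    patient_id = sprintf("B%03d", 1:200),
    mutation = "BRAF_V600E",
    histology = rep(c("classical", "follicular_variant", "other"), c(100, 80, 20))
  )
  sub <- match_braf_subsample(pool, f$ras, seed = 3)
  expect_equal(nrow(sub), 52)
  # per-stratum counts within 1 of the RAS proportions
  ras_prop <- prop.table(table(f$ras$histology))
  for (h in names(ras_prop)) {
    expect_lte(abs(sum(sub$histology == h) - 52 * ras_prop[[h]]), 1)
  }
  expect_identical(sub, match_braf_subsample(pool, f$ras, seed = 3))
  expect_false(identical(sub$patient_id, match_braf_subsample(pool, f$ras, seed = 4)$patient_id))
  # the realistic BRAF pool cannot fully match follicular variants; the
  # draw still reaches the stated size by backfilling
  w <- testthat::capture_warnings(sub2 <- match_braf_subsample(f$braf_pool, f$ras, seed = 3))
  expect_true(any(grepl("backfilling", w)))
  expect_equal(nrow(sub2), 52)
})

test_that("an empty stratum falls back to the remaining pool with a warning", {
  braf <- tibble::tibble(
    patient_id = sprintf("B%02d", 1:20),
    mutation = "BRAF_V600E",
    histology = "classical"
  )
  ras <- tibble::tibble(
    patient_id = sprintf("R%02d", 1:9),
    mutation = "RAS",
    histology = rep(c("classical", "follicular_variant", "tall_cell"), each = 3)
  )
  w <- testthat::capture_warnings(sub <- match_braf_subsample(braf, ras, seed = 1))
  expect_true(any(grepl("backfilling", w)))
  expect_equal(nrow(sub), 10)
})

test_that("the 60/20/20 split reproduces the published partition sizes", {
  m103 <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:103),
    mutation = rep(c("BRAF_V600E", "RAS"), c(52, 51))
  )
  sp <- split_patients(m103, seed = 1)
  expect_equal(as.integer(table(sp$role)[c("train", "validation", "test")]),
               c(61L, 21L, 21L))
  # partition: each patient exactly one role; both classes in every role
  expect_setequal(sp$patient_id, m103$patient_id)
  expect_false(anyDuplicated(sp$patient_id) > 0)
  expect_true(all(table(sp$role, sp$mutation) > 0))
  expect_identical(sp, split_patients(m103, seed = 1))

  m10 <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:10),
    mutation = rep(c("BRAF_V600E", "RAS"), each = 5)
  )
  expect_equal(as.integer(table(split_patients(m10, seed = 2)$role)[c("train", "validation", "test")]),
               c(6L, 2L, 2L))
  expect_error(split_patients(m103, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("training-plan arithmetic reproduces the published patch and iteration counts", {
  m103 <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:103),
    mutation = rep(c("BRAF_V600E", "RAS"), c(52, 51))
  )
  plan <- compute_training_plan(split_patients(m103, seed = 1))
  expect_equal(plan$n_train_patches, 24400L)
  expect_equal(plan$n_val_patches, 4200L)
  expect_equal(plan$n_test_patches, 4200L)
  expect_equal(plan$iterations, 610000L)
})

test_that("the plan equals brute-force counting of an emitted patch manifest", {
  m <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:12),
    mutation = rep(c("BRAF_V600E", "RAS"), each = 6)
  )
  cfg <- sampler_config(per_slide_cap = 40, per_sample_train = 25, seed = 8)
  sp <- split_patients(m, seed = 8)
  plan <- compute_training_plan(sp, cfg)
  counts <- c(train = 0L, validation = 0L, test = 0L)
  for (i in seq_len(nrow(sp))) {
    emitted <- sample_for_split(fake_patches(40, sp$patient_id[i]), sp$role[i], cfg)
    counts[sp$role[i]] <- counts[sp$role[i]] + nrow(emitted)
    # leakage guard: augmented records only ever appear in training
    if (sp$role[i] != "train") expect_true(all(is.na(emitted$augmentation_tag)))
  }
  expect_equal(unname(counts["train"]), plan$n_train_patches)
  expect_equal(unname(counts["validation"]), plan$n_val_patches)
  expect_equal(unname(counts["test"]), plan$n_test_patches)
})
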