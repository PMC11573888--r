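# shared fixture: separable tiles (dense round nuclei vs sparse elongated)
sep_tiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mk <- function(n, ar, seeds) {
        lapply(seeds, function(s) synthetic_tile(n_nuclei = n, axis_ratio = ar, seed = s)$tile)
      }
      cache <<- list(
        train = c(mk(90, 1.15, 1:20), mk(45, 1.9, 101:120)),
        train_labels = rep(c("BRAF_V600E", "RAS"), each = 20),
        val = c(mk(90, 1.15, 21:26), mk(45, 1.9, 121:126)),
        val_labels = rep(c("BRAF_V600E", "RAS"), each = 6)
      )
    }
    cache
  }
})

sep_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tiles <- sep_tiles()
      model <- build_model(model_config(epochs = 30, seed = 42))
      cache <<- train_classifier(model, tiles$train, tiles$val,
                                 tiles$train_labels, tiles$val_labels)
    }
    cache
  }
})

test_that("the softmax head emits valid seeded-deterministic probabilities", {
  m <- build_model(model_config(epochs = 1, seed = 7))
  expect_lt(n_parameters(m), 1e6) # small scale trains on a desk CPU
  withr::with_seed(1, tiles <- lapply(1:3, function(i) array(runif(512 * 512 * 3), c(512, 512, 3))))
  p <- predict_tiles(m, tiles)
  expect_equal(nrow(p), 3)
  expect_true(all(p$p_ras >= 0 & p$p_ras <= 1))
  expect_equal(p$p_braf + p$p_ras, rep(1, 3), tolerance = 1e-5)
  # rebuilding with the same seed reproduces the outputs exactly
  m2 <- build_model(model_config(epochs = 1, seed = 7))
  expect_identical(predict_tiles(m2, tiles), p)
  expect_error(build_model(model_config(architecture_scale = "tiny")), "arg")
  expect_error(predict_tiles(m, list(array(0.5, c(100, 120, 3)))), "square RGB")
})

test_that("the full-scale architecture builds and runs forward", {
  m <- build_model(model_config(architecture_scale = "full", seed = 1))
  expect_gt(n_parameters(m), 5e5)
  p <- predict_tiles(m, list(array(0.5, c(512, 512, 3))))
  expect_equal(p$p_braf + p$p_ras, 1, tolerance = 1e-5)
})

test_that("model selection is argmin of validation loss with first-on-ties", {
  log1 <- tibble::tibble(val_loss = c(0.9, 0.4, 0.6))
  expect_equal(select_best_epoch(log1), 2L)
  log2 <- tibble::tibble(val_loss = c(0.5, 0.5))
  expect_equal(select_best_epoch(log2), 1L)
})

test_that("training requires both classes", {
  m <- build_model(model_config(epochs = 1, seed = 1))
  tiles <- sep_tiles()
  expect_error(
    train_classifier(m, tiles$train[1:8], tiles$val, rep("RAS", 8), tiles$val_labels),
    "both classes"
  )
})

test_that("the small model overfits separable tiles within 30 epochs", {
  fit <- sep_fit()
  tiles <- sep_tiles()
  pr <- predict_tiles(fit$last_model, tiles$train)
  acc <- mean(ifelse(pr$p_ras >= 0.5, "RAS", "BRAF_V600E") == tiles$train_labels)
  expect_gte(acc, 0.99)
  # the selection rule equals brute-force argmin over the serialized log
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  # learning sanity: validation loss decreases from epoch 1 to the best epoch
  expect_lt(fit$log$val_loss[fit$best_epoch], fit$log$val_loss[1])
})

test_that("inference is deterministic and augmentation-variant outputs stay valid", {
  fit <- sep_fit()
  tl <- sep_tiles()$val[[1]]
  p1 <- predict_tiles(fit, list(tl))
  p2 <- predict_tiles(fit, list(tl))
  expect_identical(p1, p2)
  pr <- predict_tiles(fit, list(apply_dihedral(tl, "rot180")))
  expect_true(pr$p_ras >= 0 && pr$p_ras <= 1)
})

test_that("tidiers summarize the fit", {
  fit <- sep_fit()
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  expect_equal(sum(td$best), 1)
  gl <- glance(fit)
  expect_equal(gl$best_epoch, fit$best_epoch)
  expect_equal(gl$architecture_scale, "small")
})

test_that("occlusion maps have the stated geometry and flag informative regions", {
  fit <- sep_fit()
  # dimension rule, including a non-divisible stride
  h1 <- activation_map(fit, sep_tiles()$val[[1]], occluder_size = 96, stride = 64)
  expect_equal(dim(h1), rep(ceiling((512 - 96) / 64) + 1, 2))
  expect_error(activation_map(fit, sep_tiles()$val[[1]], occluder_size = 600), "occluder")

  # a uniform tile produces a near-uniform map (normalization skipped)
  hu <- activation_map(fit, array(0.85, c(512, 512, 3)))
  expect_lt(max(hu) - min(hu), 0.1)

  # nuclei confined to one quadrant concentrate top-decile saliency there;
  # train a cellularity detector so the predicted class's evidence is the
  # nuclei themselves
  mk <- function(n, seeds) lapply(seeds, function(s) synthetic_tile(n_nuclei = n, seed = s)$tile)
  cell_fit <- train_classifier(
    build_model(model_config(epochs = 20, seed = 3)),
    c(mk(40, 1:8), mk(0, 11:18)), c(mk(40, 21:22), mk(0, 31:32)),
    rep(c("RAS", "BRAF_V600E"), each = 8), rep(c("RAS", "BRAF_V600E"), each = 2)
  )
  q <- synthetic_tile(n_nuclei = 0, seed = 2)$tile
  dense <- synthetic_tile(n_nuclei = 60, size = 256, margin = 10, seed = 3)$tile
  q[1:256, 1:256, ] <- dense
  # the detector must read the quadrant tile as the cellular class
  expect_gt(predict_tiles(cell_fit, list(q))$p_ras, 0.5)
  # quadrant-sized occluder: top-decile saliency sits on the quadrant
  hm <- activation_map(cell_fit, q, occluder_size = 256, stride = 128)
  hits <- which(hm >= quantile(hm, 0.9), arr.ind = TRUE)
  frac_in_quadrant <- mean(hits[, 1] == 1 & hits[, 2] == 1)
  expect_gte(frac_in_quadrant, 0.6)
})

test_that("a classifier round-trips through its checkpoint files", {
  fit <- sep_fit()
  path <- withr::local_tempfile()
  save_classifier(fit, path)
  back <- load_classifier(path)
  tl <- sep_tiles()$val[1:2]
  expect_identical(predict_tiles(back, tl), predict_tiles(fit, tl))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$best_epoch, fit$best_epoch)
})
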