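test_that("percRAS counts tiles at or above the inclusive cutoff", {
  pr <- function(p) perc_ras(tibble::tibble(patient_id = "P1", p_ras = p))$perc_ras
  expect_equal(pr(c(0.9, 0.8, 0.6)), 1.0)
  expect_equal(pr(0.5), 1.0) # inclusive at the cutoff
  expect_equal(pr(c(0.6, 0.4, 0.9)), 2 / 3)
  expect_error(perc_ras(tibble::tibble(patient_id = character(0), p_ras = numeric(0))),
               "no tiles")
})

test_that("percRAS equals brute-force tile counting for every patient", {
  withr::with_seed(5, {
    tp <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:15), 400, replace = TRUE),
      p_ras = round(runif(400), 2)
    )
  })
  got <- perc_ras(tp)
  for (i in seq_len(nrow(got))) {
    sub <- tp$p_ras[tp$patient_id == got$patient_id[i]]
    expect_identical(got$n_tiles[i], length(sub))
    expect_equal(got$perc_ras[i], sum(sub >= 0.5) / length(sub))
  }
})

test_that("tumor calls respect the exclusive 0.25/0.75 band edges", {
  expect_equal(classify_tumor(0.8), "RAS")
  expect_equal(classify_tumor(0.1), "BRAF_V600E")
  expect_equal(classify_tumor(0.75), "not_predicted") # 'exceeded' is strict
  expect_equal(classify_tumor(0.25), "not_predicted") # 'below' is strict
  # exhaustive property sweep against an independent predicate
  withr::with_seed(31, s <- c(runif(10000), 0, 0.25, 0.5, 0.75, 1))
  got <- classify_tumor(s)
  want <- ifelse(s > 0.75, "RAS", ifelse(s < 0.25, "BRAF_V600E", "not_predicted"))
  expect_identical(got, want)
})

test_that("rank AUC matches the stated anchors and the all-pairs oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.4), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), n_boot = 0)$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5), n_boot = 0)$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- sample(10:200, 1)
      scores <- round(runif(n), 2) # ties present
      pos <- runif(n) > 0.5
    })
    if (all(pos) || !any(pos)) next
    expect_equal(roc_auc(scores, pos, n_boot = 0)$auc, auc_pairs(scores, pos),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation and bootstrap CI brackets it", {
  skip_if_not_installed("pROC")
  withr::with_seed(2, {
    scores <- runif(80)
    pos <- runif(80) < 0.4 + 0.4 * scores
  })
  ours <- roc_auc(scores, pos, n_boot = 500, seed = 9)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE, direction = "<")))
  expect_equal(ours$auc, ref, tolerance = 1e-9)
  expect_lte(ours$ci_low, ours$auc)
  expect_gte(ours$ci_high, ours$auc)
})

test_that("Fisher's exact test matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_p(matrix(c(3, 1, 1, 3), 2)), 34 / 70, tolerance = 1e-9)
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2)), 2 / 252, tolerance = 1e-9)
  expect_equal(fisher_exact_p(matrix(c(0, 0, 3, 4), 2)), 1) # zero margin
  expect_error(fisher_exact_p(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  for (s in 1:25) {
    tab <- withr::with_seed(s, matrix(rpois(4, 3), 2))
    if (sum(tab) > 30) next
    expect_equal(fisher_exact_p(tab), fisher_enum_p(tab), tolerance = 1e-9)
  }
})

test_that("Spearman matches the closed form on tie-free data", {
  expect_equal(spearman_cor(1:3, c(3, 1, 2))$rho, -0.5)
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(5:60, 1)
      x <- rnorm(n); y <- rnorm(n)
    })
    expect_equal(spearman_cor(x, y)$rho, spearman_d2(x, y), tolerance = 1e-9)
  }
})

eval_fixture <- function(flip = 0, seed = 1) {
  # 40 tumors, 20 tiles each; tile scores concentrated on the true side
  withr::with_seed(seed, {
    truth <- tibble::tibble(
      patient_id = sprintf("P%02d", 1:40),
      mutation = rep(c("BRAF_V600E", "RAS"), each = 20)
    )
    if (flip > 0) truth$mutation <- sample(truth$mutation)
    tp <- tidyr::expand_grid(patient_id = truth$patient_id, tile = 1:20) %>%
      dplyr::inner_join(truth, by = "patient_id") %>%
      dplyr::mutate(p_ras = ifelse(mutation == "RAS",
                                   runif(dplyr::n(), 0.8, 1),
                                   runif(dplyr::n(), 0, 0.2))) %>%
      dplyr::select(patient_id, p_ras)
    if (flip > 0) tp$p_ras <- withr::with_seed(seed + 1, runif(nrow(tp)))
    brs <- tibble::tibble(
      patient_id = truth$patient_id,
      brs = ifelse(truth$mutation == "RAS", 0.5, -0.5)
    )
    list(truth = truth, tiles = tp, brs = brs)
  })
}

test_that("a perfect prediction set scores perfectly", {
  fx <- eval_fixture()
  ev <- evaluate_predictions(fx$tiles, fx$truth, fx$brs, n_boot = 100)
  expect_equal(ev$accuracy_called, 1)
  expect_equal(ev$accuracy_all, 1)
  expect_equal(ev$tumor_auc$auc, 1)
  expect_equal(sum(ev$tumor_confusion) , 40)
  off <- ev$tumor_confusion
  diag_cells <- off["BRAF_V600E", "BRAF_V600E"] + off["RAS", "RAS"]
  expect_equal(unname(diag_cells), 40)
  expect_lt(ev$fisher_p, 1e-6)
  expect_gt(ev$brs$spearman_rho, 0.9)
})

test_that("label-independent predictions give a null-range tumor AUC", {
  fx <- eval_fixture(flip = 1, seed = 6)
  ev <- evaluate_predictions(fx$tiles, fx$truth, n_boot = 0)
  expect_gte(ev$tumor_auc$auc, 0.3)
  expect_lte(ev$tumor_auc$auc, 0.7)
})

test_that("BRS records at exactly zero are excluded from the cross-tab but counted", {
  fx <- eval_fixture()
  fx$brs$brs[1:3] <- 0
  ev <- evaluate_predictions(fx$tiles, fx$truth, fx$brs, n_boot = 0)
  expect_equal(ev$brs$n_zero_excluded, 3)
  expect_equal(sum(ev$brs$crosstab), 37)
})

test_that("disjoint prediction/truth ids are rejected", {
  fx <- eval_fixture()
  truth2 <- dplyr::mutate(fx$truth, patient_id = paste0("X", patient_id))
  expect_error(evaluate_predictions(fx$tiles, truth2), "no overlapping")
})

test_that("evaluation tidiers expose the headline metrics", {
  fx <- eval_fixture()
  ev <- evaluate_predictions(fx$tiles, fx$truth, fx$brs, n_boot = 50)
  td <- tidy(ev)
  expect_true(all(c("tile_auc", "tumor_auc", "fisher_p", "spearman_rho_vs_brs") %in% td$metric))
  gl <- glance(ev)
  expect_equal(gl$tumor_accuracy_called, 1)
  expect_equal(gl$n_tumors, 40)
})
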