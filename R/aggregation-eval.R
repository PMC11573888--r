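# Tumor-level aggregation (percRAS with the 0.25/0.75 decision bands) and
# the evaluation suite: ROC/AUC with bootstrap intervals, confusion
# matrices, Fisher's exact test, Spearman correlation and BRS concordance.

#' Aggregation configuration
#'
#' The single place the decision rules live: a tile counts as RAS when its
#' predicted RAS probability is at or above `tile_ras_cutoff` (inclusive);
#' a tumor is called RAS when its percRAS score strictly exceeds
#' `ras_band_hi`, BRAF when strictly below `braf_band_lo`, and is left
#' unpredicted inside the band (both edges land in the band).
#'
#' @param tile_ras_cutoff Tile-level probability cutoff (inclusive).
#' @param braf_band_lo,ras_band_hi percRAS band edges (exclusive calls).
#' @export
aggregation_config <- function(tile_ras_cutoff = 0.5,
                               braf_band_lo = 0.25,
                               ras_band_hi = 0.75) {
  if (!(braf_band_lo > 0 && braf_band_lo < ras_band_hi && ras_band_hi < 1)) {
    abort("need 0 < braf_band_lo < ras_band_hi < 1")
  }
  structure(
    list(
      tile_ras_cutoff = tile_ras_cutoff,
      braf_band_lo = braf_band_lo,
      ras_band_hi = ras_band_hi
    ),
    class = "wsi_aggregation_config"
  )
}

#' percRAS score per tumor
#'
#' The fraction of a patient's tiles whose predicted RAS probability is at
#' or above the tile cutoff.
#'
#' @param tile_predictions Tibble with `patient_id` and `p_ras`.
#' @param cfg An [aggregation_config()].
#' @return Tibble with `patient_id`, `n_tiles`, `perc_ras`.
#' @export
#' @examples
#' perc_ras(tibble::tibble(patient_id = "P1", p_ras = c(0.6, 0.4, 0.9)))
perc_ras <- function(tile_predictions, cfg = aggregation_config()) {
  if (nrow(tile_predictions) == 0) abort("no tiles for patient")
  if (any(tile_predictions$p_ras < 0 | tile_predictions$p_ras > 1)) {
    abort("p_ras must lie in [0, 1]")
  }
  tile_predictions %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_tiles = dplyr::n(),
      perc_ras = mean(.data$p_ras >= cfg$tile_ras_cutoff),
      .groups = "drop"
    )
}

#' Tumor-level mutation call from a percRAS score
#'
#' @param score Numeric vector of percRAS scores in `[0, 1]`, or a tibble
#'   from [perc_ras()] (a `call` column is appended).
#' @param cfg An [aggregation_config()].
#' @return Character vector (or tibble) with values `"RAS"`,
#'   `"BRAF_V600E"`, `"not_predicted"`.
#' @export
#' @examples
#' classify_tumor(c(0.8, 0.1, 0.75, 0.25))
classify_tumor <- function(score, cfg = aggregation_config()) {
  if (is.data.frame(score)) {
    return(mutate(score, call = classify_tumor(.data$perc_ras, cfg)))
  }
  if (any(score < 0 | score > 1)) abort("percRAS scores must lie in [0, 1]")
  dplyr::case_when(
    score > cfg$ras_band_hi ~ "RAS",
    score < cfg$braf_band_lo ~ "BRAF_V600E",
    TRUE ~ "not_predicted"
  )
}

#' ROC area under the curve with bootstrap interval
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted half; the
#' confidence interval is a seeded percentile bootstrap over units.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical/0-1/two-level vector; `positive` names the
#'   positive level for factors/characters.
#' @param positive Positive label for non-logical inputs.
#' @param n_boot Bootstrap replicates (0 skips the interval).
#' @param conf_level Interval coverage.
#' @param seed Integer seed for resampling.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), n_boot = 0)
roc_auc <- function(scores, labels, positive = "RAS", n_boot = 2000L,
                    conf_level = 0.95, seed = 1L) {
  pos <- if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels == 1
  else labels == positive
  if (length(scores) != length(pos)) abort("scores and labels differ in length")
  if (all(pos) || !any(pos)) abort("both classes must be present for ROC")
  auc_of <- function(s, p) {
    r <- rank(s) # mid-ranks: ties count half
    (sum(r[p]) - sum(p) * (sum(p) + 1) / 2) / (sum(p) * sum(!p))
  }
  est <- auc_of(scores, pos)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(derive_seed(seed, "auc_boot"), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(scores), replace = TRUE)
        if (all(pos[idx]) || !any(pos[idx])) return(NA_real_)
        auc_of(scores[idx], pos[idx])
      }, numeric(1))
    })
    qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(auc = est, ci_low = lo, ci_high = hi,
         n_pos = sum(pos), n_neg = sum(!pos))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param table_2x2 Nonnegative integer 2x2 matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(table_2x2) {
  if (!all(dim(table_2x2) == c(2, 2))) abort("need a 2x2 table")
  if (any(table_2x2 < 0) || any(table_2x2 != round(table_2x2))) {
    abort("cells must be nonnegative integers")
  }
  stats::fisher.test(table_2x2)$p.value
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman rho; the p-value uses the exact permutation
#' distribution for `n <= 9` on tie-free data and the t approximation
#' otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `rho` and `p`.
#' @export
#' @examples
#' spearman_cor(1:3, c(3, 1, 2))$rho
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y differ in length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("rho undefined for a constant vector")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = length(x) <= 9 && !ties)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

brs_class <- function(brs) {
  dplyr::case_when(
    brs < 0 ~ "BRAF_like",
    brs > 0 ~ "RAS_like",
    TRUE ~ "undefined"
  )
}

#' Evaluate predictions against truth
#'
#' Assembles the full evaluation report: tile- and tumor-level AUC with
#' bootstrap intervals, confusion matrices (the tumor-level one includes
#' the `not_predicted` row), Fisher's exact test on the called-tumor 2x2
#' table, per-class and overall accuracies (with and without the
#' unpredicted tumors in the denominator), and — when BRS records are
#' supplied — the Spearman correlation of percRAS against the continuous
#' BRS plus the BRAF-like/RAS-like cross-tabulation (records with BRS
#' exactly 0 are excluded and counted).
#'
#' @param tile_predictions Tibble with `patient_id`, `p_ras`.
#' @param truth Tibble with `patient_id`, `mutation`
#'   (`"BRAF_V600E"`/`"RAS"`).
#' @param brs_records Optional tibble with `patient_id`, `brs` in
#'   `[-1, 1]`.
#' @param cfg An [aggregation_config()].
#' @param n_boot Bootstrap replicates for AUC intervals.
#' @param seed Seed for the bootstrap.
#' @return A `wsi_eval` object; see [tidy.wsi_eval()] / [glance.wsi_eval()].
#' @export
evaluate_predictions <- function(tile_predictions, truth, brs_records = NULL,
                                 cfg = aggregation_config(),
                                 n_boot = 2000L, seed = 1L) {
  joined <- inner_join(tile_predictions, truth, by = "patient_id")
  if (nrow(joined) == 0) abort("no overlapping patient ids between predictions and truth")

  tumor <- classify_tumor(perc_ras(joined, cfg), cfg) %>%
    inner_join(truth, by = "patient_id")

  tile_auc <- roc_auc(joined$p_ras, joined$mutation, "RAS", n_boot, seed = seed)
  tumor_auc <- roc_auc(tumor$perc_ras, tumor$mutation, "RAS", n_boot, seed = seed + 1L)

  tile_confusion <- table(
    predicted = factor(ifelse(joined$p_ras >= cfg$tile_ras_cutoff, "RAS", "BRAF_V600E"),
                       levels = c("BRAF_V600E", "RAS")),
    truth = factor(joined$mutation, levels = c("BRAF_V600E", "RAS"))
  )
  tumor_confusion <- table(
    predicted = factor(tumor$call, levels = c("BRAF_V600E", "RAS", "not_predicted")),
    truth = factor(tumor$mutation, levels = c("BRAF_V600E", "RAS"))
  )

  called <- filter(tumor, .data$call != "not_predicted")
  fisher_p <- if (nrow(called) && length(unique(called$mutation)) == 2 &&
                  length(unique(called$call)) == 2) {
    fisher_exact_p(table(called$call, called$mutation))
  } else {
    NA_real_
  }
  acc_called <- if (nrow(called)) mean(called$call == called$mutation) else NA_real_
  acc_all <- mean(tumor$call == tumor$mutation)
  per_class <- tumor %>%
    group_by(.data$mutation) %>%
    summarise(
      n = dplyr::n(),
      n_called = sum(.data$call != "not_predicted"),
      accuracy_called = ifelse(.data$n_called > 0,
                               sum(.data$call == .data$mutation) / .data$n_called, NA_real_),
      .groups = "drop"
    )

  brs <- NULL
  if (!is.null(brs_records)) {
    bj <- inner_join(tumor, brs_records, by = "patient_id")
    if (nrow(bj) >= 3) {
      sp <- spearman_cor(bj$perc_ras, bj$brs)
      bz <- filter(bj, .data$brs != 0)
      crosstab <- table(
        brs_class = factor(brs_class(bz$brs), levels = c("BRAF_like", "RAS_like")),
        predicted = factor(bz$call, levels = c("BRAF_V600E", "RAS", "not_predicted"))
      )
      brs <- list(
        spearman_rho = sp$rho, spearman_p = sp$p,
        crosstab = crosstab, n_zero_excluded = sum(bj$brs == 0)
      )
    }
  }

  structure(
    list(
      tile_auc = tile_auc, tumor_auc = tumor_auc,
      tile_confusion = tile_confusion, tumor_confusion = tumor_confusion,
      fisher_p = fisher_p,
      accuracy_called = acc_called, accuracy_all = acc_all,
      n_not_predicted = sum(tumor$call == "not_predicted"),
      per_class = per_class,
      tumor = tumor,
      brs = brs,
      cfg = cfg
    ),
    class = "wsi_eval"
  )
}

#' @export
print.wsi_eval <- function(x, ...) {
  cat("<wsi_eval>\n")
  cat(sprintf("  tile AUC  %.3f [%.3f, %.3f]\n",
              x$tile_auc$auc, x$tile_auc$ci_low, x$tile_auc$ci_high))
  cat(sprintf("  tumor AUC %.3f [%.3f, %.3f]\n",
              x$tumor_auc$auc, x$tumor_auc$ci_low, x$tumor_auc$ci_high))
  cat(sprintf("  tumor accuracy %.3f over called tumors (%.3f incl. %d not predicted)\n",
              x$accuracy_called, x$accuracy_all, x$n_not_predicted))
  cat(sprintf("  Fisher exact p = %.4g\n", x$fisher_p))
  cat("  tumor confusion matrix:\n")
  print(x$tumor_confusion)
  if (!is.null(x$brs)) {
    cat(sprintf("  Spearman vs BRS: rho %.3f (p = %.3g)\n",
                x$brs$spearman_rho, x$brs$spearman_p))
  }
  invisible(x)
}
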