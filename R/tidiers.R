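# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a training run
#'
#' One row per epoch with train loss, validation log-loss and accuracy.
#'
#' @param x A `wsi_fit` from [train_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wsi_fit <- function(x, ...) {
  mutate(x$log, best = .data$epoch == x$best_epoch)
}

#' @rdname tidy.wsi_fit
#' @export
glance.wsi_fit <- function(x, ...) {
  tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = x$log$val_loss[x$best_epoch],
    best_val_acc = x$log$val_acc[x$best_epoch],
    n_parameters = n_parameters(x$model),
    architecture_scale = x$model$cfg$architecture_scale
  )
}

#' Tidy an evaluation report
#'
#' Long tibble of the headline metrics (one `metric`/`value` row each),
#' suitable for tabulation or plotting.
#'
#' @param x A `wsi_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble with `metric`, `value`.
#' @export
tidy.wsi_eval <- function(x, ...) {
  out <- tibble(
    metric = c(
      "tile_auc", "tile_auc_ci_low", "tile_auc_ci_high",
      "tumor_auc", "tumor_auc_ci_low", "tumor_auc_ci_high",
      "tumor_accuracy_called", "tumor_accuracy_all",
      "n_not_predicted", "fisher_p"
    ),
    value = c(
      x$tile_auc$auc, x$tile_auc$ci_low, x$tile_auc$ci_high,
      x$tumor_auc$auc, x$tumor_auc$ci_low, x$tumor_auc$ci_high,
      x$accuracy_called, x$accuracy_all,
      x$n_not_predicted, x$fisher_p
    )
  )
  if (!is.null(x$brs)) {
    out <- bind_rows(out, tibble(
      metric = c("spearman_rho_vs_brs", "spearman_p_vs_brs", "brs_zero_excluded"),
      value = c(x$brs$spearman_rho, x$brs$spearman_p, x$brs$n_zero_excluded)
    ))
  }
  out
}

#' @rdname tidy.wsi_eval
#' @export
glance.wsi_eval <- function(x, ...) {
  tibble(
    tile_auc = x$tile_auc$auc,
    tumor_auc = x$tumor_auc$auc,
    tumor_accuracy_called = x$accuracy_called,
    tumor_accuracy_all = x$accuracy_all,
    n_tumors = sum(x$tumor_confusion),
    n_not_predicted = x$n_not_predicted,
    fisher_p = x$fisher_p,
    spearman_rho_vs_brs = if (is.null(x$brs)) NA_real_ else x$brs$spearman_rho
  )
}
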