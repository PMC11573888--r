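# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_raster geom_abline
#'   geom_step labs theme_minimal scale_fill_manual scale_fill_viridis_c
#'   facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

roc_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  tibble(
    tpr = c(0, cumsum(pos[ord]) / sum(pos)),
    fpr = c(0, cumsum(!pos[ord]) / sum(!pos))
  )
}

#' ROC curves of an evaluation report
#'
#' Tile- and tumor-level ROC curves from the stored scores.
#'
#' @param x A `wsi_eval`.
#' @param tile_predictions The tile-prediction tibble used to build `x`
#'   (tile scores are not retained in the report); when `NULL` only the
#'   tumor-level curve is drawn.
#' @return A ggplot.
#' @export
plot_roc <- function(x, tile_predictions = NULL) {
  curves <- list(
    tumor = mutate(
      roc_points(x$tumor$perc_ras, x$tumor$mutation == "RAS"),
      level = sprintf("tumor (AUC %.3f)", x$tumor_auc$auc)
    )
  )
  if (!is.null(tile_predictions)) {
    jt <- inner_join(tile_predictions, x$tumor[, c("patient_id", "mutation")],
                     by = "patient_id")
    curves$tile <- mutate(
      roc_points(jt$p_ras, jt$mutation == "RAS"),
      level = sprintf("tile (AUC %.3f)", x$tile_auc$auc)
    )
  }
  ggplot(bind_rows(curves), aes(.data$fpr, .data$tpr, colour = .data$level)) +
    geom_step(linewidth = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate", colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.wsi_eval <- function(object, ...) plot_roc(object, ...)

#' Training-curve plot
#'
#' Train/validation log-loss per epoch with the selected epoch marked.
#'
#' @param object A `wsi_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wsi_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot(d, aes(.data$epoch, .data$loss, colour = .data$series)) +
    geom_line() +
    geom_point(
      data = filter(d, .data$epoch == object$best_epoch, .data$series == "val_loss"),
      size = 3, shape = 1
    ) +
    labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL,
         title = sprintf("Best epoch %d by validation log-loss", object$best_epoch)) +
    theme_minimal()
}

#' Quality-mask overview plot
#'
#' Tissue, usable and artifact masks as tiled rasters.
#'
#' @param object A `wsi_quality_mask`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wsi_quality_mask <- function(object, ...) {
  stack <- c(list(tissue = object$tissue, usable = object$usable),
             object$artifact_masks)
  d <- bind_rows(lapply(names(stack), function(nm) {
    m <- stack[[nm]]
    tibble(
      layer = nm,
      row = rep(seq_len(nrow(m)), ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      on = as.vector(m)
    )
  }))
  ggplot(d, aes(.data$col, -.data$row, fill = .data$on)) +
    geom_raster() +
    facet_wrap(~layer) +
    scale_fill_manual(values = c(`FALSE` = "grey92", `TRUE` = "#31688e")) +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}

#' Activation-map heatmap
#'
#' @param heat Matrix from [activation_map()].
#' @return A ggplot.
#' @export
plot_activation_map <- function(heat) {
  d <- tibble(
    row = rep(seq_len(nrow(heat)), ncol(heat)),
    col = rep(seq_len(ncol(heat)), each = nrow(heat)),
    saliency = as.vector(heat)
  )
  ggplot(d, aes(.data$col, -.data$row, fill = .data$saliency)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "saliency") +
    theme_minimal()
}
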