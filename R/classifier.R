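# Two-class tile classifier: inception-style CNN trained with Adam
# (learning rate 0.001, batch size 8), per-epoch validation log-loss and
# accuracy, and final model selection by lowest validation cross-entropy.
# The softmax head emits p(BRAF), p(RAS); RAS is the positive class.

#' Classifier configuration
#'
#' @param input_shape Expected tile shape (height, width, channels).
#' @param n_classes Number of output classes (fixed at 2).
#' @param architecture_scale `"small"` (default; a compact inception-style
#'   stack under 1M parameters that trains end-to-end on one CPU in
#'   minutes) or `"full"` (a deeper/wider stack of the same
#'   parallel-branch blocks operating closer to native tile resolution).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed governing weight initialization and batch
#'   shuffling.
#' @return A `wsi_model_config` list.
#' @export
model_config <- function(input_shape = c(512, 512, 3), n_classes = 2,
                         architecture_scale = c("small", "full"),
                         learning_rate = 0.001, batch_size = 8L,
                         epochs = 30L, seed = 1L) {
  architecture_scale <- match.arg(architecture_scale)
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (n_classes != 2) abort("only two-class models are supported")
  structure(
    list(
      input_shape = as.integer(input_shape),
      n_classes = 2L,
      architecture_scale = architecture_scale,
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      seed = as.integer(seed)
    ),
    class = "wsi_model_config"
  )
}

incep <- function(cin, f1, f3r, f3, f5r, f5) {
  nn_inception_node(list(
    list(nn_conv_node(1, 1, cin, f1)),
    list(nn_conv_node(1, 1, cin, f3r), nn_conv_node(3, 3, f3r, f3)),
    list(nn_conv_node(1, 1, cin, f5r), nn_conv_node(5, 5, f5r, f5))
  ))
}

#' Build a tile classifier
#'
#' Constructs the seeded, untrained network. Both scales share the same
#' layer vocabulary: a fixed mean-pooling stem, 3x3 convolutions,
#' inception-style blocks with parallel 1x1 / 3x3 / 5x5 branches, max
#' pooling, global average pooling and a 2-way softmax head.
#'
#' @param cfg A [model_config()].
#' @return A `wsi_cnn` model.
#' @export
#' @examples
#' m <- build_model(model_config(epochs = 1, seed = 42))
#' n_parameters(m)
build_model <- function(cfg = model_config()) {
  if (!inherits(cfg, "wsi_model_config")) abort("cfg must come from model_config()")
  nodes <- with_seed(cfg$seed, {
    if (cfg$architecture_scale == "small") {
      list(
        nn_stem_node(64L),
        nn_conv_node(3, 3, 3, 12),
        nn_maxpool_node(), # 32
        incep(12, 6, 6, 10, 4, 6), # -> 22
        nn_maxpool_node(), # 16
        incep(22, 10, 8, 16, 6, 8), # -> 34
        nn_maxpool_node(), # 8
        nn_gap_node(),
        nn_dense_node(34, 2)
      )
    } else {
      list(
        nn_stem_node(256L),
        nn_conv_node(3, 3, 3, 32),
        nn_maxpool_node(), # 128
        nn_conv_node(3, 3, 32, 64),
        nn_maxpool_node(), # 64
        incep(64, 32, 32, 64, 16, 32), # -> 128
        nn_maxpool_node(), # 32
        incep(128, 64, 64, 96, 32, 64), # -> 224
        nn_maxpool_node(), # 16
        incep(224, 96, 96, 128, 48, 64), # -> 288
        nn_maxpool_node(), # 8
        incep(288, 96, 96, 128, 48, 64), # -> 288
        nn_gap_node(),
        nn_dense_node(288, 2)
      )
    }
  })
  structure(
    list(nodes = nodes, cfg = cfg, classes = c("BRAF_V600E", "RAS")),
    class = "wsi_cnn"
  )
}

#' Number of trainable parameters
#' @param model A `wsi_cnn`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_params(model$nodes), length, numeric(1)))
}

#' @export
print.wsi_cnn <- function(x, ...) {
  cat(sprintf(
    "<wsi_cnn> scale '%s', %d trainable parameters, classes %s\n",
    x$cfg$architecture_scale, n_parameters(x),
    paste(x$classes, collapse = "/")
  ))
  invisible(x)
}

# [0,1] RGB tile -> network input: scaled to [-1, 1], stem-pooled (once per
# tile, not once per epoch), then standardized per tile. Without the
# whitening step the near-constant eosin background dominates every
# activation and Adam at the fixed 0.001 learning rate converges far too
# slowly; standardization is deterministic and preserves the spatial signal.
preprocess_tile <- function(tile, stem_size) {
  assert_rgb(tile, "tile")
  x <- tile * 2 - 1
  if (dim(x)[1] != stem_size) {
    f <- dim(x)[1] / stem_size
    if (f != round(f)) abort(sprintf("tile of size %d incompatible with model stem %d",
                                     dim(x)[1], stem_size))
    x <- pool_array(x, as.integer(f))
  }
  (x - mean(x)) / max(sd(x), 1e-6)
}

stack_tiles <- function(tiles, stem_size) {
  xs <- lapply(tiles, preprocess_tile, stem_size = stem_size)
  d <- dim(xs[[1]])
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

stem_size_of <- function(model) model$nodes[[1]]$size

tile_column <- function(patches) {
  if (is.list(patches) && !is.data.frame(patches)) return(patches)
  if (!"tile" %in% names(patches)) abort("patches need a 'tile' list-column")
  patches$tile
}

label_indices <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) abort(sprintf("labels must be one of: %s", paste(classes, collapse = ", ")))
  idx
}

forward_probs <- function(model, x_batch) {
  z <- nn_forward(model$nodes, x_batch)$out
  softmax_probs(z)
}

predict_probs_chunked <- function(model, xs, chunk = 32L) {
  n <- dim(xs)[4]
  out <- matrix(0, n, 2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    out[idx, ] <- forward_probs(model, xs[, , , idx, drop = FALSE])
  }
  out
}

#' Train a tile classifier
#'
#' Runs `cfg$epochs` epochs of Adam on shuffled minibatches (incomplete
#' trailing batches are dropped, matching the iterations-per-epoch
#' arithmetic of [compute_training_plan()]). At the end of every epoch the
#' validation log-loss and accuracy are recorded; the returned model is
#' the checkpoint with the lowest validation cross-entropy (first epoch on
#' ties), and the final-epoch weights are kept alongside.
#'
#' @param model An untrained [build_model()] output.
#' @param train_patches,val_patches Tibbles with a `tile` list-column
#'   (RGB arrays in `[0, 1]`) and a `label` column (`"BRAF_V600E"` /
#'   `"RAS"`), or plain lists of tiles plus `train_labels`/`val_labels`.
#' @param train_labels,val_labels Label vectors when tiles are given as
#'   bare lists.
#' @return A `wsi_fit`: `model` (best checkpoint), `last_model`, `log`
#'   (per-epoch tibble), `best_epoch`.
#' @export
train_classifier <- function(model, train_patches, val_patches,
                             train_labels = NULL, val_labels = NULL) {
  cfg <- model$cfg
  ytr_lab <- train_labels %||% train_patches$label
  yva_lab <- val_labels %||% val_patches$label
  if (length(unique(ytr_lab)) < 2) abort("training data must contain both classes")
  ss <- stem_size_of(model)
  xtr <- stack_tiles(tile_column(train_patches), ss)
  xva <- stack_tiles(tile_column(val_patches), ss)
  ytr <- label_indices(ytr_lab, model$classes)
  yva <- label_indices(yva_lab, model$classes)

  n <- length(ytr)
  nb <- n %/% cfg$batch_size
  if (nb == 0) abort("fewer training tiles than one batch")
  params <- collect_params(model$nodes)
  state <- adam_init(params)
  nodes <- model$nodes
  log <- vector("list", cfg$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = params)

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "epoch", ep), sample.int(n))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * cfg$batch_size + 1):(bi * cfg$batch_size)]
      fw <- nn_forward(nodes, xtr[, , , idx, drop = FALSE], keep_cache = TRUE)
      ce <- softmax_ce(fw$out, ytr[idx])
      ep_loss <- ep_loss + ce$loss
      grads <- nn_backward(nodes, fw$caches, ce$dz)
      upd <- adam_step(params, collect_params(nodes, grads), state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
      nodes <- assign_params(nodes, params)
    }
    pv <- predict_probs_chunked(structure(list(nodes = nodes), class = "wsi_cnn"), xva)
    val_loss <- -mean(log(pmax(pv[cbind(seq_along(yva), yva)], 1e-12)))
    val_acc <- mean(max.col(pv) == yva)
    log[[ep]] <- tibble(
      epoch = ep, train_loss = ep_loss / nb,
      val_loss = val_loss, val_acc = val_acc
    )
    if (val_loss < best$loss) best <- list(loss = val_loss, epoch = ep, params = params)
  }
  log <- bind_rows(log)
  best_model <- model
  best_model$nodes <- assign_params(model$nodes, best$params)
  last_model <- model
  last_model$nodes <- nodes
  structure(
    list(
      model = best_model, last_model = last_model,
      log = log, best_epoch = best$epoch, classes = model$classes
    ),
    class = "wsi_fit"
  )
}

#' @export
print.wsi_fit <- function(x, ...) {
  cat(sprintf(
    "<wsi_fit> %d epochs, best epoch %d (val log-loss %.4f, val acc %.3f)\n",
    nrow(x$log), x$best_epoch,
    x$log$val_loss[x$best_epoch], x$log$val_acc[x$best_epoch]
  ))
  invisible(x)
}

#' Best epoch by validation cross-entropy
#'
#' First-on-ties argmin over a training log; the rule used for final
#' model selection.
#'
#' @param log Tibble with a `val_loss` column in epoch order.
#' @return 1-based epoch index.
#' @export
select_best_epoch <- function(log) which.min(log$val_loss)

#' Predict tile-level class probabilities
#'
#' Deterministic inference. `p_ras` is the softmax probability that the
#' tile originates from a RAS-mutated tumor; `p_braf = 1 - p_ras`.
#'
#' @param fit A `wsi_fit` (or a bare `wsi_cnn`).
#' @param tiles Tibble with a `tile` list-column (extra columns such as
#'   `slide_id`, `x`, `y` are carried through) or a plain list of RGB
#'   arrays.
#' @return Tibble of predictions with `p_braf` and `p_ras` columns.
#' @export
predict_tiles <- function(fit, tiles) {
  model <- if (inherits(fit, "wsi_fit")) fit$model else fit
  tl <- tile_column(tiles)
  ss <- stem_size_of(model)
  for (i in seq_along(tl)) {
    d <- dim(tl[[i]])
    if (is.null(d) || length(d) != 3 || d[3] != 3 || d[1] != d[2]) {
      abort(sprintf("tile %d is not a square RGB array", i))
    }
  }
  probs <- predict_probs_chunked(model, stack_tiles(tl, ss))
  base <- if (is.data.frame(tiles)) select(tiles, -"tile") else tibble(.rows = length(tl))
  bind_cols(base, tibble(p_braf = probs[, 1], p_ras = probs[, 2]))
}

#' Occlusion activation map
#'
#' Slides a gray occluding square over the tile and records the drop in
#' the predicted-class probability at each position; the resulting grid
#' is min-max normalized to `[0, 1]` unless the raw response range is
#' negligible (range below 0.05, an uninformative tile), in which case the raw drops
#' (clipped to `[0, 1]`) are returned.
#'
#' @param fit A `wsi_fit` or `wsi_cnn`.
#' @param tile RGB array.
#' @param occluder_size Edge of the gray square in pixels.
#' @param stride Step between occluder positions.
#' @return Matrix heatmap of dimension `ceiling((S - occluder)/stride)+1`
#'   per side, with attributes `class_index` and `baseline`.
#' @export
activation_map <- function(fit, tile, occluder_size = 64L, stride = 64L) {
  model <- if (inherits(fit, "wsi_fit")) fit$model else fit
  assert_rgb(tile, "tile")
  s <- dim(tile)[1]
  if (occluder_size > s) abort("occluder larger than tile")
  ss <- stem_size_of(model)
  p0 <- forward_probs(model, stack_tiles(list(tile), ss))
  cls <- which.max(p0[1, ])
  pos <- unique(c(seq(0L, s - occluder_size, by = stride), s - occluder_size))
  heat <- matrix(0, length(pos), length(pos))
  occluded <- vector("list", length(pos)^2)
  k <- 0
  for (iy in seq_along(pos)) for (ix in seq_along(pos)) {
    t2 <- tile
    t2[(pos[iy] + 1):(pos[iy] + occluder_size),
       (pos[ix] + 1):(pos[ix] + occluder_size), ] <- 0.5
    k <- k + 1
    occluded[[k]] <- t2
  }
  probs <- predict_probs_chunked(model, stack_tiles(occluded, ss))
  drops <- p0[1, cls] - probs[, cls]
  heat <- matrix(drops, length(pos), length(pos), byrow = TRUE)
  rng <- diff(range(heat))
  if (rng > 0.05) {
    heat <- (heat - min(heat)) / rng
  } else {
    heat <- clamp(heat, 0, 1)
  }
  attr(heat, "class_index") <- cls
  attr(heat, "baseline") <- p0[1, cls]
  heat
}

#' Save / load a fitted classifier
#'
#' Weights are serialized in R's native format with a JSON metadata
#' sidecar (configuration, best epoch, training log).
#'
#' @param fit A `wsi_fit`.
#' @param path Base path; `.rds` and `.json` files are written.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(fit, path) {
  saveRDS(fit, paste0(path, ".rds"))
  jsonlite::write_json(
    list(
      config = unclass(fit$model$cfg),
      best_epoch = fit$best_epoch,
      classes = fit$classes,
      log = fit$log
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(paste0(path, ".rds"))
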