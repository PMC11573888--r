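# End-to-end orchestration: qc -> extract -> split -> train -> predict ->
# aggregate -> evaluate over a slide directory + cohort manifest, with
# content-hash stage caching and a reproducibility manifest.

pipeline_stages <- c("qc", "extract", "split", "train", "predict", "aggregate", "evaluate")

#' Pipeline configuration
#'
#' @param slides_dir Directory containing `<patient_id>.tiff` slides.
#' @param manifest Path to a cohort manifest TSV (`patient_id`,
#'   `mutation`, optional `histology`, `brs`, `slide_path`).
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Global seed; per-stage seeds are derived from it by
#'   hashing the stage name, so stage results do not depend on execution
#'   order.
#' @param qc,filter,sampler,model,aggregation Sub-configurations; see the
#'   respective constructors.
#' @param ratios Train/validation/test split ratios.
#' @return A `wsi_pipeline_config`.
#' @export
pipeline_config <- function(slides_dir, manifest, out_dir, seed = 1L,
                            qc = qc_config(),
                            filter = patch_filter_config(),
                            sampler = sampler_config(seed = seed),
                            model = model_config(seed = seed),
                            aggregation = aggregation_config(),
                            ratios = c(0.6, 0.2, 0.2)) {
  cfg <- structure(
    list(
      slides_dir = slides_dir, manifest = manifest, out_dir = out_dir,
      seed = as.integer(seed), qc = qc, filter = filter, sampler = sampler,
      model = model, aggregation = aggregation, ratios = ratios
    ),
    class = "wsi_pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  checks <- list(
    slides_dir = inherits(cfg$qc, "wsi_qc_config"),
    filter = inherits(cfg$filter, "wsi_patch_filter"),
    sampler = inherits(cfg$sampler, "wsi_sampler_config"),
    model = inherits(cfg$model, "wsi_model_config"),
    aggregation = inherits(cfg$aggregation, "wsi_aggregation_config")
  )
  bad <- names(checks)[!unlist(checks)]
  if (length(bad)) {
    abort(sprintf("invalid pipeline config at: %s", paste(bad, collapse = ", ")),
          class = "wsidriver_config_error")
  }
  if (abs(sum(cfg$ratios) - 1) > 1e-9) {
    abort("invalid pipeline config at: ratios (must sum to 1)",
          class = "wsidriver_config_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `slides_dir`, `manifest`, `out_dir`, `seed`, `ratios`
#' plus optional nested blocks `qc`, `filter`, `sampler`, `model`,
#' `aggregation` whose fields are passed to the corresponding
#' constructors.
#'
#' @param path YAML file.
#' @return A `wsi_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- setdiff(c("slides_dir", "manifest", "out_dir"), names(y))
  if (length(need)) {
    abort(sprintf("invalid pipeline config at: %s (missing)", paste(need, collapse = ", ")),
          class = "wsidriver_config_error")
  }
  seed <- y$seed %||% 1L
  build <- function(f, args, defaults = list()) do.call(f, utils::modifyList(defaults, args %||% list()))
  pipeline_config(
    slides_dir = y$slides_dir, manifest = y$manifest, out_dir = y$out_dir,
    seed = seed,
    qc = build(qc_config, y$qc),
    filter = build(patch_filter_config, y$filter),
    sampler = build(sampler_config, y$sampler, list(seed = seed)),
    model = build(model_config, y$model, list(seed = seed)),
    aggregation = build(aggregation_config, y$aggregation),
    ratios = y$ratios %||% c(0.6, 0.2, 0.2)
  )
}

read_manifest <- function(cfg) {
  if (!file.exists(cfg$manifest)) {
    abort(sprintf("manifest '%s' not found", cfg$manifest),
          class = "wsidriver_missing_artifact")
  }
  m <- as_tibble(utils::read.delim(cfg$manifest, stringsAsFactors = FALSE))
  if (!"slide_path" %in% names(m)) {
    m$slide_path <- file.path(cfg$slides_dir, paste0(m$patient_id, ".tiff"))
  }
  m
}

stage_paths <- function(cfg) {
  o <- cfg$out_dir
  list(
    qc = file.path(o, "qc"),
    patches = file.path(o, "patches"),
    split = file.path(o, "split.tsv"),
    model = file.path(o, "model"),
    predictions = file.path(o, "predictions.tsv"),
    tumor = file.path(o, "tumor.tsv"),
    eval_json = file.path(o, "eval.json"),
    eval_rds = file.path(o, "eval.rds"),
    manifest = file.path(o, "run_manifest.json")
  )
}

require_artifact <- function(path, stage) {
  if (!all(file.exists(path))) {
    abort(sprintf("missing upstream artifact '%s'; run stage '%s' first",
                  path[!file.exists(path)][1], stage),
          class = "wsidriver_missing_artifact")
  }
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
read_tsv_ <- function(path) as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))

# read a patch tile at level 0 and mean-pool it to the model stem size;
# dihedral augmentation commutes with blockwise pooling, so augmenting the
# pooled tile is exact
load_pooled_tile <- function(slide, x, y, stem, tag = NA_character_) {
  tile <- read_region(slide, x, y, 512L)
  small <- pool_array(tile, as.integer(512L / stem))
  if (!is.na(tag)) small <- apply_dihedral(small, tag)
  small
}

#' Run the whole-slide classification pipeline
#'
#' Executes the requested stages in order (`qc`, `extract`, `split`,
#' `train`, `predict`, `aggregate`, `evaluate`), skipping stages whose
#' input content hash matches the previous run ("cached" in the returned
#' manifest). Each stage derives its seed from the global one by hashing
#' the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of stages to run (default: all).
#' @return A `wsi_run_manifest`: per-stage status, hashes and artifact
#'   paths; the evaluation report is attached as `$eval` when the
#'   evaluate stage ran.
#' @export
run_pipeline <- function(cfg, stages = pipeline_stages) {
  validate_pipeline_config(cfg)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(cfg)
  manifest <- read_manifest(cfg)
  prev <- if (file.exists(p$manifest)) {
    jsonlite::read_json(p$manifest, simplifyVector = TRUE)
  } else {
    list(stages = list())
  }
  status <- list()
  hashes <- list()
  eval_report <- NULL
  slide_md5 <- tools::md5sum(manifest$slide_path[file.exists(manifest$slide_path)])

  stage_hash <- function(stage, extra) {
    digest::digest(list(stage, extra, cfg$seed))
  }
  cached <- function(stage, hash, outputs) {
    !is.null(prev$stages[[stage]]$hash) &&
      identical(prev$stages[[stage]]$hash, hash) &&
      all(file.exists(outputs))
  }

  for (stage in pipeline_stages) {
    if (!stage %in% stages) next
    if (stage == "qc") {
      h <- stage_hash("qc", list(slide_md5, unclass(cfg$qc)))
      outs <- file.path(p$qc, paste0(manifest$patient_id, "_qc.rds"))
      if (cached("qc", h, outs)) {
        status$qc <- "cached"
      } else {
        dir.create(p$qc, showWarnings = FALSE, recursive = TRUE)
        for (i in seq_len(nrow(manifest))) {
          sl <- open_slide(manifest$slide_path[i])
          qm <- quality_mask(sl, cfg$qc)
          saveRDS(qm, outs[i])
          jsonlite::write_json(as.list(qc_summary(qm)),
                               file.path(p$qc, paste0(manifest$patient_id[i], "_qc.json")),
                               auto_unbox = TRUE, digits = NA)
        }
        status$qc <- "run"
      }
      hashes$qc <- h
    } else if (stage == "extract") {
      require_artifact(file.path(p$qc, paste0(manifest$patient_id, "_qc.rds")), "qc")
      h <- stage_hash("extract", list(hashes$qc, unclass(cfg$filter),
                                      cfg$sampler$per_slide_cap))
      outs <- file.path(p$patches, paste0(manifest$patient_id, ".tsv"))
      if (cached("extract", h, outs)) {
        status$extract <- "cached"
      } else {
        dir.create(p$patches, showWarnings = FALSE, recursive = TRUE)
        for (i in seq_len(nrow(manifest))) {
          sl <- open_slide(manifest$slide_path[i])
          qm <- readRDS(file.path(p$qc, paste0(manifest$patient_id[i], "_qc.rds")))
          pr <- extract_patches(sl, qm, cfg$filter, cfg$sampler)
          write_tsv(pr, outs[i])
        }
        status$extract <- "run"
      }
      hashes$extract <- h
    } else if (stage == "split") {
      h <- stage_hash("split", list(tools::md5sum(cfg$manifest), cfg$ratios))
      if (cached("split", h, p$split)) {
        status$split <- "cached"
      } else {
        filt <- filter_cohort(manifest)
        included <- bind_rows(filt$ras, filt$braf_pool)
        sp <- split_patients(included, cfg$ratios, derive_seed(cfg$seed, "split"))
        write_tsv(sp, p$split)
        status$split <- "run"
      }
      hashes$split <- h
    } else if (stage == "train") {
      require_artifact(p$split, "split")
      require_artifact(file.path(p$patches, paste0(manifest$patient_id, ".tsv")), "extract")
      h <- stage_hash("train", list(hashes$extract, unclass(cfg$model),
                                    unclass(cfg$sampler), tools::md5sum(p$split)))
      outs <- paste0(p$model, c(".rds", ".json"))
      if (cached("train", h, outs)) {
        status$train <- "cached"
      } else {
        sp <- read_tsv_(p$split)
        stem <- if (cfg$model$architecture_scale == "small") 64L else 256L
        gather <- function(role) {
          ids <- sp$patient_id[sp$role == role]
          tiles <- list(); labels <- character(0)
          for (pid in ids) {
            rec <- read_tsv_(file.path(p$patches, paste0(pid, ".tsv")))
            if (nrow(rec) == 0) next
            sel <- sample_for_split(rec, role, cfg$sampler)
            sl <- open_slide(manifest$slide_path[manifest$patient_id == pid])
            for (j in seq_len(nrow(sel))) {
              tiles[[length(tiles) + 1]] <- load_pooled_tile(
                sl, sel$x[j], sel$y[j], stem, sel$augmentation_tag[j]
              )
            }
            labels <- c(labels, rep(manifest$mutation[manifest$patient_id == pid], nrow(sel)))
          }
          list(tiles = tiles, labels = labels)
        }
        tr <- gather("train"); va <- gather("validation")
        model <- build_model(cfg$model)
        fit <- train_classifier(model, tr$tiles, va$tiles, tr$labels, va$labels)
        save_classifier(fit, p$model)
        status$train <- "run"
      }
      hashes$train <- h
    } else if (stage == "predict") {
      require_artifact(paste0(p$model, ".rds"), "train")
      require_artifact(p$split, "split")
      h <- stage_hash("predict", list(hashes$train, hashes$extract))
      if (cached("predict", h, p$predictions)) {
        status$predict <- "cached"
      } else {
        fit <- load_classifier(p$model)
        sp <- read_tsv_(p$split)
        stem <- stem_size_of(fit$model)
        preds <- list()
        for (role in c("validation", "test")) {
          for (pid in sp$patient_id[sp$role == role]) {
            rec <- read_tsv_(file.path(p$patches, paste0(pid, ".tsv")))
            if (nrow(rec) == 0) next
            sel <- sample_for_split(rec, role, cfg$sampler)
            sl <- open_slide(manifest$slide_path[manifest$patient_id == pid])
            tiles <- lapply(seq_len(nrow(sel)), function(j) {
              load_pooled_tile(sl, sel$x[j], sel$y[j], stem)
            })
            pp <- predict_tiles(fit, tiles)
            preds[[length(preds) + 1]] <- bind_cols(
              tibble(patient_id = pid, role = role, x = sel$x, y = sel$y), pp
            )
          }
        }
        write_tsv(bind_rows(preds), p$predictions)
        status$predict <- "run"
      }
      hashes$predict <- h
    } else if (stage == "aggregate") {
      require_artifact(p$predictions, "predict")
      h <- stage_hash("aggregate", list(hashes$predict, unclass(cfg$aggregation)))
      if (cached("aggregate", h, p$tumor)) {
        status$aggregate <- "cached"
      } else {
        tp <- read_tsv_(p$predictions)
        write_tsv(classify_tumor(perc_ras(tp, cfg$aggregation), cfg$aggregation), p$tumor)
        status$aggregate <- "run"
      }
      hashes$aggregate <- h
    } else if (stage == "evaluate") {
      require_artifact(p$predictions, "predict")
      h <- stage_hash("evaluate", list(hashes$aggregate %||% NA, hashes$predict %||% NA,
                                       unclass(cfg$aggregation)))
      tp <- read_tsv_(p$predictions)
      brs <- if ("brs" %in% names(manifest)) manifest[, c("patient_id", "brs")] else NULL
      eval_report <- evaluate_predictions(
        tp, manifest[, c("patient_id", "mutation")], brs,
        cfg$aggregation, seed = derive_seed(cfg$seed, "evaluate")
      )
      saveRDS(eval_report, p$eval_rds)
      jsonlite::write_json(
        tidyr::pivot_wider(tidy(eval_report), names_from = "metric", values_from = "value"),
        p$eval_json, auto_unbox = TRUE, digits = NA
      )
      status$evaluate <- "run"
      hashes$evaluate <- h
    }
  }

  out <- list(
    stages = lapply(setNames(nm = names(status)), function(s) {
      list(status = status[[s]], hash = hashes[[s]])
    }),
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    out_dir = cfg$out_dir
  )
  keep <- utils::modifyList(prev$stages %||% list(), out$stages)
  jsonlite::write_json(list(stages = keep, seed = cfg$seed,
                            timestamp = out$timestamp),
                       p$manifest, auto_unbox = TRUE, digits = NA)
  structure(c(out, list(eval = eval_report, paths = p)), class = "wsi_run_manifest")
}

#' @export
print.wsi_run_manifest <- function(x, ...) {
  cat("<wsi_run_manifest>", x$out_dir, "\n")
  for (s in names(x$stages)) cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
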