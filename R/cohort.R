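# Cohort bookkeeping: dual-mutant exclusion, histology-matched BRAF
# subsampling, the leakage-free patient-level 60/20/20 split, and the
# training-plan arithmetic.

#' Filter a cohort manifest
#'
#' Drops samples carrying both driver mutations (dual mutants), keeps all
#' RAS samples, and returns the remaining BRAF pool for matched
#' subsampling.
#'
#' @param samples Tibble with columns `patient_id`, `mutation`
#'   (`"BRAF_V600E"`, `"RAS"` or `"both"`) and optionally `histology`,
#'   `brs`.
#' @return List with tibbles `ras`, `braf_pool` and `excluded`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   patient_id = paste0("P", 1:6),
#'   mutation = c("RAS", "RAS", "both", "BRAF_V600E", "BRAF_V600E", "BRAF_V600E")
#' )
#' filter_cohort(m)$excluded$patient_id
filter_cohort <- function(samples) {
  if (!all(c("patient_id", "mutation") %in% names(samples))) {
    abort("samples must have patient_id and mutation columns")
  }
  if (anyDuplicated(samples$patient_id)) abort("one record per patient required")
  bad <- setdiff(unique(samples$mutation), c("BRAF_V600E", "RAS", "both"))
  if (length(bad)) abort(sprintf("unknown mutation value(s): %s", paste(bad, collapse = ", ")))
  excluded <- filter(samples, .data$mutation == "both")
  ras <- filter(samples, .data$mutation == "RAS")
  braf <- filter(samples, .data$mutation == "BRAF_V600E")
  if (nrow(ras) == 0 || nrow(braf) == 0) {
    abort("a mutation class is empty after dual-mutant exclusion")
  }
  list(ras = ras, braf_pool = braf, excluded = excluded)
}

# largest-remainder apportionment of `total` slots over strata proportions
largest_remainder <- function(weights, total) {
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Histology-matched BRAF subsample
#'
#' Draws `nrow(ras_samples) + 1` BRAF samples from the pool with
#' per-histology counts apportioned to the RAS histology distribution by
#' largest remainder. Strata that cannot supply their quota fall back to
#' the remaining pool with a warning.
#'
#' @param braf_pool,ras_samples Tibbles with `patient_id` and `histology`.
#' @param seed Integer seed for the stratified draw.
#' @return Tibble: the selected BRAF subset.
#' @export
match_braf_subsample <- function(braf_pool, ras_samples, seed = 1L) {
  target <- nrow(ras_samples) + 1L
  if (nrow(braf_pool) < target) abort("BRAF pool smaller than required subset")
  strata <- ras_samples %>% count(.data$histology, name = "n_ras")
  strata$quota <- largest_remainder(strata$n_ras, target)
  with_seed(derive_seed(seed, "braf_subsample"), {
    chosen <- list()
    short <- 0L
    for (k in seq_len(nrow(strata))) {
      pool_k <- filter(braf_pool, .data$histology == strata$histology[k])
      take <- min(nrow(pool_k), strata$quota[k])
      if (take < strata$quota[k]) {
        short <- short + (strata$quota[k] - take)
        warn(sprintf("histology stratum '%s' short by %d; backfilling from remaining pool",
                     strata$histology[k], strata$quota[k] - take))
      }
      if (take > 0) chosen[[k]] <- pool_k[sample.int(nrow(pool_k), take), ]
    }
    out <- bind_rows(chosen)
    if (short > 0) {
      rest <- filter(braf_pool, !.data$patient_id %in% out$patient_id)
      out <- bind_rows(out, rest[sample.int(nrow(rest), short), ])
    }
    arrange(out, .data$patient_id)
  })
}

#' Patient-level stratified 60/20/20 split
#'
#' Training receives `floor(0.6 N)` patients; the remainder is split as
#' evenly as possible between validation and test, validation taking the
#' odd extra. Within that global allocation, per-class counts are
#' apportioned by largest remainder (so both mutation classes appear in
#' every role) and patients are assigned by a seeded shuffle within
#' class. For 103 patients this yields 61/21/21.
#'
#' @param samples Tibble with `patient_id` and `mutation`.
#' @param ratios Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return Tibble `patient_id`, `mutation`, `role`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   patient_id = sprintf("P%03d", 1:103),
#'   mutation = rep(c("BRAF_V600E", "RAS"), c(52, 51))
#' )
#' table(split_patients(m, seed = 1)$role)
split_patients <- function(samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) abort("ratios must sum to 1")
  classes <- unique(samples$mutation)
  if (any(table(samples$mutation) < 5)) abort("need >= 5 samples per class to split")
  n <- nrow(samples)
  n_train <- floor(ratios[1] * n)
  rem <- n - n_train
  n_val <- ceiling(rem * ratios[2] / (ratios[2] + ratios[3]))
  n_test <- rem - n_val
  role_totals <- c(train = n_train, validation = n_val, test = n_test)

  class_n <- table(samples$mutation)[classes]
  # 2-way controlled rounding: floors first, then greedily place the
  # remaining slots where both the class and the role still have deficit
  raw <- outer(as.numeric(class_n), role_totals / n)
  cell <- floor(raw)
  class_def <- as.numeric(class_n) - rowSums(cell)
  role_def <- role_totals - colSums(cell)
  frac <- raw - cell
  while (sum(class_def) > 0) {
    elig <- which(outer(class_def > 0, role_def > 0, `&`), arr.ind = TRUE)
    if (nrow(elig) == 0) abort("split apportionment failed")
    best <- elig[order(-frac[elig], elig[, 2], elig[, 1])[1], , drop = FALSE]
    cell[best] <- cell[best] + 1
    class_def[best[1]] <- class_def[best[1]] - 1
    role_def[best[2]] <- role_def[best[2]] - 1
  }

  with_seed(derive_seed(seed, "split"), {
    out <- lapply(seq_along(classes), function(ci) {
      ids <- sort(samples$patient_id[samples$mutation == classes[ci]])
      ids <- ids[sample.int(length(ids))]
      tibble(
        patient_id = ids,
        mutation = classes[ci],
        role = rep(c("train", "validation", "test"), cell[ci, ])
      )
    })
    arrange(bind_rows(out), .data$patient_id)
  })
}

#' Training-plan arithmetic
#'
#' Patch and iteration counts implied by a split and sampler
#' configuration: training patches are `patients x per_sample_train x
#' augment_select`, validation/test patches are unaugmented, and
#' iterations are `floor(n_train / batch_size) x epochs`.
#'
#' @param split Output of [split_patients()].
#' @param sampler_cfg A [sampler_config()].
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @return One-row tibble with `n_train_patches`, `n_val_patches`,
#'   `n_test_patches`, `batch_size`, `epochs`, `iterations`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   patient_id = sprintf("P%03d", 1:103),
#'   mutation = rep(c("BRAF_V600E", "RAS"), c(52, 51))
#' )
#' compute_training_plan(split_patients(m, seed = 1))
compute_training_plan <- function(split, sampler_cfg = sampler_config(),
                                  batch_size = 8L, epochs = 200L) {
  n_role <- table(factor(split$role, levels = c("train", "validation", "test")))
  n_train <- unname(n_role["train"]) * sampler_cfg$per_sample_train * sampler_cfg$augment_select
  n_val <- unname(n_role["validation"]) * sampler_cfg$per_sample_train
  n_test <- unname(n_role["test"]) * sampler_cfg$per_sample_train
  tibble(
    n_train_patches = as.integer(n_train),
    n_val_patches = as.integer(n_val),
    n_test_patches = as.integer(n_test),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    iterations = as.integer(floor(n_train / batch_size) * epochs)
  )
}
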