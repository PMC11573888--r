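# Seeded synthetic cohorts: per-patient slide specs with class phenotypes
# and a BRS-like expression score whose sign-consistency with the class is
# governed by a single separability knob.

histology_profiles <- list(
  # class-conditional histology mix mirroring the typical distribution in
  # BRAF- vs RAS-driven papillary thyroid carcinoma cohorts
  BRAF = c(classical = 0.765, follicular_variant = 0.051, tall_cell = 0.115, other = 0.069),
  RAS = c(classical = 20 / 51, follicular_variant = 29 / 51, tall_cell = 0, other = 2 / 51)
)

#' Generate a synthetic cohort manifest and slide specifications
#'
#' Each patient receives a slide spec with the class phenotype preset at
#' the requested separability, a histology drawn from a class-conditional
#' mix, and a BRS value in `[-1, 1]`: at separability 1 the BRS sign
#' matches the class exactly (negative for BRAF, positive for RAS); at 0
#' it is label-independent noise.
#'
#' @param n_braf,n_ras Patients per class (each `>= 1`).
#' @param separability Class contrast in `[0, 1]`, applied to both the
#'   rendered phenotype and the BRS mixture.
#' @param seed Integer seed.
#' @param width_px,height_px Slide dimensions handed to [slide_spec()].
#' @param base_magnification Nominal power of the synthetic slides.
#' @return List with `manifest` (tibble: `patient_id`, `mutation`,
#'   `histology`, `brs`) and `specs` (named list of [slide_spec()]s).
#' @export
#' @examples
#' co <- generate_cohort(3, 3, separability = 1, seed = 1)
#' co$manifest
generate_cohort <- function(n_braf, n_ras, separability = 1, seed = 1L,
                            width_px = 4096, height_px = 4096,
                            base_magnification = 20) {
  if (n_braf < 1 || n_ras < 1) abort("need at least one patient per class")
  if (separability < 0 || separability > 1) abort("separability must be in [0, 1]")
  classes <- rep(c("BRAF", "RAS"), c(n_braf, n_ras))
  n <- length(classes)
  with_seed(derive_seed(seed, "cohort"), {
    histology <- vapply(classes, function(cl) {
      p <- histology_profiles[[cl]]
      sample(names(p), 1, prob = p)
    }, character(1))
    magnitude <- runif(n, 0.15, 0.95)
    noise <- runif(n, -1, 1)
    sgn <- ifelse(classes == "RAS", 1, -1)
    brs <- clamp(separability * sgn * magnitude + (1 - separability) * noise, -1, 1)
    manifest <- tibble(
      patient_id = sprintf("S%03d", seq_len(n)),
      mutation = ifelse(classes == "RAS", "RAS", "BRAF_V600E"),
      histology = histology,
      brs = brs
    )
    specs <- lapply(seq_len(n), function(i) {
      slide_spec(
        width_px = width_px, height_px = height_px,
        base_magnification = base_magnification,
        phenotype = phenotype_preset(classes[i], separability),
        seed = derive_seed(seed, "slide", manifest$patient_id[i])
      )
    })
    names(specs) <- manifest$patient_id
    list(manifest = manifest, specs = specs)
  })
}

#' Materialize a synthetic cohort on disk
#'
#' Renders every slide, writes it as multi-page TIFF next to a
#' `manifest.tsv` (patient_id, mutation, histology, brs, slide path), and
#' optionally the ground-truth centroid tables.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_truth Also write per-slide nuclei centroid CSVs.
#' @return The manifest tibble with a `slide_path` column, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    pid <- cohort$manifest$patient_id[i]
    sl <- generate_slide(cohort$specs[[pid]])
    paths[i] <- file.path(dir, paste0(pid, ".tiff"))
    sl$slide$slide_id <- pid
    write_slide(sl$slide, paths[i])
    if (write_truth) {
      utils::write.csv(sl$truth$nuclei, file.path(dir, paste0(pid, "_nuclei.csv")),
                       row.names = FALSE)
    }
  }
  manifest <- mutate(cohort$manifest, slide_path = paths)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
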