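# Phenotype presets for the synthetic-slide generator. The two classes
# mimic, at cartoon level, the morphologic contrast between the classical
# papillary type (dense, round nuclei in clusters) and the follicular
# variant (sparser, elongated nuclei arranged in rings).

#' Phenotype specification for synthetic slides
#'
#' @param class_label `"BRAF"` or `"RAS"`.
#' @param nucleus_density Mean nuclei per 512x512 tissue patch (Poisson mean).
#' @param nucleus_axis_ratio Mean major/minor axis ratio (`>= 1`).
#' @param nucleus_radius_px Mean equivalent-circle radius in pixels.
#' @param arrangement `"papillary_clusters"`, `"follicular_rings"` or
#'   `"uniform"`.
#' @param arrangement_strength Fraction of nuclei placed according to the
#'   arrangement (the rest uniformly); in `[0, 1]`.
#' @param stain_jitter Per-slide lognormal scale perturbing stain densities.
#' @return A `wsi_phenotype` list.
#' @export
phenotype_spec <- function(class_label,
                           nucleus_density,
                           nucleus_axis_ratio,
                           nucleus_radius_px,
                           arrangement = c("papillary_clusters", "follicular_rings", "uniform"),
                           arrangement_strength = 1,
                           stain_jitter = 0.05) {
  arrangement <- match.arg(arrangement)
  if (!class_label %in% c("BRAF", "RAS")) abort("class_label must be 'BRAF' or 'RAS'")
  if (nucleus_density <= 0) abort("nucleus_density must be > 0")
  if (nucleus_axis_ratio < 1) abort("nucleus_axis_ratio must be >= 1")
  if (nucleus_radius_px < 2) abort("nucleus_radius_px must be >= 2")
  structure(
    list(
      class_label = class_label,
      nucleus_density = nucleus_density,
      nucleus_axis_ratio = nucleus_axis_ratio,
      nucleus_radius_px = nucleus_radius_px,
      arrangement = arrangement,
      arrangement_strength = arrangement_strength,
      stain_jitter = stain_jitter
    ),
    class = "wsi_phenotype"
  )
}

# default per-class parameters; the two presets differ in density, axis
# ratio, radius and arrangement (> 2 parameters, the separability knob)
phenotype_defaults <- list(
  BRAF = list(density = 90, ratio = 1.15, radius = 7, arrangement = "papillary_clusters"),
  RAS = list(density = 45, ratio = 1.90, radius = 8, arrangement = "follicular_rings")
)

#' Built-in phenotype presets
#'
#' With `separability = 1` the full class contrast is used; lower values
#' interpolate every numeric parameter toward the class midpoint and
#' weaken the spatial arrangement, so at 0 the two classes render
#' identically up to noise.
#'
#' @param class_label `"BRAF"` or `"RAS"`.
#' @param separability Morphologic class contrast in `[0, 1]`.
#' @param stain_jitter Per-slide stain perturbation scale.
#' @return A `wsi_phenotype`.
#' @export
#' @examples
#' phenotype_preset("RAS")$nucleus_axis_ratio
phenotype_preset <- function(class_label, separability = 1, stain_jitter = 0.05) {
  if (separability < 0 || separability > 1) abort("separability must be in [0, 1]")
  p <- phenotype_defaults[[class_label]]
  if (is.null(p)) abort("class_label must be 'BRAF' or 'RAS'")
  mid <- lapply(c("density", "ratio", "radius"), function(k) {
    mean(c(phenotype_defaults$BRAF[[k]], phenotype_defaults$RAS[[k]]))
  })
  names(mid) <- c("density", "ratio", "radius")
  lerp <- function(k) mid[[k]] + separability * (p[[k]] - mid[[k]])
  phenotype_spec(
    class_label = class_label,
    nucleus_density = lerp("density"),
    nucleus_axis_ratio = max(1, lerp("ratio")),
    nucleus_radius_px = lerp("radius"),
    arrangement = p$arrangement,
    # keep a uniform background fraction even at full contrast so no tile
    # is starved of nuclei by clustering alone
    arrangement_strength = 0.7 * separability,
    stain_jitter = stain_jitter
  )
}
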