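# Shared fixtures and independent oracles, built in code at test time.

# independent two-sided Fisher oracle: full hypergeometric enumeration over
# the table support, summing probabilities <= observed (with the standard
# relative slack for floating-point ties)
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) all-pairs concordance AUC oracle (ties count half)
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# closed-form Spearman rho on tie-free data
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

tile_lum <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# a small slide shared by several io/qc tests
small_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_slide(slide_spec(1024, 1024, seed = 404))
    }
    cache
  }
})

# fake patch records for sampler tests
fake_patches <- function(n, slide_id = "S1") {
  tibble::tibble(
    slide_id = slide_id,
    level = 0L,
    x = as.integer(512 * ((seq_len(n) - 1) %% 20)),
    y = as.integer(512 * ((seq_len(n) - 1) %/% 20)),
    size = 512L,
    nucleus_count = 30L,
    staining_density = 0.8,
    axis_ratio_mean = 1.2,
    axis_ratio_max = 1.5,
    tissue_fraction = 1,
    reason = "ok",
    accepted = TRUE
  )
}
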