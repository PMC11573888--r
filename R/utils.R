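#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap walk
#' @importFrom stats rnorm runif rpois quantile sd median setNames
#' @importFrom utils head tail
NULL

#' @importFrom magrittr %>%
#' @export
magrittr::`%>%`

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a 31-bit integer seed from an arbitrary key, stable across sessions
derive_seed <- function(...) {
  h <- digest::digest(list(...), algo = "xxhash32")
  strtoi(substr(h, 1, 7), 16L) %% .Machine$integer.max
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# image arrays are held either as doubles in [0,1] or as raw bytes
# (1 byte/pixel/channel; the storage used for pyramid levels so that
# slide-sized images stay small in memory)
to_raw_img <- function(arr) {
  if (is.raw(arr)) return(arr)
  array(as.raw(pmin(pmax(round(arr * 255), 0), 255)), dim(arr))
}

to_double_img <- function(arr) {
  if (!is.raw(arr)) return(arr)
  array(as.integer(arr) / 255, dim(arr))
}

img_channel <- function(arr, c) {
  ch <- arr[, , c]
  if (is.raw(ch)) matrix(as.integer(ch) / 255, dim(arr)[1], dim(arr)[2]) else ch
}

# mean-pool a matrix by an integer factor; trims trailing rows/cols that do
# not fill a complete block
pool_matrix <- function(m, f) {
  if (f == 1L) return(m)
  h <- (nrow(m) %/% f) * f
  w <- (ncol(m) %/% f) * f
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  a <- colMeans(matrix(m, nrow = f))            # pool rows -> (h/f * w)
  a <- matrix(a, nrow = h %/% f, ncol = w)
  a <- t(a)                                     # (w, h/f)
  a <- colMeans(matrix(a, nrow = f))            # pool cols
  t(matrix(a, nrow = w %/% f, ncol = h %/% f))
}

# mean-pool an H x W x C array channel-wise; always returns doubles
pool_array <- function(x, f) {
  if (f == 1L) return(to_double_img(x))
  ch <- lapply(seq_len(dim(x)[3]), function(c) pool_matrix(img_channel(x, c), f))
  out <- array(0, c(dim(ch[[1]]), length(ch)))
  for (c in seq_along(ch)) out[, , c] <- ch[[c]]
  out
}

# quantize [0,1] intensities to the 8-bit grid used by TIFF round trips
quantize8 <- function(x) round(clamp(x, 0, 1) * 255) / 255

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_rgb <- function(x, what = "image") {
  if (!is_rgb_array(x)) abort(paste0(what, " must be an H x W x 3 RGB array"))
  invisible(x)
}

# luminance (Rec. 601) of an RGB array in [0,1]
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# per-pixel HSV channels of an RGB array; returns list(h, s, v), h in [0,1]
rgb_to_hsv_maps <- function(rgb) {
  d <- dim(rgb)
  px <- rbind(
    as.vector(rgb[, , 1]),
    as.vector(rgb[, , 2]),
    as.vector(rgb[, , 3])
  )
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  list(
    h = matrix(hsv[1, ], d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}
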