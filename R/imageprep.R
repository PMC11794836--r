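#' Standardization configuration
#'
#' @param target_size Output dimensions; fixed at 32x32 for this pipeline.
#' @param pad_value Background value used when padding small images
#'   (default 1.0, a white micrograph background).
#' @return List of class `prep_config`.
#' @export
prep_config <- function(target_size = c(32L, 32L), pad_value = 1.0) {
  stopifnot(length(target_size) == 2, all(target_size >= 1),
            pad_value >= 0, pad_value <= 1)
  structure(list(target_size = as.integer(target_size), pad_value = pad_value),
            class = "prep_config")
}

# Area-averaging resampling matrix from n input rows to m output rows:
# entry (i, j) is the overlap of output cell i (width n/m in input units)
# with input cell j, normalized so rows sum to 1. Exact box filtering,
# hence constant-preserving and anti-aliasing for banding stripes.
area_weights <- function(n, m) {
  w <- matrix(0, nrow = m, ncol = n)
  scale <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j <- floor(lo):(ceiling(hi - 1e-12) - 1)
    j <- j[j >= 0 & j < n]
    w[i, j + 1] <- pmin(hi, j + 1) - pmax(lo, j)
  }
  w / scale
}

pad_axis <- function(n, m, pad_value) {
  # returns (before, after) pad sizes; odd remainder goes after (bottom/right)
  total <- m - n
  before <- total %/% 2L
  c(before, total - before)
}

#' Standardize a chromosome image to normalized 32x32
#'
#' Scales pixel values to `[0, 1]` (8-bit inputs are divided by 255;
#' float inputs must already lie in `[0, 1]` and are left untouched to
#' avoid contrast distortion of the banding), then per dimension either
#' pads (smaller than target: image centered, symmetric padding with the
#' background value, odd remainders to the bottom/right) or resamples
#' down by exact area averaging (larger than target). A 32x32 input in
#' `[0, 1]` is returned unchanged, so the padding path is idempotent.
#'
#' @param image A numeric matrix or a `chromo_image`.
#' @param config A [prep_config()].
#' @return Same type as the input, with 32x32 pixels in `[0, 1]`.
#' @export
standardize <- function(image, config = prep_config()) {
  if (inherits(image, "chromo_image")) {
    image$pixels <- standardize(image$pixels, config)
    return(image)
  }
  if (!is.matrix(image) || !is.numeric(image) || any(dim(image) == 0)) {
    stop("image must be a nonempty 2-D numeric matrix", call. = FALSE)
  }
  x <- image
  if (is.integer(x) || max(x) > 1) {
    x <- x / 255
    if (min(x) < 0 || max(x) > 1) stop("8-bit image values out of range", call. = FALSE)
  } else if (min(x) < 0) {
    stop("float image values must lie in [0, 1]", call. = FALSE)
  }
  x <- matrix(as.numeric(x), nrow = nrow(image))
  tgt <- config$target_size
  # rows
  if (nrow(x) > tgt[1]) {
    x <- area_weights(nrow(x), tgt[1]) %*% x
  } else if (nrow(x) < tgt[1]) {
    p <- pad_axis(nrow(x), tgt[1])
    x <- rbind(matrix(config$pad_value, p[1], ncol(x)), x,
               matrix(config$pad_value, p[2], ncol(x)))
  }
  # columns
  if (ncol(x) > tgt[2]) {
    x <- x %*% t(area_weights(ncol(x), tgt[2]))
  } else if (ncol(x) < tgt[2]) {
    p <- pad_axis(ncol(x), tgt[2])
    x <- cbind(matrix(config$pad_value, nrow(x), p[1]), x,
               matrix(config$pad_value, nrow(x), p[2]))
  }
  clamp01(x)
}
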