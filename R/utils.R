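#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm sd predict
#' @importFrom utils write.csv head
#' @importFrom Rcpp evalCpp
#' @useDynLib karyodetect, .registration = TRUE
NULL

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

clamp01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
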