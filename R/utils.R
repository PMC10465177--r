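# Internal helpers shared across modules.

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  invisible(x)
}

assert_same_size <- function(o, g) {
  if (!all(dim(o) == dim(g)))
    abort(sprintf(
      "Images must have identical dimensions (got %dx%d and %dx%d).",
      nrow(o), ncol(o), nrow(g), ncol(g)
    ))
  invisible(TRUE)
}

# Percent with round-half-away-from-zero, so 41.875 -> 42.
#' Convert a rate to a whole percent
#'
#' Rounds half away from zero, so an error rate of 0.41875 reports as 42%.
#'
#' @param rate Numeric rate(s) in \[0, 1\].
#' @return Integer percent(s).
#' @export
#' @examples
#' as_percent(134 / 320)
as_percent <- function(rate) {
  sign(rate) * floor(abs(rate) * 100 + 0.5)
}

# Separable Gaussian blur with reflective padding; works at any image size.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(n + 1 - seq_len(min(r, n))))
    # extend reflection if radius exceeds length
    while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    padded <- v[idx]
    as.numeric(stats::filter(padded, k, sides = 2))[(r + 1):(r + n)]
  }
  x2 <- apply(x, 2, blur_1d)
  t(apply(x2, 1, blur_1d))
}

# Downsample a matrix to nr x nc (area-average via EBImage).
downsample <- function(x, nr, nc) {
  EBImage::resize(x, w = nr, h = nc)
}
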