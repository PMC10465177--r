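#' Default trainable segmenter: a small encoder--decoder with skip connection
#'
#' A desk-scale segmenter honouring the contract of [leave_one_out()]:
#' images are resized to `image_size`, passed through a one-hidden-layer
#' encoder--decoder (tanh hidden, sigmoid output) with a per-pixel skip
#' connection from input to output — the skip plays the role the
#' skip paths play in U-Net-style segmenters, letting the model combine
#' local intensity evidence with the global shape prior learned by the
#' bottleneck. Trained full-batch with Adam against the mask binary
#' cross-entropy; predictions are thresholded at 0.5 and resized back to
#' the input geometry. No morphological post-processing is applied, so
#' scores reflect the raw predictor. Deterministic under `seed`.
#'
#' @param image_size Internal square working resolution (default 32).
#' @param hidden_dim Hidden width (default 48).
#' @param epochs Training epochs (default 600).
#' @param lr Adam learning rate (default 0.02).
#' @param seed Seed for initialization.
#' @return A segmenter: `function(images, masks)` returning a
#'   `function(image) -> 0/1 mask`.
#' @export
#' @examples
#' seg <- default_segmenter(image_size = 16, epochs = 50)
default_segmenter <- function(image_size = 32, hidden_dim = 48, epochs = 600,
                              lr = 0.02, seed = 1L) {
  force(image_size); force(hidden_dim); force(epochs); force(lr); force(seed)
  function(images, masks) {
    if (length(images) < 2) abort("Need >= 2 training pairs.")
    s <- image_size
    X <- t(vapply(images, function(im) as.numeric(downsample(im, s, s)) / 255,
                  numeric(s * s)))
    Yt <- t(vapply(masks, function(m) {
      as.numeric(downsample(m + 0, s, s) > 0.5) + 0
    }, numeric(s * s)))
    d <- ncol(X); n <- nrow(X); h <- hidden_dim
    with_seed(seed, {
      W1 <- glorot(d, h); b1 <- rep(0, h)
      W2 <- glorot(h, d); b2 <- rep(0, d)
      ws <- rep(0, d)                       # per-pixel input-to-output skip
      st <- purrr::map(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, ws = ws), new_adam)
      for (ep in seq_len(epochs)) {
        H <- tanh(sweep(X %*% W1, 2, b1, "+"))
        P <- sigmoid(sweep(H %*% W2, 2, b2, "+") + sweep(X, 2, ws, "*"))
        if (!all(is.finite(P))) abort("Non-finite loss in segmenter training.")
        dZ <- (P - Yt) / (n * d)            # BCE-through-sigmoid
        dH <- (dZ %*% t(W2)) * (1 - H^2)
        grads <- list(
          W1 = crossprod(X, dH), b1 = colSums(dH),
          W2 = crossprod(H, dZ), b2 = colSums(dZ),
          ws = colSums(dZ * X)
        )
        for (nm in names(grads)) {
          w <- switch(nm, W1 = W1, b1 = b1, W2 = W2, b2 = b2, ws = ws)
          u <- adam_step(w, grads[[nm]], st[[nm]], lr, ep)
          st[[nm]] <- u$st
          assign(nm, u$w)
        }
      }
      function(image) {
        hh <- nrow(image); ww <- ncol(image)
        x <- matrix(as.numeric(downsample(image, s, s)) / 255, 1)
        H <- tanh(x %*% W1 + matrix(b1, 1))
        P <- sigmoid(H %*% W2 + matrix(b2, 1) + x * ws)
        small <- matrix(as.numeric(P), s, s)
        up <- downsample(small, hh, ww)
        matrix(as.integer(up > 0.5), hh, ww)
      }
    })
  }
}
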