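#' Training configuration for the adversarial autoencoder
#'
#' Defaults follow the study profile (250x250 inputs, 2,000 epochs); the
#' examples and tests use a desk-scale profile (small square images, tens of
#' epochs) which exercises the identical code path.
#'
#' @param epochs Training epochs, >= 1 (default 2000).
#' @param image_size Square, even image side in pixels (default 250 is
#'   rounded up to the even 250; inputs are resized when they differ).
#' @param latent_dim Latent dimension (default 64).
#' @param hidden_dim Hidden layer width of encoder/decoder (default 128).
#' @param lr Learning rate for the autoencoder (default 0.02).
#' @param lr_adv Learning rate for the adversarial phases (default 0.005).
#' @param adv_weight Weight of the latent adversarial term in the generator
#'   update (default 0.05).
#' @param seed Seed controlling initialization and every draw.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 2000, image_size = 250, latent_dim = 64,
                         hidden_dim = 128, lr = 0.02, lr_adv = 0.005,
                         adv_weight = 0.05, seed = 1L) {
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (image_size %% 2 != 0) image_size <- image_size + 1
  structure(
    list(epochs = as.integer(epochs), image_size = as.integer(image_size),
         latent_dim = as.integer(latent_dim), hidden_dim = as.integer(hidden_dim),
         lr = lr, lr_adv = lr_adv, adv_weight = adv_weight,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# ---- internal MLP machinery (base R; deterministic under seed) -------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Adam state kept alongside each weight matrix
adam_step <- function(w, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), st = st)
}

new_adam <- function(w) list(m = w * 0, v = w * 0)

#' Train an adversarial autoencoder on an image group
#'
#' The generator is an encoder--decoder MLP (image -> tanh hidden -> latent;
#' latent -> tanh hidden -> sigmoid image); a discriminator MLP on the
#' latent space is trained to separate encoded latents from draws of the
#' standard-normal prior, and the encoder is simultaneously pushed to fool
#' it (the usual min--max adversarial objective). The reconstruction
#' objective is the configured loss between the real batch and its
#' reconstruction; all six losses plug in through their analytic gradients.
#'
#' Images are rescaled to `config$image_size` and intensities to \[0, 1\]
#' internally. Training is full-batch Adam and is a pure function of
#' `(images, spec, config)` including the config seed. Reconstruction MSE is
#' recorded every epoch; training aborts if the loss turns non-finite.
#'
#' @param images Image tibble (as from [make_dataset()]) or list of numeric
#'   matrices in \[0, 255\]; >= 2 images, all the same size.
#' @param spec A [loss_spec()] naming the reconstruction loss.
#' @param config A [train_config()].
#' @return An `aae_model` object with the trained weights, the loss-group
#'   label, the per-epoch reconstruction-MSE history and the config.
#' @export
#' @examples
#' ds <- make_dataset(4, default_params_sampler(c(32, 32)), seed = 3)
#' m <- train_aae(ds, loss_spec("LS"), train_config(epochs = 10, image_size = 32,
#'   hidden_dim = 32, latent_dim = 8))
#' glance(m)
train_aae <- function(images, spec, config = train_config()) {
  imgs <- if (is.data.frame(images)) images$image else images
  if (length(imgs) < 2) abort("Need at least 2 training images.")
  dims <- unique(purrr::map(imgs, dim))
  if (length(dims) != 1) abort("All training images must have the same size.")
  s <- config$image_size
  X <- t(vapply(imgs, function(im) {
    if (!all(dim(im) == c(s, s))) im <- downsample(im, s, s)
    as.numeric(im) / 255
  }, numeric(s * s)))      # n x d, values in [0, 1]
  n <- nrow(X); d <- ncol(X)
  h <- config$hidden_dim; k <- config$latent_dim

  with_seed(config$seed, {
    W <- list(
      e1 = glorot(d, h), be1 = rep(0, h),
      e2 = glorot(h, k), be2 = rep(0, k),
      d1 = glorot(k, h), bd1 = rep(0, h),
      d2 = glorot(h, d), bd2 = rep(0, d),
      a1 = glorot(k, h), ba1 = rep(0, h),
      a2 = glorot(h, 1), ba2 = 0
    )
    st <- purrr::map(W, new_adam)

    fwd_enc <- function(X) {
      H <- tanh(sweep(X %*% W$e1, 2, W$be1, "+"))
      Z <- sweep(H %*% W$e2, 2, W$be2, "+")
      list(H = H, Z = Z)
    }
    fwd_dec <- function(Z) {
      H <- tanh(sweep(Z %*% W$d1, 2, W$bd1, "+"))
      Y <- sigmoid(sweep(H %*% W$d2, 2, W$bd2, "+"))
      list(H = H, Y = Y)
    }
    fwd_disc <- function(Z) {
      H <- tanh(sweep(Z %*% W$a1, 2, W$ba1, "+"))
      P <- sigmoid(H %*% W$a2 + W$ba2)
      list(H = H, P = P)
    }

    mse_history <- numeric(config$epochs)
    init_mse <- {
      e <- fwd_enc(X); y <- fwd_dec(e$Z)$Y
      mean((X - y)^2)
    }

    for (ep in seq_len(config$epochs)) {
      ## --- reconstruction phase -----------------------------------------
      enc <- fwd_enc(X)
      dec <- fwd_dec(enc$Z)
      Y <- dec$Y
      if (!all(is.finite(Y))) abort("Non-finite activations during training.")
      L <- eval_loss(spec, X, Y)
      if (!is.finite(L)) abort(sprintf("Non-finite %s loss at epoch %d.", spec$name, ep))
      dY <- loss_grad(spec, X, Y)           # dL/dY, n x d
      dA2 <- dY * Y * (1 - Y)               # through sigmoid
      g_d2 <- crossprod(dec$H, dA2); g_bd2 <- colSums(dA2)
      dH2 <- (dA2 %*% t(W$d2)) * (1 - dec$H^2)
      g_d1 <- crossprod(enc$Z, dH2); g_bd1 <- colSums(dH2)
      dZ <- dH2 %*% t(W$d1)
      dH1 <- (dZ %*% t(W$e2)) * (1 - enc$H^2)
      g_e2 <- crossprod(enc$H, dZ); g_be2 <- colSums(dZ)
      g_e1 <- crossprod(X, dH1); g_be1 <- colSums(dH1)
      for (nm in c("e1", "be1", "e2", "be2", "d1", "bd1", "d2", "bd2")) {
        g <- switch(nm, e1 = g_e1, be1 = g_be1, e2 = g_e2, be2 = g_be2,
                    d1 = g_d1, bd1 = g_bd1, d2 = g_d2, bd2 = g_bd2)
        upd <- adam_step(W[[nm]], g, st[[nm]], config$lr, ep)
        W[[nm]] <- upd$w; st[[nm]] <- upd$st
      }

      ## --- discriminator phase (prior = 1, encoded = 0) ------------------
      Zfake <- fwd_enc(X)$Z
      Zreal <- matrix(rnorm(n * k), n, k)
      Zb <- rbind(Zreal, Zfake)
      tb <- c(rep(1, n), rep(0, n))
      di <- fwd_disc(Zb)
      dP <- (di$P - tb) / (2 * n)           # BCE-through-sigmoid gradient
      g_a2 <- crossprod(di$H, dP); g_ba2 <- sum(dP)
      dHd <- (dP %*% t(W$a2)) * (1 - di$H^2)
      g_a1 <- crossprod(Zb, dHd); g_ba1 <- colSums(dHd)
      for (nm in c("a1", "ba1", "a2", "ba2")) {
        g <- switch(nm, a1 = g_a1, ba1 = g_ba1, a2 = g_a2, ba2 = g_ba2)
        upd <- adam_step(W[[nm]], g, st[[nm]], config$lr_adv, ep)
        W[[nm]] <- upd$w; st[[nm]] <- upd$st
      }

      ## --- generator (encoder) phase: fool the discriminator -------------
      enc <- fwd_enc(X)
      di <- fwd_disc(enc$Z)
      dP <- config$adv_weight * (di$P - 1) / n
      dHd <- (dP %*% t(W$a2)) * (1 - di$H^2)
      dZ <- dHd %*% t(W$a1)
      dH1 <- (dZ %*% t(W$e2)) * (1 - enc$H^2)
      g_e2 <- crossprod(enc$H, dZ); g_be2 <- colSums(dZ)
      g_e1 <- crossprod(X, dH1); g_be1 <- colSums(dH1)
      for (nm in c("e1", "be1", "e2", "be2")) {
        g <- switch(nm, e1 = g_e1, be1 = g_be1, e2 = g_e2, be2 = g_be2)
        upd <- adam_step(W[[nm]], g, st[[nm]], config$lr_adv, ep)
        W[[nm]] <- upd$w; st[[nm]] <- upd$st
      }

      e <- fwd_enc(X); y <- fwd_dec(e$Z)$Y
      mse_history[ep] <- mean((X - y)^2)
    }

    structure(
      list(weights = W, spec = spec, config = config,
           group = spec$name, n_train = n,
           init_mse = init_mse, mse_history = mse_history,
           final_loss = eval_loss(spec, X, fwd_dec(fwd_enc(X)$Z)$Y)),
      class = "aae_model"
    )
  })
}

#' Reconstruct images through a trained model
#'
#' @param model An `aae_model`.
#' @param images Image tibble or list of matrices.
#' @return List of reconstructed image matrices in \[0, 255\].
#' @export
reconstruct <- function(model, images) {
  imgs <- if (is.data.frame(images)) images$image else images
  s <- model$config$image_size
  W <- model$weights
  purrr::map(imgs, function(im) {
    if (!all(dim(im) == c(s, s))) im <- downsample(im, s, s)
    x <- matrix(as.numeric(im) / 255, 1)
    H <- tanh(x %*% W$e1 + matrix(W$be1, 1))
    Z <- H %*% W$e2 + matrix(W$be2, 1)
    Hd <- tanh(Z %*% W$d1 + matrix(W$bd1, 1))
    Y <- sigmoid(Hd %*% W$d2 + matrix(W$bd2, 1))
    matrix(clamp255(as.numeric(Y) * 255), s, s)
  })
}

#' Synthesize new images from a trained model
#'
#' Draws `n` latent vectors from the standard-normal prior and decodes
#' them. Every image is tagged with the model's loss-group label.
#'
#' @param model A trained `aae_model`.
#' @param n Number of images, >= 1.
#' @param seed Seed for the latent draws.
#' @return Image tibble (`id`, `group`, `image`); intensities in \[0, 255\].
#' @export
synthesize <- function(model, n, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  s <- model$config$image_size
  W <- model$weights
  with_seed(seed, {
    Z <- matrix(rnorm(n * model$config$latent_dim), n)
    Hd <- tanh(sweep(Z %*% W$d1, 2, W$bd1, "+"))
    Y <- sigmoid(sweep(Hd %*% W$d2, 2, W$bd2, "+"))
    tibble(
      id = sprintf("%s_%03d", model$group, seq_len(n)),
      group = model$group,
      image = purrr::map(seq_len(n), function(i) {
        matrix(clamp255(Y[i, ] * 255), s, s)
      })
    )
  })
}

#' @export
print.aae_model <- function(x, ...) {
  cat(sprintf(
    "<aae_model> loss=%s  images=%d  epochs=%d  size=%dx%d\n  reconstruction MSE: %.5f -> %.5f\n",
    x$group, x$n_train, x$config$epochs, x$config$image_size,
    x$config$image_size, x$init_mse, x$mse_history[length(x$mse_history)]
  ))
  invisible(x)
}

#' Tidy the training history of an AAE
#'
#' @param x An `aae_model`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `reconstruction_mse`.
#' @export
tidy.aae_model <- function(x, ...) {
  tibble(epoch = seq_along(x$mse_history), reconstruction_mse = x$mse_history)
}

#' One-row summary of a trained AAE
#'
#' @inheritParams tidy.aae_model
#' @return One-row tibble: loss group, epochs, initial and final
#'   reconstruction MSE, final configured-loss value.
#' @export
glance.aae_model <- function(x, ...) {
  tibble(
    loss = x$group, epochs = x$config$epochs, n_train = x$n_train,
    initial_mse = x$init_mse,
    final_mse = x$mse_history[length(x$mse_history)],
    final_loss = x$final_loss
  )
}
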