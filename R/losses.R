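#' Specification of a discriminator / reconstruction loss
#'
#' Bundles the loss name with its hyper-parameters: `alpha` weights the L1
#' term of the BCE+L1 loss (default 1e-4) and `epsilon` regularizes the
#' Poisson loss logarithm (default 0.25).
#'
#' @param name One of `"BCE"`, `"BCE_L1"`, `"LS"`, `"POISSON"`, `"WASS"`,
#'   `"P_WASS"`.
#' @param alpha L1 weight, >= 0.
#' @param epsilon Poisson regularizer, > 0.
#' @return A `loss_spec` object.
#' @export
#' @examples
#' loss_spec("P_WASS")
loss_spec <- function(name, alpha = 1e-4, epsilon = 0.25) {
  name <- match.arg(toupper(name), loss_names())
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (epsilon <= 0) abort("`epsilon` must be > 0.")
  structure(list(name = name, alpha = alpha, epsilon = epsilon),
            class = "loss_spec")
}

# numerical floor keeping log() finite; documented so tests can be exact
BCE_DELTA <- 1e-7

check_batch <- function(y, y_prime) {
  if (length(y) == 0 || length(y_prime) == 0) abort("Empty batch.")
  if (!all(dim(as.array(y)) == dim(as.array(y_prime))))
    abort("`y` and `y_prime` must have the same shape.")
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood `-(y log y' + (1-y) log(1-y'))` over all
#' elements, with predictions clipped to `(1e-7, 1 - 1e-7)` before the
#' logarithm. Targets and predictions live in \[0, 1\].
#'
#' @param y Target array (real images scaled to \[0, 1\] or 0/1 labels).
#' @param y_prime Prediction array, same shape, values in \[0, 1\].
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5)) # log(2)
bce_loss <- function(y, y_prime) {
  check_batch(y, y_prime)
  if (any(y_prime < 0 | y_prime > 1))
    abort("`y_prime` must lie in [0, 1] before clipping.")
  yp <- pmin(pmax(y_prime, BCE_DELTA), 1 - BCE_DELTA)
  -mean(y * log(yp) + (1 - y) * log(1 - yp))
}

#' BCE plus a weighted L1 term
#'
#' `bce_loss(y, y') + alpha * mean(|y - y'|)`; `alpha = 0` reduces exactly
#' to [bce_loss()].
#'
#' @inheritParams bce_loss
#' @param alpha L1 weight, >= 0 (default 1e-4).
#' @export
bce_l1_loss <- function(y, y_prime, alpha = 1e-4) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  bce_loss(y, y_prime) + alpha * mean(abs(y - y_prime))
}

#' Least-squares loss
#'
#' Mean squared difference; zero iff the batches are identical.
#' @inheritParams bce_loss
#' @export
ls_loss <- function(y, y_prime) {
  check_batch(y, y_prime)
  mean((y - y_prime)^2)
}

#' Poisson loss
#'
#' `mean((y' - y) * log(y' + epsilon))`. Can be negative; the sign carries
#' information about under- versus over-prediction.
#'
#' @inheritParams bce_loss
#' @param epsilon Regularizer keeping the logarithm finite, > 0 (default 0.25).
#' @export
#' @examples
#' poisson_loss(0, 1) # log(1.25)
poisson_loss <- function(y, y_prime, epsilon = 0.25) {
  check_batch(y, y_prime)
  if (any(y_prime + epsilon <= 0)) abort("`y_prime + epsilon` must be > 0.")
  mean((y_prime - y) * log(y_prime + epsilon))
}

#' Order-1 Wasserstein loss (1-D sorted-sample transport)
#'
#' Treats the flattened batches as two empirical distributions of equal
#' size and returns the exact 1-D optimal transport cost with absolute-value
#' ground distance: the mean absolute difference of the sorted samples.
#'
#' @inheritParams bce_loss
#' @return Scalar >= 0; 0 for identical distributions.
#' @export
#' @examples
#' wasserstein_loss(0, 1) # point masses at 0 and 1 -> 1
wasserstein_loss <- function(y, y_prime) {
  check_batch(y, y_prime)
  mean(abs(sort(as.numeric(y)) - sort(as.numeric(y_prime))))
}

#' Perceptual Wasserstein loss (squared ground distance)
#'
#' Same optimal 1-D transport plan as [wasserstein_loss()] but with squared
#' L2 ground distance: the mean squared difference of the sorted samples.
#'
#' @inheritParams bce_loss
#' @return Scalar >= 0; 0 iff the distributions coincide.
#' @export
perceptual_wasserstein_loss <- function(y, y_prime) {
  check_batch(y, y_prime)
  mean((sort(as.numeric(y)) - sort(as.numeric(y_prime)))^2)
}

#' Evaluate a loss by specification
#'
#' @param spec A [loss_spec()].
#' @param y,y_prime Batch arrays.
#' @return Scalar loss value.
#' @export
eval_loss <- function(spec, y, y_prime) {
  switch(spec$name,
    BCE = bce_loss(y, y_prime),
    BCE_L1 = bce_l1_loss(y, y_prime, spec$alpha),
    LS = ls_loss(y, y_prime),
    POISSON = poisson_loss(y, y_prime, spec$epsilon),
    WASS = wasserstein_loss(y, y_prime),
    P_WASS = perceptual_wasserstein_loss(y, y_prime)
  )
}

# Gradient of each loss w.r.t. y_prime (same shape as y_prime); used by the
# AAE trainer. For the transport losses the elementwise gradient is computed
# on the sorted matching and mapped back through the sort permutation.
loss_grad <- function(spec, y, y_prime) {
  n <- length(y)
  g <- switch(spec$name,
    BCE = {
      yp <- pmin(pmax(y_prime, BCE_DELTA), 1 - BCE_DELTA)
      -(y / yp - (1 - y) / (1 - yp)) / n
    },
    BCE_L1 = {
      yp <- pmin(pmax(y_prime, BCE_DELTA), 1 - BCE_DELTA)
      -(y / yp - (1 - y) / (1 - yp)) / n + spec$alpha * sign(y_prime - y) / n
    },
    LS = 2 * (y_prime - y) / n,
    POISSON = (log(y_prime + spec$epsilon) +
                 (y_prime - y) / (y_prime + spec$epsilon)) / n,
    WASS = {
      oy <- order(as.numeric(y)); op <- order(as.numeric(y_prime))
      gr <- numeric(n)
      gr[op] <- sign(as.numeric(y_prime)[op] - as.numeric(y)[oy]) / n
      gr
    },
    P_WASS = {
      oy <- order(as.numeric(y)); op <- order(as.numeric(y_prime))
      gr <- numeric(n)
      gr[op] <- 2 * (as.numeric(y_prime)[op] - as.numeric(y)[oy]) / n
      gr
    }
  )
  array(g, dim = dim(as.array(y_prime)))
}
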