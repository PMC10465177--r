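# Segmentation evaluation: classical augmentation, vote-thresholded
# training sets, confusion-based mask scores, FP/FN overlays, and the
# leave-one-out harness.

#' Classical augmentation of an image/mask pair
#'
#' `flip` mirrors horizontally, `rotate` rotates by 90 degrees (apply k
#' times for k quarter-turns) — both exact, mask-preserving transforms.
#' `crop` takes a seeded random crop of `crop_frac` of the canvas and
#' resizes back (mask re-binarized at 0.5). `whiten` standardizes the image
#' intensities and rescales to \[0, 255\], leaving the mask untouched.
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param mask 0/1 matrix of the same size.
#' @param op One of `"flip"`, `"rotate"`, `"whiten"`, `"crop"`.
#' @param seed Seed (used by `crop`).
#' @param crop_frac Linear fraction of the canvas kept by `crop`.
#' @return List with `image` and `mask`.
#' @export
classical_augment <- function(image, mask, op = c("flip", "rotate", "whiten", "crop"),
                              seed = 1L, crop_frac = 0.8) {
  op <- tryCatch(match.arg(op), error = function(e) abort(
    sprintf("Unknown op '%s'.", op[1])))
  assert_image(image); assert_same_size(image, mask)
  switch(op,
    flip = list(image = image[, ncol(image):1], mask = mask[, ncol(mask):1]),
    rotate = {
      rot90 <- function(m) t(m)[nrow(m):1, , drop = FALSE]
      list(image = rot90(image), mask = rot90(mask))
    },
    whiten = {
      s <- sd(as.numeric(image))
      img <- if (s == 0) image else (image - mean(image)) / s
      rng <- range(img)
      img <- if (diff(rng) == 0) img * 0 else (img - rng[1]) / diff(rng) * 255
      list(image = img, mask = mask)
    },
    crop = with_seed(seed, {
      h <- nrow(image); w <- ncol(image)
      ch <- max(2L, round(crop_frac * h)); cw <- max(2L, round(crop_frac * w))
      r0 <- sample.int(h - ch + 1L, 1); c0 <- sample.int(w - cw + 1L, 1)
      sub_i <- image[r0:(r0 + ch - 1), c0:(c0 + cw - 1)]
      sub_m <- mask[r0:(r0 + ch - 1), c0:(c0 + cw - 1)]
      img <- downsample(sub_i, h, w)
      msk <- matrix(as.integer(downsample(sub_m, h, w) > 0.5), h, w)
      list(image = clamp255(img), mask = msk)
    })
  )
}

#' Build a classical-augmentation pool from originals
#'
#' One augmented pair per original, cycling through the four ops with
#' seeded crops.
#'
#' @param originals Image tibble with `id`, `image`, `mask`.
#' @param n Pool size (default one per original).
#' @param seed Master seed.
#' @return Image tibble with `group = "classical"`.
#' @export
classical_pool <- function(originals, n = nrow(originals), seed = 1L) {
  ops <- c("flip", "rotate", "whiten", "crop")
  seeds <- derive_seeds(seed, n)
  rows <- purrr::map(seq_len(n), function(i) {
    src <- ((i - 1) %% nrow(originals)) + 1
    aug <- classical_augment(originals$image[[src]], originals$mask[[src]],
                             ops[((i - 1) %% 4) + 1], seed = seeds[i])
    tibble(id = sprintf("classical_%03d", i), group = "classical",
           image = list(aug$image), mask = list(aug$mask))
  })
  dplyr::bind_rows(rows)
}

#' Build a vote-thresholded training set
#'
#' All originals are kept; synthetic images whose expert-vote count passes
#' the threshold fill as many of the remaining slots as they can (capped at
#' `total - nrow(originals)`, highest-voted first); classical augmentations
#' fill the rest. `mode = "at_least"` admits images with `votes >= k`;
#' `mode = "exact"` admits `votes == k` (the "validated by exactly k
#' experts" reading).
#'
#' @param originals Image tibble (all included).
#' @param synthetic_pool Image tibble with a `votes` column.
#' @param classical Image tibble of classical augmentations.
#' @param k Vote threshold (e.g. 0, 2, 4, 6, 8).
#' @param total Training-set size (default 80).
#' @param mode `"at_least"` or `"exact"`.
#' @return Image tibble of `total` rows with a `provenance` column; the
#'   composition is attached as attribute `"composition"` and messaged.
#' @export
build_training_set <- function(originals, synthetic_pool, classical,
                               k, total = 80, mode = c("at_least", "exact")) {
  mode <- match.arg(mode)
  stopifnot("votes" %in% names(synthetic_pool))
  n_orig <- nrow(originals)
  if (n_orig > total) abort("`total` is smaller than the number of originals.")
  slots <- total - n_orig
  eligible <- switch(mode,
    at_least = synthetic_pool[synthetic_pool$votes >= k, ],
    exact = synthetic_pool[synthetic_pool$votes == k, ]
  )
  eligible <- eligible[order(-eligible$votes), ]
  syn <- head(eligible, slots)
  n_classical <- slots - nrow(syn)
  if (nrow(classical) < n_classical)
    abort(sprintf("Classical pool too small: need %d, have %d.",
                  n_classical, nrow(classical)))
  cls <- head(classical, n_classical)
  out <- dplyr::bind_rows(
    dplyr::mutate(originals[, c("id", "group", "image", "mask")], provenance = "original"),
    dplyr::mutate(syn[, c("id", "group", "image", "mask")], provenance = "synthetic"),
    dplyr::mutate(cls[, c("id", "group", "image", "mask")], provenance = "classical")
  )
  comp <- c(n_original = n_orig, n_synthetic = nrow(syn), n_classical = nrow(cls))
  inform(sprintf("Training set: %d original + %d synthetic (votes %s %d) + %d classical = %d.",
                 comp[1], comp[2], if (mode == "at_least") ">=" else "==",
                 k, comp[3], sum(comp)))
  attr(out, "composition") <- comp
  out
}

#' Confusion-based segmentation scores
#'
#' Per-pixel confusion of a predicted mask `u` against ground truth `gt`:
#' Dice `2 TP / (2 TP + FP + FN)`, accuracy, sensitivity (recall),
#' specificity, precision, and F1 (harmonic mean of precision and
#' sensitivity — algebraically equal to Dice). Ratios with zero
#' denominators are NaN with a warning.
#'
#' @param gt,u 0/1 matrices of the same shape.
#' @return One-row tibble: `dice`, `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, plus the raw `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' seg_scores(m, m)$dice
seg_scores <- function(gt, u) {
  if (!all(dim(gt) == dim(u))) abort("Masks must have the same shape.")
  if (!all(gt %in% c(0, 1)) || !all(u %in% c(0, 1)))
    abort("Masks must be 0/1.")
  tp <- sum(gt == 1 & u == 1); fp <- sum(gt == 0 & u == 1)
  tn <- sum(gt == 0 & u == 0); fn <- sum(gt == 1 & u == 0)
  safe <- function(num, den) if (den == 0) { warn("Zero denominator in segmentation score."); NaN } else num / den
  sens <- safe(tp, tp + fn); prec <- safe(tp, tp + fp)
  tibble(
    dice = safe(2 * tp, 2 * tp + fp + fn),
    accuracy = safe(tp + tn, tp + fp + tn + fn),
    sensitivity = sens,
    specificity = safe(tn, tn + fp),
    precision = prec,
    f1 = if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN
         else 2 * prec * sens / (prec + sens),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' FP/FN overlay of a predicted mask on its image
#'
#' False-positive pixels are painted light pink, false negatives light
#' green, all other pixels keep their grayscale value — so the pixel
#' classes are exactly recoverable from the colors.
#'
#' @param gt,u 0/1 masks of the same shape.
#' @param image Grayscale matrix in \[0, 255\].
#' @return `h x w x 3` array in \[0, 1\] (RGB).
#' @export
overlay <- function(gt, u, image) {
  if (!all(dim(gt) == dim(u)) || !all(dim(gt) == dim(image)))
    abort("Masks and image must share the same shape.")
  lightpink <- c(255, 182, 193) / 255
  lightgreen <- c(144, 238, 144) / 255
  g <- image / 255
  out <- array(rep(g, 3), dim = c(dim(image), 3))
  fp <- gt == 0 & u == 1
  fn <- gt == 1 & u == 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fp] <- lightpink[ch]
    plane[fn] <- lightgreen[ch]
    out[, , ch] <- plane
  }
  out
}

#' Leave-one-out segmentation harness
#'
#' One training session per original image: the held-out pair is removed,
#' `set_builder(held_out_id)` assembles the session's training tibble (it
#' must not contain the held-out id — leakage aborts the run), `segmenter`
#' is trained on it, and the held-out prediction is scored against ground
#' truth.
#'
#' @param originals Image tibble with `id`, `image`, `mask` (>= 2 rows).
#' @param set_builder Function `held_out_id -> training tibble`; defaults
#'   to training on the remaining originals.
#' @param segmenter Function `(images, masks) -> function(image) -> mask`
#'   (see [default_segmenter()] and [oracle_segmenter()]).
#' @param scorer Scoring function `(gt, u) -> one-row tibble`
#'   (default [seg_scores()]).
#' @return List with `per_image` (tibble of scores, one row per session)
#'   and `means` (one-row tibble of mean scores).
#' @export
leave_one_out <- function(originals, set_builder = NULL,
                          segmenter = oracle_segmenter(originals),
                          scorer = seg_scores) {
  if (nrow(originals) < 2) abort("Need >= 2 originals.")
  if (is.null(set_builder)) {
    set_builder <- function(held_out_id) {
      originals[originals$id != held_out_id, ]
    }
  }
  rows <- purrr::map_dfr(seq_len(nrow(originals)), function(i) {
    held <- originals[i, ]
    train <- set_builder(held$id)
    if (held$id %in% train$id)
      abort(sprintf("Leakage: held-out image '%s' found in its training set.", held$id))
    predict_fn <- segmenter(train$image, train$mask)
    pred <- predict_fn(held$image[[1]])
    dplyr::bind_cols(tibble(id = held$id), scorer(held$mask[[1]], pred))
  })
  score_cols <- c("dice", "accuracy", "sensitivity", "specificity", "precision", "f1")
  means <- rows |>
    dplyr::summarise(dplyr::across(dplyr::any_of(score_cols), ~ mean(.x, na.rm = TRUE)))
  list(per_image = rows, means = means, n_sessions = nrow(rows))
}

#' Oracle segmenter (harness sanity check)
#'
#' Builds a segmenter that ignores its training input and returns the true
#' mask of any image found in `reference` (matched by exact pixel
#' equality), so the leave-one-out harness must score Dice 1.0. Used to
#' validate the harness plumbing, not to segment.
#'
#' @param reference Image tibble with `image` and `mask` covering every
#'   image that will be predicted.
#' @return A segmenter `(images, masks) -> predictor` suitable for
#'   [leave_one_out()].
#' @export
oracle_segmenter <- function(reference) {
  force(reference)
  function(images, masks) {
    function(image) {
      for (i in seq_len(nrow(reference))) {
        if (identical(dim(reference$image[[i]]), dim(image)) &&
            all(reference$image[[i]] == image)) {
          return(reference$mask[[i]])
        }
      }
      abort("Oracle segmenter: image not found in its reference set.")
    }
  }
}
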