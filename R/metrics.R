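# Seven-metric similarity / quality suite and its group aggregation protocol.
#
# All pairwise metrics take two numeric matrices with intensities in
# [0, 255]; FID compares two image *groups*. Sample moments use the usual
# n-1 denominators throughout (R's var/cov), and all logarithms are natural
# unless a metric's definition fixes the base (PSNR uses log10).

img_list <- function(x) {
  if (is.data.frame(x)) x$image else if (is.matrix(x)) list(x) else x
}

# default FID feature recipe: per-image (mean, sd, 8x8 area-downsample) on
# the [0, 1] intensity scale -> 66-dim vector
fid_features <- function(img) {
  x <- img / 255
  c(mean(x), sd(as.numeric(x)), as.numeric(downsample(x, 8, 8)))
}

# symmetric PSD square root via eigendecomposition, clipping tiny negatives
sqrtm_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two image groups
#'
#' Gaussians are fit to per-image pixel-statistic feature vectors (default:
#' mean, standard deviation and an 8x8 downsample of each image) and the
#' Frechet distance `||mu_A - mu_B||^2 + Tr(S_A + S_B - 2 (S_A S_B)^(1/2))`
#' is returned. Symmetric; 0 for identical groups. When a covariance is
#' (near-)singular a small diagonal loading is added and reported via a
#' message.
#'
#' @param groupA,groupB Image tibbles or lists of matrices, each >= 2 images.
#' @param feature_fun Function image -> numeric feature vector.
#' @param ridge Diagonal loading used when covariances are singular.
#' @return Scalar >= 0.
#' @export
#' @examples
#' ds <- make_dataset(3, default_params_sampler(c(32, 32)), seed = 1)
#' fid(ds, ds) # 0
fid <- function(groupA, groupB, feature_fun = fid_features, ridge = 1e-8) {
  A <- img_list(groupA); B <- img_list(groupB)
  if (length(A) < 2 || length(B) < 2) abort("Each group needs >= 2 images.")
  proto <- feature_fun(A[[1]])
  FA <- vapply(A, feature_fun, proto)
  FB <- vapply(B, feature_fun, proto)
  if (length(proto) == 1) {
    FA <- matrix(FA, ncol = 1); FB <- matrix(FB, ncol = 1)
  } else {
    FA <- t(FA); FB <- t(FB)
  }
  muA <- colMeans(FA); muB <- colMeans(FB)
  SA <- cov(FA); SB <- cov(FB)
  k <- ncol(FA)
  if (min(eigen(SA, symmetric = TRUE, only.values = TRUE)$values,
          eigen(SB, symmetric = TRUE, only.values = TRUE)$values) < ridge) {
    inform("Singular covariance in FID; applying diagonal loading.")
    SA <- SA + diag(ridge, k); SB <- SB + diag(ridge, k)
  }
  sA <- sqrtm_psd(SA)
  cross <- sqrtm_psd(sA %*% SB %*% sA)
  val <- sum((muA - muB)^2) + sum(diag(SA + SB - 2 * cross))
  max(val, 0)
}

#' Structural similarity index (global)
#'
#' Evaluated on whole-image statistics with the standard stabilising
#' constants `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, dynamic range `L = 255`.
#' Equals 1 for identical images (including identical constants, which the
#' constants guard against 0/0).
#'
#' @param o,g Numeric matrices of equal size.
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(o, g) {
  assert_image(o, "o"); assert_image(g, "g"); assert_same_size(o, g)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mo <- mean(o); mg <- mean(g)
  vo <- var(as.numeric(o)); vg <- var(as.numeric(g))
  cog <- cov(as.numeric(o), as.numeric(g))
  ((2 * mo * mg + c1) * (2 * cog + c2)) /
    ((mo^2 + mg^2 + c1) * (vo + vg + c2))
}

#' Universal quality index
#'
#' `4 mu_o mu_g sigma_og / ((mu_o^2 + mu_g^2)(sigma_o^2 + sigma_g^2))`,
#' where `sigma_og` is the covariance of the two images; 1 for identical
#' non-constant images. When both images are constant the variance term
#' vanishes and the luminance term `2 mu_o mu_g / (mu_o^2 + mu_g^2)` is
#' returned with a warning (its limit value).
#'
#' @inheritParams ssim
#' @return Scalar in \[-1, 1\].
#' @export
uqm <- function(o, g) {
  assert_image(o, "o"); assert_image(g, "g"); assert_same_size(o, g)
  mo <- mean(o); mg <- mean(g)
  vo <- var(as.numeric(o)); vg <- var(as.numeric(g))
  if (vo + vg == 0) {
    warn("Both images constant; returning the luminance-term limit.")
    if (mo == 0 && mg == 0) return(1)
    return(2 * mo * mg / (mo^2 + mg^2))
  }
  cog <- cov(as.numeric(o), as.numeric(g))
  4 * mo * mg * cog / ((mo^2 + mg^2) * (vo + vg))
}

#' Normalized mutual information of the joint intensity histogram
#'
#' Raw mutual information (natural log) of the joint histogram over `bins`
#' equal-width intensity bins on \[0, 255\], normalized by
#' `min(H(o), H(g))` so identical images score 1 and independent images
#' score ~0. Set `normalize = FALSE` for the raw value in nats.
#'
#' @inheritParams ssim
#' @param bins Number of intensity bins per axis (>= 2, default 64).
#' @param normalize Normalize by the smaller marginal entropy?
#' @return Scalar >= 0 (<= 1 when normalized).
#' @export
mutual_information <- function(o, g, bins = 64, normalize = TRUE) {
  assert_image(o, "o"); assert_image(g, "g"); assert_same_size(o, g)
  if (bins < 2) abort("`bins` must be >= 2.")
  breaks <- seq(0, 255, length.out = bins + 1)
  io <- findInterval(as.numeric(o), breaks, rightmost.closed = TRUE, all.inside = TRUE)
  ig <- findInterval(as.numeric(g), breaks, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(io, levels = seq_len(bins)),
                 factor(ig, levels = seq_len(bins))) / length(io)
  po <- rowSums(joint); pg <- colSums(joint)
  nz <- joint > 0
  mi_raw <- sum(joint[nz] * log(joint[nz] / (po[row(joint)[nz]] * pg[col(joint)[nz]])))
  if (!normalize) return(max(mi_raw, 0))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ho <- ent(po); hg <- ent(pg)
  if (min(ho, hg) == 0) {
    # constant image(s): identical constants are perfectly informative
    return(if (identical(dim(o), dim(g)) && all(io == ig)) 1 else 0)
  }
  max(mi_raw, 0) / min(ho, hg)
}

#' Mean squared error between two images
#' @inheritParams ssim
#' @return Scalar >= 0.
#' @export
mse <- function(o, g) {
  assert_image(o, "o"); assert_image(g, "g"); assert_same_size(o, g)
  mean((o - g)^2)
}

#' Peak signal-to-noise ratio
#'
#' Default (`form = "standard"`): `10 log10(max(o)^2 / MSE)` in dB, the form
#' whose magnitudes match the study's reported 12--14 dB regime. The printed
#' variant `20 log10(max(o)) - 20 log10(MSE)` is available as
#' `form = "printed"`. The maximum is taken from `o` (the reference), which
#' makes the metric asymmetric. Identical images hit the `cap` (default
#' 100 dB).
#'
#' @inheritParams ssim
#' @param form `"standard"` or `"printed"`.
#' @param cap Value returned when MSE is 0.
#' @return Scalar (dB).
#' @export
psnr <- function(o, g, form = c("standard", "printed"), cap = 100) {
  form <- match.arg(form)
  m <- mse(o, g)
  if (m == 0) return(cap)
  mx <- max(o)
  v <- switch(form,
    standard = 10 * log10(mx^2 / m),
    printed = 20 * log10(mx) - 20 * log10(m)
  )
  min(v, cap)
}

#' Blur index (predictive-residue variance)
#'
#' Residues are horizontal first differences `p(i, j) = x(i, j+1) - x(i, j)`;
#' the index is the mean squared deviation of the residues from their
#' per-image median, `1/(m (n-1)) * sum (p - median(p))^2`. Sharp, textured
#' images score high; constant and heavily blurred images score low.
#'
#' @param img Numeric matrix with >= 2 columns.
#' @return Scalar >= 0.
#' @export
blur_index <- function(img) {
  assert_image(img, "img")
  if (ncol(img) < 2) abort("Blur index needs at least 2 columns.")
  p <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  mean((p - median(p))^2)
}

#' Average a pairwise metric over the cross-product of two groups
#'
#' Computes `metric(o, g)` for every (original, candidate) pair and returns
#' the mean — the 40 x 40 protocol at arbitrary group sizes. With
#' `exclude_self = TRUE` (used for the original-vs-original reference
#' range) pairs with equal index are skipped.
#'
#' @param metric A pairwise metric function `(o, g) -> scalar` (not [fid()],
#'   which is group-level).
#' @param groupO,groupG Image tibbles or lists of matrices.
#' @param exclude_self Skip same-index pairs (for a group against itself)?
#' @return Scalar mean.
#' @export
pairwise_group_average <- function(metric, groupO, groupG, exclude_self = FALSE) {
  if (identical(metric, fid))
    abort("`fid` is a group-level metric; pass a pairwise metric.")
  O <- img_list(groupO); G <- img_list(groupG)
  if (length(O) == 0 || length(G) == 0) abort("Both groups must be non-empty.")
  vals <- c()
  for (i in seq_along(O)) for (j in seq_along(G)) {
    if (exclude_self && i == j) next
    vals <- c(vals, metric(O[[i]], G[[j]]))
  }
  mean(vals)
}

# the six per-image/pairwise metrics used for tables and combinations
pairwise_metric_funs <- function(bins = 64) {
  list(
    ssim = ssim,
    uqm = uqm,
    mi = function(o, g) mutual_information(o, g, bins = bins),
    mse = mse,
    psnr = psnr
  )
}

#' Per-image metric table
#'
#' For every image, each pairwise metric (SSIM, UQM, MI, MSE, PSNR) is
#' averaged over all original images (excluding the self-pair for
#' originals), and the blur index is computed on the image itself. This is
#' the per-image representation consumed by the concordance search.
#'
#' @param data Image tibble with `id`, `group`, `image`; the rows with
#'   `group == original` are the reference.
#' @param original Label of the reference group.
#' @param bins Intensity bins for mutual information.
#' @return Tibble: `id`, `group`, `blur`, `ssim`, `psnr`, `mse`, `mi`, `uqm`.
#' @export
metric_table <- function(data, original = "original", bins = 64) {
  stopifnot(is.data.frame(data), all(c("id", "group", "image") %in% names(data)))
  orig <- data$image[data$group == original]
  if (length(orig) == 0) abort(sprintf("No images with group '%s'.", original))
  funs <- pairwise_metric_funs(bins)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    im <- data$image[[i]]
    is_orig <- data$group[i] == original
    per_metric <- purrr::map_dbl(funs, function(f) {
      vals <- purrr::imap_dbl(orig, function(o, j) {
        if (is_orig && identical(o, im)) NA_real_ else f(o, im)
      })
      mean(vals, na.rm = TRUE)
    })
    tibble(id = data$id[i], group = data$group[i],
           blur = blur_index(im), ssim = per_metric[["ssim"]],
           psnr = per_metric[["psnr"]], mse = per_metric[["mse"]],
           mi = per_metric[["mi"]], uqm = per_metric[["uqm"]])
  })
  dplyr::bind_rows(rows)
}

#' Group-level metric report
#'
#' The aggregation protocol behind the study's metric table: for each
#' pairwise metric the reference range over all ordered original pairs
#' (self-pairs excluded) and the cross-product average per synthetic group;
#' blur as per-image min/max over originals and per-image mean per group;
#' FID group-wise against the originals, with the reference range taken
#' over strata of the originals (a `stage` column if present, otherwise an
#' odd/even split).
#'
#' @param data Image tibble with `id`, `group`, `image` (optionally `stage`
#'   on the original rows).
#' @param original Label of the reference group.
#' @param bins Intensity bins for mutual information.
#' @return A tibble of class `organoid_group_report`: `metric`, `group`,
#'   `statistic` (`"range_min"`, `"range_max"`, `"mean"`), `value`.
#' @export
group_report <- function(data, original = "original", bins = 64) {
  stopifnot(is.data.frame(data))
  groups <- setdiff(unique(data$group), original)
  if (any(is.na(data$group)) || any(!nzchar(data$group)))
    abort("Every image must carry a non-empty group tag.")
  orig <- data[data$group == original, ]
  if (nrow(orig) < 2) abort("Need >= 2 original images.")
  funs <- pairwise_metric_funs(bins)

  rows <- list()
  for (m in names(funs)) {
    pair_vals <- c()
    for (i in seq_len(nrow(orig))) for (j in seq_len(nrow(orig))) {
      if (i == j) next
      pair_vals <- c(pair_vals, funs[[m]](orig$image[[i]], orig$image[[j]]))
    }
    rows[[length(rows) + 1]] <- tibble(
      metric = m, group = original,
      statistic = c("range_min", "range_max"),
      value = range(pair_vals)
    )
    for (g in groups) {
      gv <- pairwise_group_average(funs[[m]], orig, data[data$group == g, ])
      rows[[length(rows) + 1]] <- tibble(metric = m, group = g,
                                         statistic = "mean", value = gv)
    }
  }

  # blur: per-image min/max (original) or mean (synthetic)
  bl_orig <- purrr::map_dbl(orig$image, blur_index)
  rows[[length(rows) + 1]] <- tibble(
    metric = "blur", group = original,
    statistic = c("range_min", "range_max"), value = range(bl_orig)
  )
  for (g in groups) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "blur", group = g, statistic = "mean",
      value = mean(purrr::map_dbl(data$image[data$group == g], blur_index))
    )
  }

  # fid: reference range over original strata, mean per group
  strata <- if ("stage" %in% names(orig)) split(orig$image, orig$stage)
            else split(orig$image, rep(c(1, 2), length.out = nrow(orig)))
  strata <- strata[purrr::map_int(strata, length) >= 2]
  fid_ref <- if (length(strata) >= 2) {
    combos <- utils::combn(length(strata), 2)
    apply(combos, 2, function(ij) fid(strata[[ij[1]]], strata[[ij[2]]]))
  } else NA_real_
  rows[[length(rows) + 1]] <- tibble(
    metric = "fid", group = original,
    statistic = c("range_min", "range_max"),
    value = if (all(is.na(fid_ref))) c(NA_real_, NA_real_) else range(fid_ref)
  )
  for (g in groups) {
    rows[[length(rows) + 1]] <- tibble(
      metric = "fid", group = g, statistic = "mean",
      value = fid(orig, data[data$group == g, ])
    )
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("organoid_group_report", class(out))
  out
}
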