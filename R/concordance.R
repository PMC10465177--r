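# Concordance search: can a metric combination proxy the expert decision?
# All 2^n - 1 metric subsets are reduced to a single per-image feature,
# group feature histograms are compared by KL divergence, and combination
# scores are correlated (Pearson, Kendall) with the normalized error rate
# and the mean decision time.

#' Enumerate all non-empty metric subsets
#'
#' Deterministic order: by subset size, then lexicographically. Six metrics
#' give 63 subsets.
#'
#' @param metric_names Character vector of distinct metric names (>= 1).
#' @return List of character vectors.
#' @export
#' @examples
#' length(enumerate_combinations(c("blur", "ssim", "psnr", "mse", "mi", "uqm")))
enumerate_combinations <- function(metric_names) {
  if (length(metric_names) < 1) abort("Need at least one metric name.")
  if (anyDuplicated(metric_names)) abort("Duplicate metric names.")
  nm <- metric_names
  out <- list()
  for (k in seq_along(nm)) {
    combos <- utils::combn(sort(nm), k, simplify = FALSE)
    ord <- order(purrr::map_chr(combos, paste, collapse = "\r"))
    out <- c(out, combos[ord])
  }
  out
}

#' Reduce a metric subset to one scalar per image
#'
#' Each selected metric column is standardized to zero mean and unit
#' variance over all images; a single metric returns its z-score, larger
#' subsets are reduced to the score on the first principal direction of the
#' standardized columns (sign fixed so the first metric loads positively).
#' Zero-variance metrics are dropped from the subset with a warning.
#'
#' @param metric_table Per-image metric tibble ([metric_table()] format).
#' @param subset Character vector of metric column names.
#' @return Numeric vector, one feature value per row of `metric_table`.
#' @export
combo_feature <- function(metric_table, subset) {
  stopifnot(is.data.frame(metric_table))
  missing <- setdiff(subset, names(metric_table))
  if (length(missing) > 0)
    abort(paste0("Metric(s) not in table: ", paste(missing, collapse = ", ")))
  M <- as.matrix(metric_table[, subset, drop = FALSE])
  if (!all(is.finite(M))) abort("Metric values must be finite.")
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Dropping zero-variance metric(s): ",
                paste(subset[sds == 0], collapse = ", ")))
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) == 0) abort("All metrics in subset have zero variance.")
  }
  Z <- scale(M)
  if (ncol(Z) == 1) return(as.numeric(Z))
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) score <- -score
  as.numeric(score)
}

#' Kullback--Leibler divergence between two histograms
#'
#' `sum(p * log(p / q))` in nats over a shared binning, after additive
#' smoothing (`eps` added to every bin, then renormalized) so empty bins
#' never produce infinities. Non-negative; zero only for identical
#' (smoothed) histograms; asymmetric in `(p, q)` — `p` is the subject
#' distribution, `q` the reference.
#'
#' @param p_hist,q_hist Non-negative numeric vectors of equal length
#'   (counts or probabilities over the same bins).
#' @param eps Additive smoothing constant (default 1e-6).
#' @return Scalar >= 0, in nats.
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.9, 0.1)) # ~0.5108
kl_divergence <- function(p_hist, q_hist, eps = 1e-6) {
  if (length(p_hist) != length(q_hist))
    abort("Histograms must share the same binning (equal length).")
  if (any(p_hist < 0) || any(q_hist < 0)) abort("Histogram masses must be >= 0.")
  p <- p_hist + eps; q <- q_hist + eps
  p <- p / sum(p); q <- q / sum(q)
  max(sum(p * log(p / q)), 0)
}

feature_histogram <- function(x, breaks) {
  h <- hist(x, breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts)
}

#' Per-group KL divergence of a feature against a reference group
#'
#' Histograms use 16 equal-width bins over the pooled feature range. Groups
#' with fewer than 5 images trigger a warning (their histograms are
#' unreliable at this binning).
#'
#' @param features Numeric feature vector (one value per image).
#' @param groups Group label per image.
#' @param reference_group Label of the reference group.
#' @param bins Number of equal-width bins (default 16).
#' @return Tibble: `group`, `kl` (KL(group || reference); 0 for the
#'   reference itself).
#' @export
group_kl_map <- function(features, groups, reference_group, bins = 16) {
  groups <- as.character(groups)
  if (!reference_group %in% groups) abort("Reference group not present.")
  small <- names(which(table(groups) < 5))
  if (length(small) > 0)
    warn(paste0("Group(s) with < 5 images: ", paste(small, collapse = ", ")))
  rng <- range(features)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  q <- feature_histogram(features[groups == reference_group], breaks)
  purrr::map_dfr(unique(groups), function(g) {
    p <- feature_histogram(features[groups == g], breaks)
    tibble(group = g, kl = if (g == reference_group) 0 else kl_divergence(p, q))
  })
}

#' Correlate every metric combination with the expert decision
#'
#' For each non-empty subset of `metric_names`, the per-image combination
#' feature is aggregated to group means and correlated (Pearson r and
#' Kendall tau) with the per-group normalized error rate and mean decision
#' time; with `level = "image"` the correlation is computed per image
#' against per-image values. Combinations are ranked by |Pearson r| with
#' NER, ties broken by |Kendall tau|. Constant vectors leave the
#' correlation as NA.
#'
#' @param metric_table Per-image metric tibble ([metric_table()] format,
#'   must include `group`).
#' @param rates Tibble with `group`, `ner`, `mean_time` (as from
#'   [ner_by_group()]); with `level = "image"`, per-image columns
#'   `image_id`, `ner`, `mean_time` instead.
#' @param metric_names Metrics to combine (default the six per-image ones).
#' @param level `"group"` (default) or `"image"`.
#' @return Tibble of class `combo_correlations`: `combination`, `size`,
#'   `pearson_ner`, `kendall_ner`, `pearson_time`, `kendall_time`, `rank`.
#' @export
correlate_combinations <- function(metric_table, rates,
                                   metric_names = c("blur", "ssim", "psnr",
                                                    "mse", "mi", "uqm"),
                                   level = c("group", "image")) {
  level <- match.arg(level)
  subsets <- enumerate_combinations(metric_names)
  if (level == "group") {
    if (nrow(rates) < 3)
      abort("Need >= 3 groups for group-level correlations.")
  } else if (nrow(rates) < 3) {
    abort("Need >= 3 paired observations.")
  }

  safe_cor <- function(a, b, method) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    suppressWarnings(cor(a, b, method = method))
  }

  rows <- purrr::map_dfr(subsets, function(ss) {
    feat <- combo_feature(metric_table, ss)
    if (level == "group") {
      agg <- tibble(group = metric_table$group, feat = feat) |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(feat = mean(.data$feat), .groups = "drop") |>
        dplyr::inner_join(rates, by = "group")
    } else {
      agg <- tibble(image_id = metric_table$id, feat = feat) |>
        dplyr::inner_join(rates, by = "image_id")
    }
    tibble(
      combination = paste(ss, collapse = "+"),
      size = length(ss),
      pearson_ner = safe_cor(agg$feat, agg$ner, "pearson"),
      kendall_ner = safe_cor(agg$feat, agg$ner, "kendall"),
      pearson_time = safe_cor(agg$feat, agg$mean_time, "pearson"),
      kendall_time = safe_cor(agg$feat, agg$mean_time, "kendall")
    )
  })
  ord <- order(-abs(rows$pearson_ner), -abs(rows$kendall_ner))
  rows$rank <- NA_integer_
  rows$rank[ord] <- seq_len(nrow(rows))
  out <- rows[order(rows$rank), ]
  class(out) <- c("combo_correlations", class(out))
  out
}

#' Top combinations by decision concordance
#'
#' @param results A `combo_correlations` tibble.
#' @param n How many to keep (default 10).
#' @return The `n` best-ranked rows.
#' @export
top_combinations <- function(results, n = 10) {
  head(results[order(results$rank), ], n)
}
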