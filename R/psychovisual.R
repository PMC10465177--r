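# Psychovisual analysis: confusion counts, error / positive rates,
# time-weighted rates, decision-time summaries, vote histograms, and the
# statistical test battery.

#' Label decisions into per-group confusion counts
#'
#' Original images: answer "real" is a true positive, "generated" a false
#' negative. Synthetic images: answer "real" is a false positive,
#' "generated" a true negative. Passes are handled per `pass_policy`:
#' `"exclude"` (default) tallies them separately outside the four counts, so
#' `tp + fn + pass` (originals) or `fp + tn + pass` (synthetic) equals
#' experts x group size; `"as_generated"` counts a pass as a "generated"
#' answer.
#'
#' @param records Decision tibble ([simulate_experts()] /
#'   [read_session_csvs()] format).
#' @param pass_policy `"exclude"` or `"as_generated"`.
#' @return Tibble: `group`, `tp`, `fp`, `tn`, `fn`, `pass_count`, `n`.
#' @export
label_decisions <- function(records, pass_policy = c("exclude", "as_generated")) {
  pass_policy <- match.arg(pass_policy)
  stopifnot(is.data.frame(records))
  known <- organoid_groups()
  bad <- setdiff(unique(records$group), known)
  if (length(bad) > 0)
    abort(sprintf("Unknown group(s): %s.", paste(bad, collapse = ", ")))
  r <- records
  if (pass_policy == "as_generated") {
    r$answer[r$answer == "pass"] <- "generated"
  }
  r |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      tp = sum(.data$true_label == "real" & .data$answer == "real"),
      fp = sum(.data$true_label == "generated" & .data$answer == "real"),
      tn = sum(.data$true_label == "generated" & .data$answer == "generated"),
      fn = sum(.data$true_label == "real" & .data$answer == "generated"),
      pass_count = sum(.data$answer == "pass"),
      n = dplyr::n(),
      .groups = "drop"
    )
}

rate_or_nan <- function(num, den) {
  if (den == 0) {
    warn("Zero denominator in rate; returning NaN.")
    return(NaN)
  }
  num / den
}

#' Error and positive rates from confusion counts
#'
#' For each group: the overall error rate
#' `ER = (FP + FN) / (FP + FN + TP + TN)`, the original-image error rate
#' `ER_O = FN / (FN + TP)`, the synthetic-image error rate
#' `ER_G = FP / (FP + TN)`, and the positive rate of the originals
#' `PR_O = 1 - ER_O = TP / (FN + TP)` (for synthetic groups the positive
#' rate equals `ER_G`). Rates with zero denominators are NaN with a warning.
#'
#' @param counts Confusion tibble from [label_decisions()] (or any data
#'   frame with `group`, `tp`, `fp`, `tn`, `fn`).
#' @return Tibble: `group`, `er`, `er_original`, `er_generated`,
#'   `positive_rate`.
#' @export
#' @examples
#' error_rates(data.frame(group = "WASS", tp = 0, fp = 134, tn = 186, fn = 0))
error_rates <- function(counts) {
  stopifnot(is.data.frame(counts))
  purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    ct <- counts[i, ]
    er <- rate_or_nan(ct$fp + ct$fn, ct$fp + ct$fn + ct$tp + ct$tn)
    er_o <- if (ct$fn + ct$tp > 0) ct$fn / (ct$fn + ct$tp) else NaN
    er_g <- if (ct$fp + ct$tn > 0) ct$fp / (ct$fp + ct$tn) else NaN
    # PR = 1 - ER_O for images that are truly real; PR = ER_G otherwise
    pr <- if (!is.nan(er_o)) 1 - er_o else er_g
    tibble(group = ct$group, er = er, er_original = er_o,
           er_generated = er_g, positive_rate = pr)
  })
}

#' Time-weighted (normalized) error rates
#'
#' Error counts weighted by the mean decision time of the corresponding
#' error category: overall
#' `NER = (FP t_FP + FN t_FN) / (FP + FN + TP + TN)`, originals
#' `NER_O = FN t_FN / (FN + TP)`, synthetic `NER_G = FP t_FP / (FP + TN)`.
#' With both times 1 these reduce to the plain error rates. `t_fp`/`t_fn`
#' default to the mean error-decision times found in `records` for the
#' group (per-category within-group means), or can be given directly.
#'
#' @param counts One-row confusion data frame (or tibble row) for a group.
#' @param t_fp,t_fn Mean decision times (seconds) of false-positive and
#'   false-negative decisions.
#' @return Tibble: `ner`, `ner_original`, `ner_generated`.
#' @export
#' @examples
#' normalized_error_rate(data.frame(tp = 0, fp = 134, tn = 186, fn = 0),
#'   t_fp = 2, t_fn = 1)
normalized_error_rate <- function(counts, t_fp = 1, t_fn = 1) {
  stopifnot(is.data.frame(counts), nrow(counts) == 1)
  if (t_fp < 0 || t_fn < 0) abort("Times must be >= 0.")
  ct <- counts
  total <- ct$fp + ct$fn + ct$tp + ct$tn
  tibble(
    ner = rate_or_nan(ct$fp * t_fp + ct$fn * t_fn, total),
    ner_original = if (ct$fn + ct$tp > 0) ct$fn * t_fn / (ct$fn + ct$tp) else NaN,
    ner_generated = if (ct$fp + ct$tn > 0) ct$fp * t_fp / (ct$fp + ct$tn) else NaN
  )
}

#' Per-group normalized error rates from raw records
#'
#' Convenience wrapper computing, per group, the confusion counts, the
#' within-group mean FP/FN decision times, and the resulting NER.
#'
#' @inheritParams label_decisions
#' @return Tibble: `group`, `ner`, `ner_original`, `ner_generated`,
#'   `t_fp`, `t_fn`, `mean_time`.
#' @export
ner_by_group <- function(records) {
  counts <- label_decisions(records)
  purrr::map_dfr(counts$group, function(g) {
    rg <- records[records$group == g, ]
    t_fp <- mean(rg$time_s[rg$true_label == "generated" & rg$answer == "real"])
    t_fn <- mean(rg$time_s[rg$true_label == "real" & rg$answer == "generated"])
    if (is.nan(t_fp)) t_fp <- 0
    if (is.nan(t_fn)) t_fn <- 0
    ner <- normalized_error_rate(counts[counts$group == g, ], t_fp, t_fn)
    dplyr::bind_cols(tibble(group = g), ner,
                     tibble(t_fp = t_fp, t_fn = t_fn,
                            mean_time = mean(rg$time_s)))
  })
}

#' Decision-time summary
#'
#' Mean, standard deviation and count of decision times by group, by
#' decision category (TP/FP/TN/FN/pass), or by their cross. Empty cells are
#' kept with `n = 0` and NA moments.
#'
#' @inheritParams label_decisions
#' @param by `"group"`, `"decision"`, or `"group_decision"`.
#' @return Tibble with the grouping column(s) plus `mean_time`, `sd_time`, `n`.
#' @export
decision_time_summary <- function(records, by = c("group", "decision", "group_decision")) {
  by <- match.arg(by)
  r <- records |>
    dplyr::mutate(decision = dplyr::case_when(
      .data$answer == "pass" ~ "pass",
      .data$true_label == "real" & .data$answer == "real" ~ "TP",
      .data$true_label == "real" ~ "FN",
      .data$answer == "real" ~ "FP",
      TRUE ~ "TN"
    ))
  keys <- switch(by, group = "group", decision = "decision",
                 group_decision = c("group", "decision"))
  r |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_time = mean(.data$time_s),
      sd_time = sd(.data$time_s),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Vote histogram and per-expert positive-answer counts
#'
#' Counts how many images received k "real" answers, k = 0..number of
#' experts, and how many positive ("real") answers each expert gave. The
#' record set must be complete: one record per (expert, image).
#'
#' @inheritParams label_decisions
#' @return List with `histogram` (tibble `k`, `n_images`) and `per_expert`
#'   (tibble `expert_id`, `n_positive`).
#' @export
votes_histogram <- function(records) {
  experts <- unique(records$expert_id)
  images <- unique(records$image_id)
  tallied <- records |>
    dplyr::count(.data$expert_id, .data$image_id)
  missing <- nrow(tidyr::expand_grid(expert_id = experts, image_id = images)) -
    nrow(tallied)
  if (missing > 0 || any(tallied$n != 1)) {
    have <- paste0(tallied$expert_id, "\r", tallied$image_id)
    want <- as.character(outer(experts, images, paste, sep = "\r"))
    gone <- setdiff(want, have)
    abort(paste0("Missing expert-image cells: ",
                 paste(head(gsub("\r", " / ", gone), 5), collapse = "; "),
                 if (length(gone) > 5) " ..."))
  }
  per_image <- records |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(k = sum(.data$answer == "real"), .groups = "drop")
  hist <- per_image |>
    dplyr::count(.data$k, name = "n_images") |>
    tidyr::complete(k = 0:length(experts), fill = list(n_images = 0L))
  per_expert <- records |>
    dplyr::group_by(.data$expert_id) |>
    dplyr::summarise(n_positive = sum(.data$answer == "real"), .groups = "drop")
  list(histogram = hist, per_expert = per_expert)
}

#' Per-image expert-vote counts
#'
#' Number of "real" answers each image received — the vote counts used to
#' threshold synthetic images for segmentation training sets.
#'
#' @inheritParams label_decisions
#' @return Tibble: `image_id`, `group`, `votes`.
#' @export
image_votes <- function(records) {
  records |>
    dplyr::group_by(.data$image_id, .data$group) |>
    dplyr::summarise(votes = sum(.data$answer == "real"), .groups = "drop")
}

#' Statistical test battery over groups
#'
#' Routes per the classical decision tree at alpha = 0.05: per-group
#' Shapiro normality, then Bartlett (if all groups normal) or Levene
#' homoscedasticity, then one-way ANOVA with a Tukey HSD post hoc in the
#' parametric branch or Kruskal--Wallis with Holm-adjusted pairwise
#' Wilcoxon tests otherwise. Groups with fewer than 3 observations are
#' excluded with a warning. Every routing decision is logged in the result.
#'
#' @param values Numeric response vector.
#' @param factors Grouping factor (same length).
#' @param alpha Significance level (default 0.05).
#' @return A `psy_stats_report`: list with `route` (character log),
#'   `normality`, `homoscedasticity`, `omnibus`, `posthoc` tibbles/objects
#'   and `alpha`.
#' @export
stats_report <- function(values, factors, alpha = 0.05) {
  f <- factor(factors)
  keep_lv <- names(which(table(f) >= 3))
  dropped <- setdiff(levels(f), keep_lv)
  if (length(dropped) > 0)
    warn(paste0("Excluding group(s) with n < 3: ", paste(dropped, collapse = ", ")))
  keep <- f %in% keep_lv
  x <- values[keep]; f <- droplevels(f[keep])
  if (nlevels(f) < 2) abort("Need at least 2 groups with n >= 3.")
  route <- character()

  sh <- purrr::map_dfr(levels(f), function(lv) {
    v <- x[f == lv]
    p <- if (length(unique(v)) < 3) 0 else shapiro.test(v)$p.value
    tibble(group = lv, shapiro_p = p)
  })
  normal <- all(sh$shapiro_p > alpha)
  route <- c(route, sprintf("normality: %s (min Shapiro p = %.4g)",
                            if (normal) "normal" else "non-normal",
                            min(sh$shapiro_p)))

  if (normal) {
    hv <- bartlett.test(x, f)
    route <- c(route, sprintf("homoscedasticity: Bartlett p = %.4g", hv$p.value))
  } else {
    hv <- car::leveneTest(x ~ f)
    route <- c(route, sprintf("homoscedasticity: Levene p = %.4g", hv$`Pr(>F)`[1]))
  }
  homosced <- if (normal) hv$p.value > alpha else hv$`Pr(>F)`[1] > alpha

  if (normal && homosced) {
    fit <- aov(x ~ f)
    omni_p <- summary(fit)[[1]]$`Pr(>F)`[1]
    post <- as.data.frame(TukeyHSD(fit)$f)
    post <- tibble(comparison = rownames(post), diff = post$diff,
                   p_adj = post$`p adj`)
    route <- c(route, sprintf("branch: parametric (ANOVA p = %.4g, Tukey post hoc)", omni_p))
  } else {
    kw <- kruskal.test(x, f)
    omni_p <- kw$p.value
    pw <- pairwise.wilcox.test(x, f, p.adjust.method = "holm", exact = FALSE)
    pm <- pw$p.value
    post <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
      purrr::map_dfr(seq_len(ncol(pm)), function(j) {
        if (is.na(pm[i, j])) return(NULL)
        tibble(comparison = paste(rownames(pm)[i], colnames(pm)[j], sep = "-"),
               diff = NA_real_, p_adj = pm[i, j])
      })
    })
    route <- c(route,
               sprintf("branch: nonparametric (Kruskal-Wallis p = %.4g, Holm pairwise)", omni_p))
  }

  structure(
    list(route = route, normality = sh, homoscedasticity = hv,
         omnibus_p = omni_p, posthoc = post, alpha = alpha,
         branch = if (normal && homosced) "parametric" else "nonparametric"),
    class = "psy_stats_report"
  )
}

#' @export
print.psy_stats_report <- function(x, ...) {
  cat("<psy_stats_report>\n")
  for (r in x$route) cat("  ", r, "\n", sep = "")
  cat(sprintf("  omnibus p = %.4g (alpha = %g)\n", x$omnibus_p, x$alpha))
  invisible(x)
}

#' Tidy the post-hoc table of a stats report
#'
#' @param x A `psy_stats_report`.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with adjusted p values.
#' @export
tidy.psy_stats_report <- function(x, ...) x$posthoc

#' One-row summary of a stats report
#'
#' @inheritParams tidy.psy_stats_report
#' @return One-row tibble: branch, omnibus p, number of significant
#'   pairwise comparisons at alpha.
#' @export
glance.psy_stats_report <- function(x, ...) {
  tibble(
    branch = x$branch, omnibus_p = x$omnibus_p,
    n_significant_pairs = sum(x$posthoc$p_adj < x$alpha, na.rm = TRUE),
    alpha = x$alpha
  )
}
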