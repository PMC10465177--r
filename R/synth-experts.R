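#' Behavioural profile of a simulated expert
#'
#' Encodes how an evaluator decides whether an image is a natural
#' acquisition: per-loss-group probabilities of calling a synthetic image
#' "real" (false positive), the probability of calling an original image
#' "generated" (false negative), a pass probability, and a lognormal
#' decision-time model per decision category. Error times default to longer
#' medians than correct times, emulating the longer hesitation observed on
#' wrong answers.
#'
#' @param expert_id Identifier string.
#' @param fp_prob_by_group Named numeric vector / list: loss group ->
#'   probability of a false positive, each in \[0, 1\].
#' @param fn_prob Probability of a false negative on original images.
#' @param pass_prob Probability of passing (no decision) on any image.
#' @param time_model Named list of `c(meanlog, sdlog)` per category
#'   `"correct"`, `"error"`, `"pass"` (seconds).
#' @return An `expert_profile` object.
#' @export
#' @examples
#' expert_profile("E1", fp_prob_by_group = c(WASS = 0.42, P_WASS = 0.62))
expert_profile <- function(expert_id,
                           fp_prob_by_group,
                           fn_prob = 0.07,
                           pass_prob = 0,
                           time_model = list(
                             correct = c(meanlog = log(2.0), sdlog = 0.5),
                             error = c(meanlog = log(3.5), sdlog = 0.6),
                             pass = c(meanlog = log(1.5), sdlog = 0.5)
                           )) {
  fp <- unlist(fp_prob_by_group)
  probs <- c(fp, fn_prob, pass_prob)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (is.null(names(fp)) || any(!nzchar(names(fp))))
    abort("`fp_prob_by_group` must be named by loss group.")
  structure(
    list(expert_id = as.character(expert_id), fp_prob_by_group = fp,
         fn_prob = fn_prob, pass_prob = pass_prob, time_model = time_model),
    class = "expert_profile"
  )
}

#' Default panel of simulated experts
#'
#' Eight profiles whose per-group false-positive probabilities follow the
#' ordering reported for the study losses: evaluators are misled most by the
#' perceptual-Wasserstein and Wasserstein groups (around 60% and 40%) and
#' far less by the blurrier BCE-family groups, with a small false-negative
#' rate on originals. Individual experts vary around these centres, including
#' a few conservative raters, mirroring the observed spread of per-expert
#' positive-answer counts.
#'
#' @param n_experts Number of profiles (default 8).
#' @param seed Seed controlling the between-expert variation.
#' @return List of [expert_profile()] objects.
#' @export
default_expert_panel <- function(n_experts = 8, seed = 2024L) {
  base_fp <- c(BCE = 0.25, BCE_L1 = 0.24, LS = 0.12, POISSON = 0.23,
               WASS = 0.42, P_WASS = 0.62)
  seeds <- derive_seeds(seed, n_experts)
  purrr::map(seq_len(n_experts), function(i) {
    with_seed(seeds[i], {
      jitter <- runif(length(base_fp), 0.7, 1.3)
      fp <- pmin(pmax(base_fp * jitter, 0.01), 0.95)
      expert_profile(
        expert_id = sprintf("expert_%02d", i),
        fp_prob_by_group = fp,
        fn_prob = min(0.3, max(0.01, rlnorm(1, log(0.07), 0.4))),
        pass_prob = 0
      )
    })
  })
}

#' Simulate expert decisions over a labeled image set
#'
#' Emits one decision record per (expert, image). For original images the
#' expert errs (answers "generated") with probability `fn_prob`; for a
#' synthetic image of group g they err (answer "real") with probability
#' `fp_prob_by_group[g]`. Passes are drawn first with `pass_prob` and kept
#' as an explicit third answer. Decision times are lognormal draws from the
#' profile's category model. Deterministic under `seed`.
#'
#' @param images A tibble with at least `id` and `group` columns (as from
#'   [make_dataset()]); `group` `"original"` means a real acquisition.
#' @param profiles List of [expert_profile()] objects (>= 1).
#' @param seed Master seed.
#' @return A tibble of decision records with columns `expert_id`, `image_id`,
#'   `group`, `true_label` (`"real"`/`"generated"`), `answer`
#'   (`"real"`/`"generated"`/`"pass"`), `time_s`.
#' @export
simulate_experts <- function(images, profiles, seed = 1L) {
  stopifnot(is.data.frame(images), all(c("id", "group") %in% names(images)))
  if (length(profiles) < 1) abort("Need at least one expert profile.")
  if (inherits(profiles, "expert_profile")) profiles <- list(profiles)
  syn_groups <- setdiff(unique(images$group), "original")
  for (p in profiles) {
    missing <- setdiff(syn_groups, names(p$fp_prob_by_group))
    if (length(missing) > 0)
      abort(sprintf("Profile '%s' lacks fp probabilities for group(s): %s.",
                    p$expert_id, paste(missing, collapse = ", ")))
  }
  seeds <- derive_seeds(seed, length(profiles))
  recs <- purrr::map2(profiles, seeds, function(p, s) {
    with_seed(s, {
      n <- nrow(images)
      is_orig <- images$group == "original"
      pass <- runif(n) < p$pass_prob
      err_p <- ifelse(is_orig, p$fn_prob,
                      unname(p$fp_prob_by_group[images$group]))
      err <- runif(n) < err_p
      true_label <- ifelse(is_orig, "real", "generated")
      # an error flips the true label; fp = "real" on synthetic, fn = "generated" on original
      answer <- ifelse(pass, "pass",
                       ifelse(err,
                              ifelse(is_orig, "generated", "real"),
                              true_label))
      cat_ <- ifelse(pass, "pass", ifelse(err, "error", "correct"))
      tm <- vapply(cat_, function(k) {
        m <- p$time_model[[k]]
        rlnorm(1, m[["meanlog"]], m[["sdlog"]])
      }, numeric(1))
      tibble(
        expert_id = p$expert_id, image_id = images$id, group = images$group,
        true_label = true_label, answer = answer, time_s = unname(tm)
      )
    })
  })
  dplyr::bind_rows(recs)
}
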