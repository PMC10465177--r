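test_that("decision labeling follows the TP/FN vs FP/TN convention", {
  recs <- dplyr::bind_rows(
    records_from_counts("original", tp = 6, fn = 2),
    records_from_counts("WASS", fp = 3, tn = 5)
  )
  counts <- label_decisions(recs)
  orig <- counts[counts$group == "original", ]
  expect_equal(c(orig$tp, orig$fn, orig$fp, orig$tn), c(6, 2, 0, 0))
  wass <- counts[counts$group == "WASS", ]
  expect_equal(c(wass$fp, wass$tn, wass$tp, wass$fn), c(3, 5, 0, 0))
  expect_error(label_decisions(dplyr::mutate(recs, group = "mystery")),
               "Unknown group")
})

test_that("the study's Wasserstein confusion row yields a 42% FP rate", {
  # fixture realizing the printed counts FP = 134, TN = 186 (320 decisions)
  recs <- records_from_counts("WASS", fp = 134, tn = 186)
  counts <- label_decisions(recs)
  expect_equal(counts$fp, 134)
  expect_equal(counts$tn, 186)
  rates <- error_rates(counts)
  expect_equal(rates$er_generated, 0.41875)
  expect_equal(as_percent(rates$er_generated), 42)
})

test_that("positive rate of originals complements the error rate exactly", {
  recs <- records_from_counts("original", tp = 297, fn = 23)
  rates <- error_rates(label_decisions(recs))
  expect_equal(rates$positive_rate, 297 / 320)
  expect_equal(rates$positive_rate, 0.928125)
  expect_equal(rates$er_original + rates$positive_rate, 1)
})

test_that("zero denominators give NaN with a warning", {
  ct <- data.frame(group = "WASS", tp = 0, fp = 0, tn = 0, fn = 0)
  expect_warning(r <- error_rates(ct), "Zero denominator")
  expect_true(is.nan(r$er))
})

test_that("normalized error rates weight errors by category times", {
  ct <- data.frame(tp = 0, fp = 134, tn = 186, fn = 0)
  # unit times reduce NER to ER
  expect_equal(normalized_error_rate(ct, 1, 1)$ner_generated, 0.41875)
  # hand value at t_fp = 2
  expect_equal(normalized_error_rate(ct, 2, 1)$ner_generated, 134 * 2 / 320)
  # no errors -> 0 regardless of times
  clean <- data.frame(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(normalized_error_rate(clean, 99, 99)$ner, 0)
})

test_that("slower simulated error times surface in the summaries", {
  imgs <- labeled_image_set(groups = c("original", "WASS"), per_group = 40)
  profs <- lapply(1:6, function(i) expert_profile(
    sprintf("e%d", i), fp_prob_by_group = c(WASS = 0.5), fn_prob = 0.1,
    time_model = list(correct = c(meanlog = log(1.5), sdlog = 0.3),
                      error = c(meanlog = log(4), sdlog = 0.3),
                      pass = c(meanlog = log(1), sdlog = 0.1))))
  recs <- simulate_experts(imgs, profs, seed = 17)
  by_dec <- decision_time_summary(recs, by = "decision")
  err_mean <- weighted.mean(by_dec$mean_time[by_dec$decision %in% c("FP", "FN")],
                            by_dec$n[by_dec$decision %in% c("FP", "FN")])
  ok_mean <- weighted.mean(by_dec$mean_time[by_dec$decision %in% c("TP", "TN")],
                           by_dec$n[by_dec$decision %in% c("TP", "TN")])
  expect_gt(err_mean, ok_mean)
  by_group <- decision_time_summary(recs, by = "group")
  expect_equal(nrow(by_group), 2)
  # the per-group NER wrapper uses within-group error-category times
  ner <- ner_by_group(recs)
  expect_true(all(c("ner_generated", "t_fp", "mean_time") %in% names(ner)))
  expect_gt(ner$t_fp[ner$group == "WASS"], 0)
})

test_that("constant decision times summarize to mean 1, sd 0", {
  recs <- records_from_counts("original", tp = 8, time_s = 1)
  s <- decision_time_summary(recs, by = "group")
  expect_equal(s$mean_time, 1)
  expect_equal(s$sd_time, 0)
})

test_that("vote histograms conserve image counts and track binomial voting", {
  imgs <- labeled_image_set(groups = "WASS", per_group = 60)
  profs <- lapply(1:8, function(i) expert_profile(
    sprintf("e%d", i), fp_prob_by_group = c(WASS = 0.5), fn_prob = 0))
  recs <- simulate_experts(imgs, profs, seed = 23)
  v <- votes_histogram(recs)
  expect_equal(sum(v$histogram$n_images), 60)
  expect_equal(sum(v$per_expert$n_positive),
               sum(recs$answer == "real"))
  # mean votes per image should sit near 8 x 0.5 within binomial noise
  mean_k <- sum(v$histogram$k * v$histogram$n_images) / 60
  se <- sqrt(8 * 0.5 * 0.5 / 60)
  expect_lt(abs(mean_k - 4), 4 * se)

  # unanimous experts put every image in the top bin
  all_real <- dplyr::mutate(recs, answer = "real")
  v2 <- votes_histogram(all_real)
  expect_equal(v2$histogram$n_images[v2$histogram$k == 8], 60)

  expect_error(votes_histogram(recs[-1, ]), "Missing expert-image cells")
})

test_that("image_votes counts positive answers per image", {
  recs <- dplyr::bind_rows(
    tibble::tibble(expert_id = c("a", "b"), image_id = "i1", group = "WASS",
                   true_label = "generated", answer = c("real", "real"), time_s = 1),
    tibble::tibble(expert_id = c("a", "b"), image_id = "i2", group = "WASS",
                   true_label = "generated", answer = c("real", "generated"), time_s = 1)
  )
  v <- image_votes(recs)
  expect_equal(v$votes[v$image_id == "i1"], 2)
  expect_equal(v$votes[v$image_id == "i2"], 1)
})

test_that("the test battery routes between parametric and nonparametric", {
  set.seed(41)
  # identical groups: no omnibus significance
  x <- rep(rnorm(30), 2)
  f <- rep(c("a", "b"), each = 30)
  r0 <- stats_report(x, f)
  expect_gt(r0$omnibus_p, 0.9)
  expect_equal(sum(tidy(r0)$p_adj < 0.05, na.rm = TRUE), 0)

  # well-separated normal samples: parametric branch, p < 0.05
  x1 <- c(rnorm(30), rnorm(30, mean = 5))
  r1 <- stats_report(x1, f)
  expect_equal(r1$branch, "parametric")
  expect_lt(r1$omnibus_p, 0.05)
  expect_true(any(grepl("ANOVA", r1$route)))

  # heavy-tailed data fails Shapiro: nonparametric branch, logged
  x2 <- c(rcauchy(30), rcauchy(30, location = 3))
  r2 <- stats_report(x2, f)
  expect_equal(r2$branch, "nonparametric")
  expect_true(any(grepl("Kruskal", r2$route)))
  expect_equal(glance(r2)$branch, "nonparametric")
})

test_that("groups below n = 3 are excluded with a warning", {
  x <- c(rnorm(10), rnorm(10, 2), 1, 2)
  f <- c(rep("a", 10), rep("b", 10), "c", "c")
  expect_warning(r <- stats_report(x, f), "n < 3")
  expect_equal(nrow(r$normality), 2)
})
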