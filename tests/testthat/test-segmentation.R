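test_that("segmentation scores equal brute-force pixel confusion counting", {
  set.seed(19)
  for (rep in 1:5) {
    gt <- matrix(rbinom(100, 1, 0.4), 10)
    u <- matrix(rbinom(100, 1, 0.4), 10)
    sc <- suppressWarnings(seg_scores(gt, u))
    ct <- brute_confusion(gt, u)
    expect_equal(sc$tp, ct[["tp"]]); expect_equal(sc$fp, ct[["fp"]])
    expect_equal(sc$tn, ct[["tn"]]); expect_equal(sc$fn, ct[["fn"]])
    expect_equal(sc$dice, 2 * ct[["tp"]] / (2 * ct[["tp"]] + ct[["fp"]] + ct[["fn"]]))
    # dice = f1 from the same confusion counts (algebraic identity)
    if (!is.nan(sc$f1)) expect_equal(sc$dice, sc$f1, tolerance = 1e-12)
  }
})

test_that("hand-computed confusion example gives the expected six scores", {
  gt <- matrix(0, 10, 10); gt[1, 1:4] <- 1           # 4 positives
  u <- matrix(0, 10, 10); u[1, 1:2] <- 1             # TP=2, FN=2, FP=0, TN=96
  sc <- seg_scores(gt, u)
  # dice = 2TP / (2TP + FP + FN) = 4/6; identical to F1 by construction
  expect_equal(sc$dice, 2 / 3)
  expect_equal(sc$accuracy, 0.98)
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$specificity, 1.0)
  expect_equal(sc$precision, 1.0)
  expect_equal(sc$f1, 2 * (1 * 0.5) / (1 + 0.5), tolerance = 1e-12)
})

test_that("identity and disjoint masks hit the score extremes", {
  m <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3)
  sc <- seg_scores(m, m)
  expect_true(all(unlist(sc[c("dice", "accuracy", "sensitivity",
                              "specificity", "precision", "f1")]) == 1))
  disj <- matrix(c(0, 0, 1, 1, 0, 0, 0, 0, 0), 3)
  sc2 <- seg_scores(m, disj)
  expect_equal(sc2$dice, 0)
  expect_equal(sc2$sensitivity, 0)
  expect_error(seg_scores(m, matrix(0, 2, 2)), "same shape")
  expect_error(seg_scores(m, m * 2), "0/1")
})

test_that("classical augmentations are exact where they must be", {
  ds <- easy_organoid_dataset(1, seed = 30)
  img <- ds$image[[1]]; msk <- ds$mask[[1]]
  f1 <- classical_augment(img, msk, "flip")
  f2 <- classical_augment(f1$image, f1$mask, "flip")
  expect_identical(f2$image, img)
  expect_identical(f2$mask, msk)
  r <- list(image = img, mask = msk)
  for (i in 1:4) r <- classical_augment(r$image, r$mask, "rotate")
  expect_identical(r$image, img)
  expect_identical(r$mask, msk)
  # area preserved exactly under flip / quarter-turns
  expect_equal(sum(classical_augment(img, msk, "flip")$mask), sum(msk))
  expect_equal(sum(classical_augment(img, msk, "rotate")$mask), sum(msk))
  # whitening touches only the image
  w <- classical_augment(img, msk, "whiten")
  expect_identical(w$mask, msk)
  expect_true(all(w$image >= 0 & w$image <= 255))
  # crops are seeded and keep geometry
  c1 <- classical_augment(img, msk, "crop", seed = 4)
  c2 <- classical_augment(img, msk, "crop", seed = 4)
  expect_identical(c1$image, c2$image)
  expect_equal(dim(c1$image), dim(img))
  expect_error(classical_augment(img, msk, "sharpen"), "Unknown op")
})

test_that("vote-thresholded training sets have the documented composition", {
  orig <- easy_organoid_dataset(40, seed = 31)
  syn <- easy_organoid_dataset(40, seed = 32) |>
    dplyr::mutate(group = "P_WASS", id = paste0("syn_", id),
                  votes = c(rep(8, 14), rep(6, 6), rep(4, 10), rep(2, 6), rep(0, 4)))
  cls <- classical_pool(orig, 40, seed = 33)
  # 14 images at votes >= 8 -> 14 synthetic + 26 classical + 40 original
  ts <- suppressMessages(build_training_set(orig, syn, cls, k = 8))
  comp <- attr(ts, "composition")
  expect_equal(unname(comp), c(40, 14, 26))
  expect_equal(nrow(ts), 80)
  # a threshold above any vote count gives the pure classical baseline
  ts0 <- suppressMessages(build_training_set(orig, syn, cls, k = 9))
  expect_equal(unname(attr(ts0, "composition")), c(40, 0, 40))
  # conservation across the k sweep
  for (k in c(0, 2, 4, 6, 8)) {
    tsk <- suppressMessages(build_training_set(orig, syn, cls, k = k))
    expect_equal(nrow(tsk), 80)
  }
  # exact-k mode admits only the matching stratum
  tse <- suppressMessages(build_training_set(orig, syn, cls, k = 6, mode = "exact"))
  expect_equal(unname(attr(tse, "composition"))[2], 6)
  expect_error(suppressMessages(
    build_training_set(orig, syn, cls[1:5, ], k = 9)), "too small")
})

test_that("overlays paint FP pink and FN green, recoverably", {
  ds <- easy_organoid_dataset(1, seed = 35)
  img <- ds$image[[1]]; gt <- ds$mask[[1]]
  ov_same <- overlay(gt, gt, img)
  # identical masks: every pixel stays gray (R = G = B)
  expect_true(all(ov_same[, , 1] == ov_same[, , 2]))
  expect_true(all(ov_same[, , 2] == ov_same[, , 3]))

  all1 <- matrix(1L, nrow(gt), ncol(gt)); all0 <- matrix(0L, nrow(gt), ncol(gt))
  ov_pink <- overlay(all0, all1, img)
  expect_true(all(abs(ov_pink[, , 1] - 255 / 255) < 1e-9))
  expect_true(all(abs(ov_pink[, , 2] - 182 / 255) < 1e-9))

  u <- gt; u[1:5, 1:5] <- 1L   # add false positives in a background corner
  sc <- suppressWarnings(seg_scores(gt, u))
  ov <- overlay(gt, u, img)
  pink <- ov[, , 1] == 1 & abs(ov[, , 2] - 182 / 255) < 1e-9
  expect_equal(sum(pink), sc$fp)
})

test_that("leave-one-out runs one leak-free session per original", {
  ds <- easy_organoid_dataset(6, seed = 36)
  res <- leave_one_out(ds)    # oracle segmenter by default
  expect_equal(res$n_sessions, 6)
  expect_equal(res$means$dice, 1.0)
  expect_equal(nrow(res$per_image), 6)
  # a leaking set builder aborts
  expect_error(
    leave_one_out(ds, set_builder = function(id) ds),
    "Leakage"
  )
})

test_that("the default segmenter learns easy high-contrast fixtures", {
  ds <- easy_organoid_dataset(20, seed = 42)
  seg <- default_segmenter(image_size = 32, epochs = 600, seed = 7)
  pred <- seg(ds$image[1:16], ds$mask[1:16])
  dice <- vapply(17:20, function(i) {
    seg_scores(ds$mask[[i]], pred(ds$image[[i]]))$dice
  }, numeric(1))
  expect_gt(mean(dice), 0.8)

  # an essentially untrained predictor performs far worse
  seg0 <- default_segmenter(image_size = 32, epochs = 1, seed = 7)
  pred0 <- seg0(ds$image[1:16], ds$mask[1:16])
  dice0 <- vapply(17:20, function(i) {
    suppressWarnings(seg_scores(ds$mask[[i]], pred0(ds$image[[i]]))$dice)
  }, numeric(1))
  expect_lt(mean(dice0, na.rm = TRUE), mean(dice))

  # determinism under a fixed seed
  pred_b <- default_segmenter(image_size = 32, epochs = 50, seed = 7)(
    ds$image[1:4], ds$mask[1:4])
  pred_c <- default_segmenter(image_size = 32, epochs = 50, seed = 7)(
    ds$image[1:4], ds$mask[1:4])
  expect_identical(pred_b(ds$image[[5]]), pred_c(ds$image[[5]]))
})

test_that("training-mask label noise does not help held-out dice", {
  ds <- easy_organoid_dataset(12, seed = 44)
  train_idx <- 1:10; test_idx <- 11:12
  run <- function(noise_frac) {
    masks <- lapply(ds$mask[train_idx], function(m) {
      organoidval:::with_seed(100 + round(noise_frac * 1000), {
        flip <- matrix(runif(length(m)) < noise_frac, nrow(m))
        out <- m; out[flip] <- 1L - out[flip]; out
      })
    })
    pred <- default_segmenter(image_size = 32, epochs = 250, seed = 5)(
      ds$image[train_idx], masks)
    mean(vapply(test_idx, function(i) {
      suppressWarnings(seg_scores(ds$mask[[i]], pred(ds$image[[i]]))$dice)
    }, numeric(1)))
  }
  expect_gte(run(0) + 0.02, run(0.35))   # small slack for optimizer noise
})
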