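# Independent oracles: every pairwise metric is re-evaluated in test code
# directly from its formula on small images.

oracle_ssim <- function(o, g) {
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mo <- mean(o); mg <- mean(g)
  vo <- var(as.numeric(o)); vg <- var(as.numeric(g))
  cog <- cov(as.numeric(o), as.numeric(g))
  ((2 * mo * mg + c1) * (2 * cog + c2)) / ((mo^2 + mg^2 + c1) * (vo + vg + c2))
}

oracle_uqm <- function(o, g) {
  mo <- mean(o); mg <- mean(g)
  4 * mo * mg * cov(as.numeric(o), as.numeric(g)) /
    ((mo^2 + mg^2) * (var(as.numeric(o)) + var(as.numeric(g))))
}

test_that("identity axioms hold for every metric", {
  img <- textured_fixture(24)
  expect_equal(ssim(img, img), 1, tolerance = 1e-12)
  expect_equal(uqm(img, img), 1, tolerance = 1e-12)
  expect_equal(mutual_information(img, img), 1, tolerance = 1e-12)
  expect_equal(mse(img, img), 0)
  expect_equal(psnr(img, img), 100)             # documented cap
  expect_equal(blur_index(matrix(42, 5, 5)), 0)
  ds <- easy_organoid_dataset(3, seed = 2)
  expect_lt(fid(ds, ds), 1e-6)
})

test_that("constant-image edge cases return their documented limits", {
  a <- matrix(100, 4, 4)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_warning(v <- uqm(a, a), "constant")
  expect_equal(v, 1)                            # luminance-term limit at mu_o = mu_g
  expect_equal(mutual_information(a, a), 1)
})

test_that("small-image values equal direct evaluation of the formulas", {
  o2 <- matrix(c(0, 0, 255, 255), 2)            # columns [0,0] and [255,255]
  g2 <- o2[, 2:1]                               # rows reversed per row
  expect_equal(ssim(o2, g2), oracle_ssim(o2, g2), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:5) {
    o <- matrix(runif(16, 0, 255), 4); g <- matrix(runif(16, 0, 255), 4)
    expect_equal(ssim(o, g), oracle_ssim(o, g), tolerance = 1e-12)
    expect_equal(uqm(o, g), oracle_uqm(o, g), tolerance = 1e-12)
    expect_equal(mse(o, g), mean((o - g)^2), tolerance = 1e-12)
    expect_equal(psnr(o, g), 10 * log10(max(o)^2 / mean((o - g)^2)),
                 tolerance = 1e-12)
    p <- o[, -1] - o[, -ncol(o)]
    expect_equal(blur_index(o), mean((p - median(p))^2), tolerance = 1e-12)
  }

  o3 <- matrix(c(10, 50, 90, 130, 170, 210, 250, 30, 70), 3)
  g3 <- matrix(c(15, 45, 95, 125, 175, 205, 245, 35, 65), 3)
  expect_equal(uqm(o3, g3), oracle_uqm(o3, g3), tolerance = 1e-12)
})

test_that("independent white-noise images score near zero on UQM and MI", {
  set.seed(12)
  o <- matrix(runif(250 * 250, 0, 255), 250)
  g <- matrix(runif(250 * 250, 0, 255), 250)
  expect_lt(abs(uqm(o, g)), 0.1)
  expect_lt(mutual_information(o, g), 0.05)
})

test_that("a diagonal two-level joint distribution gives normalized MI of 1", {
  o <- matrix(rep(c(0, 255), each = 8), 4)      # half dark, half bright
  expect_equal(mutual_information(o, o, bins = 2), 1, tolerance = 1e-12)
  # raw MI for P = [[.5,0],[0,.5]] is ln 2
  expect_equal(mutual_information(o, o, bins = 2, normalize = FALSE), log(2),
               tolerance = 1e-12)
})

test_that("MSE and PSNR arithmetic matches hand calculations", {
  o <- matrix(100, 3, 3); g <- matrix(110, 3, 3)
  expect_equal(mse(o, g), 100)
  # a 255-peak image at MSE 3000 sits in the ~13 dB regime
  expect_equal(10 * log10(255^2 / 3000), 13.36, tolerance = 1e-3)
  o2 <- matrix(c(255, 0, 0, 0), 2)
  g2 <- o2 + sqrt(3000) * c(1, -1, 1, -1)
  expect_equal(psnr(o2, g2), 10 * log10(255^2 / mse(o2, g2)), tolerance = 1e-12)
})

test_that("blur index on a 1x3 spike equals its hand value", {
  img <- matrix(c(0, 255, 0), 1)
  # residues (255, -255), median 0 -> mean of squares = 255^2
  expect_equal(blur_index(img), 255^2)
  expect_error(blur_index(matrix(1, 3, 1)), "2 columns")
})

test_that("psnr is asymmetric in its reference and documented as such", {
  o <- matrix(c(200, 100, 50, 25), 2)
  g <- matrix(c(100, 90, 40, 20), 2)
  expect_false(isTRUE(all.equal(psnr(o, g), psnr(g, o))))
  expect_equal(mse(o, g), mse(g, o))
})

test_that("FID matches the 1-D closed form and is symmetric", {
  # feature recipe injected: identity on 1x1 "images"
  gA <- lapply(c(-1, 0, 1), function(v) matrix(v, 1, 1))        # mean 0, var 1
  gB <- lapply(c(0, 1, 2), function(v) matrix(v, 1, 1))         # mean 1, var 1
  f1 <- function(im) im[1, 1]
  expect_equal(fid(gA, gB, feature_fun = f1), 1, tolerance = 1e-9)
  ds1 <- easy_organoid_dataset(4, seed = 5)
  ds2 <- easy_organoid_dataset(4, seed = 6)
  expect_equal(fid(ds1, ds2), fid(ds2, ds1), tolerance = 1e-9)
  expect_error(fid(gA[1], gB), ">= 2")
})

test_that("pairwise group averages equal a brute-force double loop", {
  set.seed(8)
  O <- lapply(1:2, function(i) matrix(runif(16, 0, 255), 4))
  G <- lapply(1:3, function(i) matrix(runif(16, 0, 255), 4))
  got <- pairwise_group_average(mse, O, G)
  brute <- mean(sapply(O, function(o) sapply(G, function(g) mse(o, g))))
  expect_equal(got, brute, tolerance = 1e-12)
  # single-image groups: the single pair value
  expect_equal(pairwise_group_average(mse, O[1], G[1]), mse(O[[1]], G[[1]]))
  # self-comparison with self-pairs excluded is positive for distinct images
  expect_gt(pairwise_group_average(mse, O, O, exclude_self = TRUE), 0)
  expect_error(pairwise_group_average(fid, O, G), "group-level")
})

test_that("the group report has the full 7-metric shape and sane ranges", {
  orig <- easy_organoid_dataset(4, seed = 9)
  synA <- easy_organoid_dataset(3, seed = 10) |> dplyr::mutate(group = "WASS")
  synB <- easy_organoid_dataset(3, seed = 11) |> dplyr::mutate(group = "P_WASS")
  rep_tbl <- suppressMessages(group_report(dplyr::bind_rows(orig, synA, synB)))
  expect_setequal(unique(rep_tbl$metric),
                  c("ssim", "uqm", "mi", "mse", "psnr", "blur", "fid"))
  # 7 metrics x (2 range rows + 2 group means)
  expect_equal(nrow(rep_tbl), 7 * 4)
  wide <- tidyr::pivot_wider(rep_tbl[rep_tbl$group == "original", ],
                             names_from = "statistic", values_from = "value")
  expect_true(all(wide$range_min <= wide$range_max, na.rm = TRUE))
  # a synthetic group identical to the originals scores FID ~ 0
  same <- orig |> dplyr::mutate(group = "LS", id = paste0("ls_", id))
  rep2 <- suppressMessages(group_report(dplyr::bind_rows(orig, same)))
  expect_lt(rep2$value[rep2$metric == "fid" & rep2$group == "LS"], 1e-6)
})

test_that("per-image metric table covers every image and metric", {
  orig <- easy_organoid_dataset(3, seed = 14)
  syn <- easy_organoid_dataset(2, seed = 15) |> dplyr::mutate(group = "WASS")
  mt <- metric_table(dplyr::bind_rows(orig, syn))
  expect_equal(nrow(mt), 5)
  expect_true(all(c("blur", "ssim", "psnr", "mse", "mi", "uqm") %in% names(mt)))
  expect_true(all(is.finite(unlist(mt[, 3:8]))))
})
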