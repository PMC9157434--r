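test_that("build_confusion tabulates paired scores", {
  cm <- build_confusion(c(0, 1, 1), c(0, 0, 1), levels = 0:1)
  expect_equal(unname(cm$counts), matrix(c(1, 1, 0, 1), 2))
  expect_equal(cm$total, 3)
  expect_error(build_confusion(c(0, 5), c(0, 1), levels = 0:4),
               class = "fpd_level_out_of_range")
  expect_error(build_confusion(0:2, 0:1), class = "fpd_bad_ratings")
})

test_that("packaged fixtures carry the published totals and margins", {
  a <- fpd_fixture("table3a")
  b <- fpd_fixture("table3b")
  expect_equal(a$total, 2646)
  expect_equal(b$total, 2510)
  expect_equal(unname(rowSums(a$counts)), c(26, 182, 1553, 723, 162))
  expect_equal(unname(colSums(b$counts)), c(125, 656, 1158, 541, 30))
})

test_that("alpha is 1 on perfect agreement and -0.5 on the crossed pair", {
  diag5 <- as_diag <- fpdscore:::as_confusion(diag(c(5, 8, 2, 4, 6)))
  expect_equal(krippendorff_alpha(diag5, "ordinal")$alpha, 1)
  expect_equal(krippendorff_alpha(diag5, "nominal")$alpha, 1)
  # two units rated (0,1) and (1,0): Do = 1, De = 2/3
  crossed <- build_confusion(c(0, 1), c(1, 0), levels = 0:1)
  expect_equal(krippendorff_alpha(crossed, "nominal")$alpha, -0.5)
})

test_that("degenerate ratings yield NA alpha with a warning", {
  same <- build_confusion(rep(1, 4), rep(1, 4), levels = 0:4)
  expect_warning(res <- krippendorff_alpha(same, "ordinal"),
                 class = "fpd_degenerate_ratings")
  expect_true(is.na(res$alpha))
})

test_that("ordinal alpha with two categories equals nominal alpha", {
  for (seed in 1:4) {
    cm <- fpdscore:::with_seed(seed, build_confusion(
      sample(0:1, 60, TRUE), sample(0:1, 60, TRUE), levels = 0:1))
    expect_equal(krippendorff_alpha(cm, "ordinal")$alpha,
                 krippendorff_alpha(cm, "nominal")$alpha,
                 tolerance = 1e-12)
  }
})

test_that("alpha is invariant under confusion-matrix transposition", {
  for (seed in 1:5) {
    M <- fpdscore:::with_seed(seed,
                              matrix(rpois(25, lambda = 12), 5, 5))
    a <- krippendorff_alpha(fpdscore:::as_confusion(M), "ordinal")$alpha
    b <- krippendorff_alpha(fpdscore:::as_confusion(t(M)), "ordinal")$alpha
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("alpha converges to 0 for independent uniform ratings", {
  cm <- fpdscore:::with_seed(99, build_confusion(
    sample(0:4, 10000, TRUE), sample(0:4, 10000, TRUE)))
  for (metric in c("nominal", "ordinal", "interval"))
    expect_lt(abs(krippendorff_alpha(cm, metric)$alpha), 0.02)
})

test_that("brute-force pair-loop alpha matches the implementation to 1e-12", {
  # complete two-rater data
  for (seed in 1:3) {
    n <- 60
    ratings <- fpdscore:::with_seed(seed, data.frame(
      unit = rep(1:n, 2),
      rater = rep(c("A", "B"), each = n),
      value = c(sample(0:4, n, TRUE, prob = c(.1, .2, .4, .2, .1)),
                sample(0:4, n, TRUE))))
    for (metric in c("nominal", "ordinal", "interval"))
      expect_equal(krippendorff_alpha(ratings, metric)$alpha,
                   brute_alpha(ratings, metric), tolerance = 1e-12)
  }
  # three raters with missing values
  n <- 40
  ratings <- fpdscore:::with_seed(77, {
    df <- expand.grid(unit = 1:n, rater = c("A", "B", "C"))
    df$value <- sample(0:3, nrow(df), TRUE)
    df$value[sample(nrow(df), 15)] <- NA
    df
  })
  for (metric in c("nominal", "ordinal"))
    expect_equal(krippendorff_alpha(ratings, metric)$alpha,
                 brute_alpha(ratings, metric), tolerance = 1e-12)
})

test_that("the bootstrap CI is seed-reproducible and brackets the estimate", {
  cm <- fpd_fixture("table3a")
  r1 <- krippendorff_alpha(cm, "ordinal", n_boot = 400, seed = 5)
  r2 <- krippendorff_alpha(cm, "ordinal", n_boot = 400, seed = 5)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_identical(r1$ci_high, r2$ci_high)
  expect_lte(r1$ci_low, r1$alpha)
  expect_gte(r1$ci_high, r1$alpha)
  r3 <- krippendorff_alpha(cm, "ordinal", n_boot = 400, seed = 6)
  expect_false(identical(r1$ci_low, r3$ci_low))
  # ratings-path bootstrap is reproducible too
  ratings <- confusion_to_ratings(build_confusion(
    c(0, 0, 1, 1, 2, 2, 2), c(0, 1, 1, 1, 2, 1, 2), levels = 0:2))
  b1 <- krippendorff_alpha(ratings, "ordinal", n_boot = 200, seed = 3)
  b2 <- krippendorff_alpha(ratings, "ordinal", n_boot = 200, seed = 3)
  expect_identical(b1$ci_low, b2$ci_low)
})

test_that("landis_koch_label reproduces the published bands", {
  expect_identical(landis_koch_label(0.43), "moderate")
  expect_identical(landis_koch_label(-0.1), "poor")
  expect_identical(landis_koch_label(0.82), "almost perfect")
  expect_identical(landis_koch_label(c(0, 0.20, 0.21, 0.40, 0.41,
                                       0.60, 0.61, 0.80, 0.81, 1)),
                   c("slight", "slight", "fair", "fair", "moderate",
                     "moderate", "substantial", "substantial",
                     "almost perfect", "almost perfect"))
  expect_error(landis_koch_label(1.2), class = "fpd_bad_config")
})

test_that("performance measures count a 2x2 collapse correctly", {
  ident <- fpdscore:::as_confusion(diag(c(5, 5)))
  p <- performance_measures(ident, "gold_a")
  expect_true(all(unlist(p[, c("sensitivity", "specificity", "ppv",
                               "npv", "accuracy")]) == 1))
  M <- fpdscore:::as_confusion(matrix(c(8, 1, 2, 9), 2,
                                      dimnames = list(0:1, 0:1)))
  p2 <- performance_measures(M, "gold_a")
  lv1 <- p2[p2$level == "1", ]
  expect_equal(lv1$sensitivity, 0.9)
  expect_equal(lv1$specificity, 0.8)
  expect_equal(lv1$ppv, 9 / 11)
  expect_equal(lv1$npv, 8 / 9)
  expect_equal(lv1$accuracy, 0.85)
  expect_equal(lv1$se_accuracy, sqrt(0.85 * 0.15 / 20))
})

test_that("zero denominators give NA, never 0", {
  M <- fpdscore:::as_confusion(matrix(c(0, 0, 4, 6), 2, byrow = TRUE,
                                      dimnames = list(0:1, 0:1)))
  p <- performance_measures(M, "gold_a")
  expect_true(is.na(p$sensitivity[p$level == "0"]))   # TP+FN = 0
  expect_true(is.na(p$se_sensitivity[p$level == "0"]))
})

test_that("sensitivity under one orientation is PPV on the transpose", {
  for (seed in 1:6) {
    M <- fpdscore:::with_seed(seed, matrix(rpois(25, 7), 5, 5,
                                           dimnames = list(0:4, 0:4)))
    a <- performance_measures(fpdscore:::as_confusion(M), "gold_a")
    b <- performance_measures(fpdscore:::as_confusion(t(M)), "gold_a")
    expect_equal(a$sensitivity, b$ppv, tolerance = 1e-12)
    # accuracy is transposition-invariant
    expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
    # and gold_b on the original equals gold_a on the transpose
    g <- performance_measures(fpdscore:::as_confusion(M), "gold_b")
    expect_equal(g$sensitivity, b$sensitivity, tolerance = 1e-12)
  }
})

test_that("deviation_summary is zero on diagonal matrices", {
  d <- fpdscore:::as_confusion(diag(c(3, 4, 5, 6, 7)))
  s <- deviation_summary(d, "cols")
  expect_true(all(s$pct_differing == 0))
  expect_true(all(s$pct_differing_gt1 == 0))
})

test_that("confusion_to_ratings expands counts faithfully", {
  cm <- fpd_fixture("table3a")
  r <- confusion_to_ratings(cm)
  expect_equal(nrow(r), 2 * 2646)
  back <- fpdscore:::coincidence_matrix(r)
  expect_equal(unname(back$o), unname(cm$counts + t(cm$counts)))
})
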