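test_that("level-0 feet have no lesion and reproduce bit-identically", {
  out <- generate_foot(synthetic_foot_spec(target_level = 0,
                                           angle_class = 0, seed = 7))
  expect_equal(sum(out$truth$lesion), 0)
  expect_equal(out$truth$true_ratio, 0)
  expect_equal(out$truth$true_level, 0L)
  out2 <- generate_foot(synthetic_foot_spec(target_level = 0,
                                            angle_class = 0, seed = 7))
  expect_identical(out$image$pixels, out2$image$pixels)
  expect_identical(out$truth, out2$truth)
})

test_that("rendered lesion area hits the target ratio within 0.02", {
  for (seed in c(1, 2, 3)) {
    out <- quiet_foot(target_ratio = 0.30, seed = seed)
    expect_lt(abs(out$truth$true_ratio - 0.30), 0.02)
  }
  out <- quiet_foot(target_ratio = 0.70, seed = 4)
  expect_lt(abs(out$truth$true_ratio - 0.70), 0.02)
})

test_that("every truth satisfies mask nesting and level consistency", {
  for (seed in 1:6) {
    lvl <- (seed - 1) %% 5
    acl <- seed %% 3
    out <- generate_foot(synthetic_foot_spec(target_level = lvl,
                                             angle_class = acl, seed = seed))
    tr <- out$truth
    expect_true(all(which(tr$lesion) %in% which(tr$footpad)))
    expect_true(all(which(tr$footpad) %in% which(tr$foot)))
    expect_identical(tr$true_level,
                     classify_score(tr$true_ratio,
                                    has_lesion = sum(tr$lesion) > 0))
    expect_identical(audit_angle(tr$skew_deg), tr$angle_class)
  }
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_foot_spec(target_ratio = 1.2),
               class = "fpd_infeasible_spec")
  expect_error(synthetic_foot_spec(target_ratio = 0.9),
               class = "fpd_infeasible_spec")
  expect_error(synthetic_foot_spec(skew_deg = 70),
               class = "fpd_infeasible_spec")
  expect_error(synthetic_foot_spec(width = 32),
               class = "fpd_infeasible_spec")
})

test_that("flock marginals converge to the configured distribution", {
  # small canvas: the marginal draws do not depend on render resolution
  fl <- generate_flock(1000, width = 128, height = 128, noise = 0,
                       seed = 101)
  freq <- prop.table(table(factor(fl$manifest$true_level, 0:4)))
  target <- c(0.0167, 0.1096, 0.6602, 0.1932, 0.0203)
  expect_true(all(abs(freq - target) < 0.03))
  # chi-square goodness of fit not rejected at alpha = 0.01
  gof <- stats::chisq.test(table(factor(fl$manifest$true_level, 0:4)),
                           p = target)
  expect_gt(gof$p.value, 0.01)
})

test_that("right feet are mostly straight, left feet mostly skewed", {
  fl <- generate_flock(500, laterality_mix = 0, width = 128, height = 128,
                       noise = 0, seed = 55)   # all right feet
  straight <- mean(fl$manifest$angle_class == 0)
  expect_lt(abs(straight - 0.772), 0.04)
  fl2 <- generate_flock(500, laterality_mix = 1, width = 128, height = 128,
                        noise = 0, seed = 56)  # all left feet
  expect_lt(abs(mean(fl2$manifest$angle_class == 0) - 0.424), 0.05)
})

test_that("empty flocks and manifest writing work", {
  fl <- generate_flock(0, seed = 1)
  expect_equal(nrow(fl$manifest), 0)
  d <- withr::local_tempdir()
  fl5 <- generate_flock(5, width = 128, height = 128, seed = 2, dir = d)
  expect_equal(nrow(fl5$manifest), 5)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_length(list.files(d, pattern = "^foot_.*[0-9]_(left|right)\\.png$"), 5)
  # per-foot truth masks are written as bilevel PNGs
  expect_length(list.files(d, pattern = "_pad\\.png$"), 5)
  img <- read_png(fl5$manifest$image_path[1])
  expect_s3_class(img, "fpd_image")
})

test_that("flock generation is order-independent via seed splitting", {
  fl <- generate_flock(6, width = 128, height = 128, seed = 9)
  # regenerate foot 4 in isolation from its spec: identical
  again <- generate_foot(fl$specs[[4]])
  expect_equal(again$truth$true_ratio, fl$manifest$true_ratio[4])
  expect_equal(again$truth$skew_deg, fl$manifest$skew_deg[4])
})
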