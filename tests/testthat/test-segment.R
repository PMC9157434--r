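test_that("segment_foot recovers the synthetic truth mask", {
  out <- quiet_foot(target_ratio = 0.2, seed = 4)
  foot <- segment_foot(out$image)
  expect_gte(fpdscore:::jaccard(foot, out$truth$foot), 0.95)
})

test_that("segment_foot rejects uniform blue frames and keeps the largest blob", {
  expect_error(segment_foot(blue_frame()), class = "fpd_no_foot")
  # hand-built frame: one large and one small non-background blob
  px <- array(0L, c(100, 100, 3))
  for (ch in 1:3) px[, , ch] <- c(40L, 90L, 200L)[ch]
  px[20:70, 20:70, 1] <- 215L; px[20:70, 20:70, 2] <- 170L
  px[20:70, 20:70, 3] <- 150L
  px[85:95, 85:95, 1] <- 215L; px[85:95, 85:95, 2] <- 170L
  px[85:95, 85:95, 3] <- 150L
  mask <- segment_foot(rgb_image(px))
  expect_true(all(mask[20:70, 20:70]))
  expect_false(any(mask[85:95, 85:95]))
})

test_that("locate_footpad finds the pad, not the toes", {
  out <- quiet_foot(target_ratio = 0, seed = 6)
  foot <- segment_foot(out$image)
  fp <- locate_footpad(foot)
  expect_gt(fp$radius, 0)
  # centre inside the true pad mask (centre is 0-based)
  expect_true(out$truth$footpad[fp$center[1] + 1, fp$center[2] + 1])
  # overlap with true toe masks is at most 5% of the circle area
  toes <- Reduce(`|`, out$truth$toe_segments)
  circ <- fpdscore:::circle_mask(nrow(foot), ncol(foot), fp$center, fp$radius)
  expect_lte(sum(circ & toes) / sum(circ), 0.05)
  # footpad mask is a subset of the foot mask
  expect_true(all(which(fp$mask) %in% which(foot)))
})

test_that("locate_footpad errors on empty or vanishing masks", {
  expect_error(locate_footpad(matrix(FALSE, 64, 64)),
               class = "fpd_footpad_not_found")
  thin <- matrix(FALSE, 64, 64); thin[10:50, 30] <- TRUE
  expect_error(locate_footpad(thin, opening_radius_frac = 0.05),
               class = "fpd_footpad_not_found")
})

test_that("detect_lesions is empty on uniform pads and accurate on a 30% lesion", {
  out0 <- quiet_foot(target_ratio = 0, seed = 8)
  foot <- segment_foot(out0$image)
  fp <- locate_footpad(foot)
  for (alg in c("AUT1", "AUT2")) {
    les <- detect_lesions(out0$image, fp, algorithm = alg)
    expect_equal(les$total_area_px, 0)
  }
  out <- quiet_foot(target_ratio = 0.30, seed = 9)
  foot <- segment_foot(out$image)
  fp <- locate_footpad(foot)
  for (alg in c("AUT1", "AUT2")) {
    les <- detect_lesions(out$image, fp, algorithm = alg)
    expect_lt(abs(les$total_area_px / fp$area_px - 0.30), 0.05)
    # lesion mask nests inside the footpad mask
    expect_true(all(which(les$mask) %in% which(fp$mask)))
    # AUT1 leaves the strata unpopulated
    if (alg == "AUT1") expect_true(all(is.na(les$components$stratum)))
    else expect_true(all(les$components$stratum %in%
                           c("dark", "intermediate")))
  }
})

test_that("boundary-arc pseudo-lesions are kept by AUT1 and rejected by AUT2", {
  out <- generate_foot(synthetic_foot_spec(target_level = 0, angle_class = 0,
                                           noise = 0, pseudo_lesion = TRUE,
                                           seed = 42))
  foot <- segment_foot(out$image)
  fp <- locate_footpad(foot)
  l1 <- detect_lesions(out$image, fp, algorithm = "AUT1")
  l2 <- detect_lesions(out$image, fp, algorithm = "AUT2")
  expect_gt(l1$total_area_px, 0)
  expect_equal(l2$total_area_px, 0)
  rejected <- l2$components[!l2$components$kept, ]
  expect_gte(nrow(rejected), 1)
  expect_true(all(rejected$boundary_contact > 0.5 | rejected$elongation > 6))
})

test_that("compute_area_ratio divides and clamps", {
  fp <- structure(list(area_px = 1000), class = "fpd_footpad")
  les <- structure(list(total_area_px = 50), class = "fpd_lesions")
  expect_equal(compute_area_ratio(les, fp), 0.05)
  les$total_area_px <- 0
  expect_equal(compute_area_ratio(les, fp), 0)
  les$total_area_px <- 1000
  expect_equal(compute_area_ratio(les, fp), 1)
  fp$area_px <- 0
  expect_error(compute_area_ratio(les, fp),
               class = "fpd_degenerate_footpad")
})

test_that("classify_score follows the half-open boundary convention", {
  expect_equal(classify_score(0, has_lesion = FALSE), 0L)
  expect_equal(classify_score(0.05, TRUE), 1L)
  expect_equal(classify_score(0.32, TRUE), 3L)
  expect_equal(classify_score(0.60, TRUE), 4L)
  # strict "<" in the class definitions: exact boundaries go up
  expect_equal(classify_score(0.10, TRUE), 2L)
  expect_equal(classify_score(0.25, TRUE), 3L)
  expect_equal(classify_score(0.50, TRUE), 4L)
  expect_error(score_thresholds(t1 = 0.3, t2 = 0.2, t3 = 0.5),
               class = "fpd_invalid_thresholds")
})

test_that("classify_score is a monotone step function of the ratio", {
  r <- seq(0, 1, by = 0.005)
  lv <- classify_score(r, has_lesion = TRUE)
  expect_true(all(diff(lv) >= 0))
  expect_setequal(unique(lv), 1:4)
})

test_that("score_image composes the pipeline and embeds errors as QC flags", {
  out <- quiet_foot(target_ratio = 0.30, seed = 7)
  rec <- score_image(out$image)
  expect_equal(rec$level, 3L)
  expect_identical(rec$qc_flag, "")
  bad <- score_image(blue_frame())
  expect_identical(bad$qc_flag, "fpd_no_foot")
  expect_true(is.na(bad$level))
  df <- records_to_df(list(rec, bad))
  expect_equal(nrow(df), 2)
  expect_identical(names(df),
                   c("foot_id", "laterality", "algorithm", "level", "ratio",
                     "footpad_area_px", "lesion_area_px", "qc_flag"))
})

test_that("scoring is deterministic and mirror-invariant", {
  out <- quiet_foot(target_ratio = 0.18, seed = 10, laterality = "right")
  r1 <- score_image(out$image)
  r2 <- score_image(out$image)
  expect_identical(records_to_df(r1), records_to_df(r2))
  rm <- score_image(mirror_image(out$image))
  expect_identical(rm$level, r1$level)
  expect_equal(rm$ratio, r1$ratio, tolerance = 1e-12)
})

test_that("select_foot implements the left-default policy", {
  out <- quiet_foot(target_ratio = 0.05, seed = 11)
  good <- score_image(out$image)
  bad <- score_image(blue_frame())
  left <- good; left$foot_id <- "L"
  right <- good; right$foot_id <- "R"
  expect_identical(select_foot(left, right)$foot_id, "L")
  expect_identical(select_foot(bad, right)$foot_id, "R")
  pair <- select_foot(bad, bad)
  expect_identical(pair$qc_flag, "fpd_unscorable_pair")
  both <- select_foot(left, right, policy = "both")
  expect_identical(both$left$foot_id, "L")
  expect_error(select_foot(NULL, NULL), class = "fpd_bad_pair")
})
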