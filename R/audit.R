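# Ground-truth detection audit: grades how well the pipeline detected the
# metatarsal footpad (0-3), the alteration (0/1/3) and classifies the
# presentation angle (0-2), mirroring the manual accuracy audit that human
# raters perform on line images.

#' Audit the footpad detection against ground truth
#'
#' Excess detected area outside the true pad is measured in units of the
#' mean toe-segment area (the manual audit's "1/2 segment of a toe"
#' yardstick). A 2-px dilation of the true pad is tolerated on the excess
#' side, mirroring the manual scale's allowance for the gap/interspace
#' between pad and toes.
#'
#' Scores: 0 correct; 1 detected too big or slipped, by less than half a
#' toe segment; 2 the same, by at least half a segment; 3 detected
#' smaller than the true pad (relative deficit above `deficit_tol`).
#'
#' @param detected an `fpd_footpad` or logical mask of the detected pad.
#' @param truth an `fpd_truth` (needs `footpad` and `toe_segments`).
#' @param deficit_tol maximum tolerated relative area deficit for score 0.
#' @param slack_px dilation of the true pad tolerated on the excess side.
#' @return Integer audit score in `{0, 1, 2, 3}`.
#' @export
audit_footpad <- function(detected, truth, deficit_tol = 0.05,
                          slack_px = 2) {
  if (!inherits(truth, "fpd_truth") || is.null(truth$footpad) ||
      is.null(truth$toe_segments))
    fpd_stop("fpd_missing_truth", "truth must provide footpad and toe masks")
  det <- if (inherits(detected, "fpd_footpad")) detected$mask else detected
  pad <- truth$footpad
  seg_area <- mean(vapply(truth$toe_segments, sum, numeric(1)))
  tol_pad <- dilate_disc(pad, slack_px)
  excess_px <- sum(det & !tol_pad)
  excess <- excess_px / max(seg_area, 1)
  overlap <- sum(det & pad)
  deficit <- if (sum(pad) > 0) 1 - overlap / sum(pad) else 0
  if (excess >= 0.5) return(2L)
  if (excess >= 0.1) return(1L)
  if (deficit > deficit_tol) return(3L)
  0L
}

#' Audit the alteration (lesion) detection against ground truth
#'
#' Scores: 0 detected area within `rel_tol` of the true area; 1 detected
#' bigger; 3 detected smaller. (The manual scale has no level 2 for
#' alterations; that gap is preserved.)
#'
#' @param detected_area detected lesion area (px), or an `fpd_lesions`.
#' @param true_area true lesion area (px), or an `fpd_truth`.
#' @param rel_tol relative tolerance on the area difference.
#' @return Integer audit score in `{0, 1, 3}`.
#' @export
audit_alteration <- function(detected_area, true_area, rel_tol = 0.15) {
  if (inherits(detected_area, "fpd_lesions"))
    detected_area <- detected_area$total_area_px
  if (inherits(true_area, "fpd_truth")) true_area <- sum(true_area$lesion)
  if (true_area < 0) fpd_stop("fpd_bad_config", "true_area must be >= 0")
  tol <- rel_tol * max(true_area, 1)
  d <- detected_area - true_area
  if (abs(d) <= tol) 0L else if (d > 0) 1L else 3L
}

#' Classify the presentation angle
#'
#' @param skew_deg skew angle in degrees (>= 0).
#' @param bins class boundaries: straight up to `bins[1]`, slightly skew
#'   in `(bins[1], bins[2]]`, skew above.
#' @return Integer angle class in `{0, 1, 2}` (vectorised).
#' @export
audit_angle <- function(skew_deg, bins = c(10, 25)) {
  if (any(skew_deg < 0)) fpd_stop("fpd_bad_config", "skew_deg must be >= 0")
  as.integer(ifelse(skew_deg <= bins[1], 0L,
                    ifelse(skew_deg <= bins[2], 1L, 2L)))
}

#' Run the full audit for one synthetic foot
#'
#' Scores the image, then audits the detected footpad and lesion against
#' the generator's ground truth.
#'
#' @param image an `fpd_image`.
#' @param truth the matching `fpd_truth`.
#' @param config an [fpd_config()].
#' @return A one-row data frame: `foot_id, laterality, algorithm,
#'   angle_class, skew_deg, footpad_score, alteration_score, angle_score,
#'   qc_flag`.
#' @export
audit_scores <- function(image, truth, config = fpd_config()) {
  rec <- score_image(image, config)
  fp <- al <- NA_integer_
  if (is_scorable(rec)) {
    fp <- audit_footpad(rec$footpad, truth)
    al <- audit_alteration(rec$lesions, truth)
  }
  data.frame(foot_id = rec$foot_id, laterality = image$laterality,
             algorithm = config$algorithm,
             angle_class = truth$angle_class, skew_deg = truth$skew_deg,
             footpad_score = fp, alteration_score = al,
             angle_score = audit_angle(truth$skew_deg),
             qc_flag = rec$qc_flag)
}

#' Summarise audit records as percentage tables
#'
#' @param records data frame of audit rows (as from [audit_scores()]).
#' @param stratify_by grouping column: `"algorithm"`, `"angle"` (the
#'   angle class) or `"laterality"`.
#' @return A data frame with one row per (stratum, parameter, score):
#'   columns `stratum, parameter, score, n, pct`. Percentages sum to 100
#'   within each stratum and parameter; empty strata are dropped with a
#'   warning.
#' @export
summarize_audit <- function(records,
                            stratify_by = c("algorithm", "angle",
                                            "laterality")) {
  stratify_by <- match.arg(stratify_by)
  if (nrow(records) == 0)
    fpd_stop("fpd_bad_ratings", "no audit records to summarise")
  key <- switch(stratify_by, algorithm = "algorithm",
                angle = "angle_class", laterality = "laterality")
  out <- list()
  for (stratum in sort(unique(records[[key]]))) {
    sub <- records[records[[key]] == stratum, ]
    for (param in c("footpad_score", "alteration_score", "angle_score")) {
      v <- sub[[param]]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        fpd_warn("fpd_empty_stratum",
                 "stratum '%s' has no usable %s records", stratum, param)
        next
      }
      tab <- table(v)
      out[[length(out) + 1L]] <- data.frame(
        stratum = as.character(stratum), parameter = param,
        score = as.integer(names(tab)), n = as.integer(tab),
        pct = 100 * as.integer(tab) / length(v))
    }
  }
  do.call(rbind, out)
}
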