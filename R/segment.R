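# The automated scoring pipeline: foot segmentation, footpad localisation,
# lesion detection (AUT1 / AUT2), area-ratio computation and severity
# classification.

#' Segment the foot from the blue background
#'
#' Background pixels are those inside the configured hue window with
#' saturation at least `min_saturation`; everything else is candidate
#' foot. The largest 8-connected non-background component is kept and its
#' interior holes filled.
#'
#' @param image an `fpd_image`.
#' @param color a [color_config()].
#' @return A logical foot mask (`H x W`).
#' @section Errors: signals a condition of class `fpd_no_foot` when no
#'   component reaches 1\% of the image area (empty slaughter hook /
#'   unusable frame).
#' @export
segment_foot <- function(image, color = color_config()) {
  hsv <- image_hsv(image)
  win <- color$background_hue_window
  bg <- hsv$h >= win[1] & hsv$h <= win[2] & hsv$s >= color$min_saturation
  fg <- !bg
  foot <- largest_component(fg)
  if (sum(foot) < 0.01 * length(foot))
    fpd_stop("fpd_no_foot", "no foot detected (largest blob < 1%% of frame)")
  fill_holes(foot)
}

#' Locate the metatarsal footpad as the largest inscribed circle
#'
#' A morphological opening with a disc of radius `opening_radius_frac` of
#' the image width (at least 1 px) suppresses the toe strips; the footpad
#' is then the largest circle inscribed in the opened mask, centred at the
#' row-major-first argmax of the Euclidean distance transform.
#'
#' @param foot logical foot mask from [segment_foot()].
#' @param opening_radius_frac opening disc radius as a fraction of width.
#' @return A list of class `fpd_footpad`: `center` (0-based row/col),
#'   `radius` (px), `mask` (filled circle intersected with the foot mask)
#'   and `area_px`.
#' @section Errors: `fpd_footpad_not_found` when the opened mask is empty.
#' @export
locate_footpad <- function(foot, opening_radius_frac = 0.02) {
  if (!any(foot)) fpd_stop("fpd_footpad_not_found", "empty foot mask")
  r <- max(1L, as.integer(round(opening_radius_frac * ncol(foot))))
  opened <- open_disc(foot, r)
  circ <- inscribed_circle(opened)
  if (is.null(circ))
    fpd_stop("fpd_footpad_not_found",
             "foot too thin or fragmented after opening (radius %d px)", r)
  mask <- circle_mask(nrow(foot), ncol(foot), circ$center, circ$radius) & foot
  structure(list(center = circ$center, radius = circ$radius,
                 mask = mask, area_px = sum(mask)),
            class = "fpd_footpad")
}

#' Detect dermatitis lesions inside the footpad
#'
#' Lesions are discoloured (dark) areas of the footpad. Candidates are
#' footpad pixels whose luminance falls below a factor of the healthy-skin
#' reference luminance (upper quantile of footpad luminance, see
#' [color_config()]). `AUT1` applies the single factor `k`; `AUT2` splits
#' candidates into a dark stratum (kept, subject only to the minimum
#' component area) and an intermediate stratum that must additionally pass
#' the pseudo-lesion filters (elongation, boundary contact).
#'
#' @param image the source `fpd_image`.
#' @param footpad an `fpd_footpad` from [locate_footpad()].
#' @param color a [color_config()].
#' @param algorithm `"AUT1"` or `"AUT2"`.
#' @param thresholds a [score_thresholds()] (supplies the minimum lesion
#'   component area, resolution-scaled).
#' @return A list of class `fpd_lesions`: `mask`, `components` (data frame
#'   with `stratum`, `area_px`, `elongation`, `boundary_contact`, `kept`),
#'   `total_area_px`. An empty segmentation is a valid result.
#' @export
detect_lesions <- function(image, footpad, color = color_config(),
                           algorithm = c("AUT2", "AUT1"),
                           thresholds = score_thresholds()) {
  algorithm <- match.arg(algorithm)
  lum <- luminance(image)
  fp <- footpad$mask
  ref <- stats::quantile(lum[fp], color$reference_quantile, names = FALSE)
  min_px <- min_lesion_px_at(thresholds, ncol(fp))

  # radial distance map for boundary-contact scoring
  H <- nrow(fp); W <- ncol(fp)
  rr <- matrix(0:(H - 1), H, W); cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  rad <- sqrt((rr - footpad$center[1])^2 + (cc - footpad$center[2])^2)
  annulus <- rad > (footpad$radius - color$boundary_annulus_px) &
    rad <= footpad$radius

  strata <- if (algorithm == "AUT1") {
    list(list(name = NA_character_, mask = fp & lum < color$k * ref,
              filtered = FALSE))
  } else {
    dark <- fp & lum < color$k_dark * ref
    inter <- fp & lum >= color$k_dark * ref & lum < color$k_intermediate * ref
    list(list(name = "dark", mask = dark, filtered = FALSE),
         list(name = "intermediate", mask = inter, filtered = TRUE))
  }

  comp_rows <- list()
  keep_mask <- matrix(FALSE, H, W)
  for (st in strata) {
    lab <- label_components(st$mask)
    ncomp <- max(lab)
    if (ncomp == 0) next
    for (ci in seq_len(ncomp)) {
      idx <- which(lab == ci)
      area <- length(idx)
      pos <- cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
      elong <- component_elongation(pos)
      bc <- mean(annulus[idx])
      kept <- area >= min_px
      if (kept && st$filtered)
        kept <- elong <= color$max_elongation &&
          bc <= color$max_boundary_contact
      if (kept) keep_mask[idx] <- TRUE
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        stratum = st$name, area_px = area, elongation = elong,
        boundary_contact = bc, kept = kept)
    }
  }
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(stratum = character(), area_px = integer(),
               elongation = numeric(), boundary_contact = numeric(),
               kept = logical())
  structure(list(mask = keep_mask, components = components,
                 total_area_px = sum(keep_mask), algorithm = algorithm),
            class = "fpd_lesions")
}

#' Lesion-to-footpad area ratio
#'
#' @param lesions an `fpd_lesions`.
#' @param footpad an `fpd_footpad` with `area_px > 0`.
#' @return Ratio of lesion area to footpad area, clamped to `[0, 1]`.
#' @section Errors: `fpd_degenerate_footpad` when the footpad area is zero.
#' @export
compute_area_ratio <- function(lesions, footpad) {
  if (footpad$area_px == 0)
    fpd_stop("fpd_degenerate_footpad", "footpad area is zero")
  min(1, max(0, lesions$total_area_px / footpad$area_px))
}

#' Classify the area ratio onto the five-level severity scale
#'
#' Level 0 means no lesion at all; otherwise the ratio is binned with
#' half-open boundaries (strict upper bounds): level 1 below `t1`, level 2
#' in `[t1, t2)`, level 3 in `[t2, t3)`, level 4 at or above `t3`. A ratio
#' of exactly 0.10 therefore falls in level 2, and exactly 0.50 in level 4.
#'
#' @param ratio lesion/footpad area ratio in `[0, 1]`.
#' @param has_lesion does any lesion component survive detection?
#' @param thresholds a [score_thresholds()].
#' @return Integer severity level 0--4.
#' @export
classify_score <- function(ratio, has_lesion = ratio > 0,
                           thresholds = score_thresholds()) {
  if (!inherits(thresholds, "fpd_thresholds"))
    thresholds <- do.call(score_thresholds, as.list(thresholds))
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE))
    fpd_stop("fpd_bad_ratio", "ratio must be in [0, 1]")
  n <- max(length(ratio), length(has_lesion))
  ratio <- rep_len(ratio, n)
  has_lesion <- rep_len(has_lesion, n)
  lvl <- ifelse(!has_lesion, 0L,
         ifelse(ratio < thresholds$t1, 1L,
         ifelse(ratio < thresholds$t2, 2L,
         ifelse(ratio < thresholds$t3, 3L, 4L))))
  as.integer(lvl)
}

#' Score one foot image end to end
#'
#' Composes [segment_foot()], [locate_footpad()], [detect_lesions()],
#' [compute_area_ratio()] and [classify_score()]. Never raises on stage
#' failures: an unscorable image yields a record whose `qc_flag` carries
#' the error class (mirroring the exclusion bookkeeping of line use, where
#' unusable frames are counted, not dropped).
#'
#' @param image an `fpd_image`.
#' @param config an [fpd_config()].
#' @return A list of class `fpd_record` with fields `foot_id`,
#'   `laterality`, `algorithm`, `level`, `ratio`, `footpad_area_px`,
#'   `lesion_area_px`, `qc_flag` (empty string when scorable) and the
#'   intermediate `footpad` / `lesions` objects.
#' @export
score_image <- function(image, config = fpd_config()) {
  rec <- list(foot_id = image$id, laterality = image$laterality,
              algorithm = config$algorithm, level = NA_integer_,
              ratio = NA_real_, footpad_area_px = NA_integer_,
              lesion_area_px = NA_integer_, qc_flag = "",
              footpad = NULL, lesions = NULL)
  out <- tryCatch({
    foot <- segment_foot(image, config$color)
    footpad <- locate_footpad(foot, config$opening_radius_frac)
    lesions <- detect_lesions(image, footpad, config$color,
                              config$algorithm, config$thresholds)
    ratio <- compute_area_ratio(lesions, footpad)
    level <- classify_score(ratio, has_lesion = lesions$total_area_px > 0,
                            thresholds = config$thresholds)
    rec$level <- level
    rec$ratio <- ratio
    rec$footpad_area_px <- footpad$area_px
    rec$lesion_area_px <- lesions$total_area_px
    rec$footpad <- footpad
    rec$lesions <- lesions
    rec
  }, fpd_error = function(e) {
    rec$qc_flag <- class(e)[1]
    rec
  })
  structure(out, class = "fpd_record")
}

#' @export
print.fpd_record <- function(x, ...) {
  if (nzchar(x$qc_flag))
    cat(sprintf("<fpd_record '%s' UNSCORABLE (%s)>\n", x$foot_id, x$qc_flag))
  else
    cat(sprintf("<fpd_record '%s' %s level=%d ratio=%.3f pad=%dpx lesion=%dpx>\n",
                x$foot_id, x$algorithm, x$level, x$ratio,
                x$footpad_area_px, x$lesion_area_px))
  invisible(x)
}

is_scorable <- function(record) {
  !is.null(record) && !nzchar(record$qc_flag)
}

#' Select which foot of a pair to report
#'
#' The default line policy scores the left foot; when it is unscorable the
#' system switches to the right foot. With `policy = "both"` both records
#' are returned (the experimental design scores both feet per pair).
#'
#' @param left,right `fpd_record`s (either may be `NULL`).
#' @param policy `"left_default"` or `"both"`.
#' @return The chosen record, a list of both, or an unscorable pair record.
#' @export
select_foot <- function(left, right, policy = c("left_default", "both")) {
  policy <- match.arg(policy)
  if (is.null(left) && is.null(right))
    fpd_stop("fpd_bad_pair", "at least one record must be present")
  if (policy == "both") return(list(left = left, right = right))
  if (is_scorable(left)) return(left)
  if (is_scorable(right)) return(right)
  # neither scorable: an unscorable pair record
  base <- if (!is.null(left)) left else right
  base$foot_id <- paste0(base$foot_id, "_pair")
  base$qc_flag <- "fpd_unscorable_pair"
  base
}

#' Convert records to the per-foot output table
#'
#' @param records a list of `fpd_record`s.
#' @return A data frame, one row per foot, in the CSV column layout
#'   `foot_id, laterality, algorithm, level, ratio, footpad_area_px,
#'   lesion_area_px, qc_flag`.
#' @export
records_to_df <- function(records) {
  if (inherits(records, "fpd_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) data.frame(
    foot_id = r$foot_id, laterality = r$laterality, algorithm = r$algorithm,
    level = r$level, ratio = r$ratio, footpad_area_px = r$footpad_area_px,
    lesion_area_px = r$lesion_area_px, qc_flag = r$qc_flag)))
}
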