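# Configuration objects for the scoring pipeline.

#' Colour and lesion-detection configuration
#'
#' Controls background segmentation and lesion thresholding. Background
#' pixels are those whose HSV hue falls inside `background_hue_window`
#' (degrees on the 0--360 circle) with saturation at least
#' `min_saturation`. The default window `[170, 270]` spans the cyan-to-blue
#' hues of industrial blue belts and backdrops.
#'
#' Lesion candidates are footpad pixels darker than a fraction of the
#' healthy-skin luminance, estimated as the `reference_quantile` upper
#' quantile of footpad luminance. (A median reference breaks down exactly
#' in the severe class, where the lesion covers more than half the pad and
#' becomes the median itself.) The one-threshold variant AUT1 uses factor
#' `k`; the stratified variant AUT2 splits candidates into a dark stratum
#' (`< k_dark`) kept unconditionally and an intermediate stratum
#' (`k_dark`--`k_intermediate`) subject to pseudo-lesion rejection:
#' components more elongated than `max_elongation` or with more than
#' `max_boundary_contact` of their pixels inside the `boundary_annulus_px`
#' inner rim of the footpad circle are discarded as shadow/boundary
#' artifacts.
#'
#' @param background_hue_window numeric length 2, hue window in degrees.
#' @param min_saturation minimum saturation for a background pixel.
#' @param k AUT1 darkness factor.
#' @param k_dark,k_intermediate AUT2 stratum factors, `0 < k_dark <
#'   k_intermediate < 1`.
#' @param max_elongation,max_boundary_contact,boundary_annulus_px AUT2
#'   pseudo-lesion filters.
#' @param reference_quantile quantile of footpad luminance used as the
#'   healthy-skin reference (0.5 reproduces a plain median).
#' @return A list of class `fpd_color_config`.
#' @export
color_config <- function(background_hue_window = c(170, 270),
                         min_saturation = 0.25,
                         k = 0.60,
                         k_dark = 0.45,
                         k_intermediate = 0.65,
                         max_elongation = 6.0,
                         max_boundary_contact = 0.5,
                         boundary_annulus_px = 3,
                         reference_quantile = 0.90) {
  if (!(k_dark > 0 && k_dark < k_intermediate && k_intermediate < 1))
    fpd_stop("fpd_bad_config", "need 0 < k_dark < k_intermediate < 1")
  if (length(background_hue_window) != 2)
    fpd_stop("fpd_bad_config", "background_hue_window must have length 2")
  structure(as.list(environment()), class = "fpd_color_config")
}

#' Severity-score thresholds
#'
#' Area-ratio boundaries of the five-level severity scale and the smallest
#' pixel area counted as a lesion. Boundaries are half-open with strict
#' upper bounds, so a ratio of exactly `t1` falls in the next class up:
#' level 1 is `[0, t1)`, level 2 `[t1, t2)`, level 3 `[t2, t3)` and level 4
#' `[t3, 1]`. `min_lesion_px` is stated at `reference_width` image width and
#' scaled quadratically with actual resolution.
#'
#' @param t1,t2,t3 ratio boundaries, `0 < t1 < t2 < t3 < 1`.
#' @param min_lesion_px minimum component area (px) at the reference width.
#' @param reference_width image width at which `min_lesion_px` is stated.
#' @return A list of class `fpd_thresholds`.
#' @export
score_thresholds <- function(t1 = 0.10, t2 = 0.25, t3 = 0.50,
                             min_lesion_px = 9, reference_width = 512) {
  if (!(is.finite(t1) && is.finite(t2) && is.finite(t3) &&
        0 < t1 && t1 < t2 && t2 < t3 && t3 < 1))
    fpd_stop("fpd_invalid_thresholds", "need 0 < t1 < t2 < t3 < 1")
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 min_lesion_px = min_lesion_px,
                 reference_width = reference_width),
            class = "fpd_thresholds")
}

min_lesion_px_at <- function(thresholds, width) {
  max(1L, as.integer(round(
    thresholds$min_lesion_px * (width / thresholds$reference_width)^2)))
}

#' Full pipeline configuration
#'
#' Bundles every tunable of a scoring run. All fields have defaults; the
#' resolved configuration is serialised (JSON) next to the outputs of every
#' CLI run so that a run can be repeated bit-for-bit.
#'
#' @param color a [color_config()].
#' @param thresholds a [score_thresholds()].
#' @param algorithm `"AUT1"` (single threshold) or `"AUT2"` (stratified,
#'   with pseudo-lesion rejection); AUT2 is the default.
#' @param opening_radius_frac disc radius of the morphological opening that
#'   suppresses toes, as a fraction of image width.
#' @param selection foot-selection policy: `"left_default"` (score the left
#'   foot, fall back to the right) or `"both"`.
#' @param n_boot,ci bootstrap settings for agreement statistics.
#' @param seed integer seed for all randomness in a run.
#' @return A list of class `fpd_config`.
#' @export
fpd_config <- function(color = color_config(),
                       thresholds = score_thresholds(),
                       algorithm = c("AUT2", "AUT1"),
                       opening_radius_frac = 0.02,
                       selection = c("left_default", "both"),
                       n_boot = 5000L,
                       ci = 0.95,
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  selection <- match.arg(selection)
  structure(list(color = color, thresholds = thresholds,
                 algorithm = algorithm,
                 opening_radius_frac = opening_radius_frac,
                 selection = selection, n_boot = as.integer(n_boot),
                 ci = ci, seed = as.integer(seed)),
            class = "fpd_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_to_json <- function(config, path = NULL) {
  x <- strip_classes(config)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- fpd_config()
  merge_block <- function(ctor, block, given) {
    if (is.null(given)) return(block)
    do.call(ctor, modifyList(lapply(unclass(block), identity),
                             as.list(given)))
  }
  fpd_config(
    color = merge_block(color_config, defaults$color, x$color),
    thresholds = merge_block(score_thresholds, defaults$thresholds,
                             x$thresholds),
    algorithm = x$algorithm %||% defaults$algorithm,
    opening_radius_frac = x$opening_radius_frac %||%
      defaults$opening_radius_frac,
    selection = x$selection %||% defaults$selection,
    n_boot = x$n_boot %||% defaults$n_boot,
    ci = x$ci %||% defaults$ci,
    seed = x$seed %||% defaults$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
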