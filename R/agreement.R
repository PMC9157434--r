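# Krippendorff's alpha (nominal / ordinal / interval) with bootstrap CIs,
# confusion matrices, one-vs-rest performance measures with binomial
# standard errors, deviation summaries and Landis-Koch bands.

#' Build a confusion matrix from paired ordinal scores
#'
#' @param a,b equal-length vectors of scores (axis A, e.g. the human
#'   rater, tabulated on rows; axis B, e.g. the automated scorer, on
#'   columns).
#' @param levels the ordered category set (default 0--4).
#' @param labels length-2 character, names of the two axes.
#' @return An object of class `fpd_confusion`: integer `counts` matrix
#'   with the axis labels, plus cell percentages of the grand total.
#' @export
build_confusion <- function(a, b, levels = 0:4,
                            labels = c("HUM", "AUT")) {
  if (length(a) != length(b))
    fpd_stop("fpd_bad_ratings", "paired score vectors differ in length")
  if (!all(a %in% levels) || !all(b %in% levels))
    fpd_stop("fpd_level_out_of_range",
             "scores outside the declared level set")
  counts <- table(factor(a, levels = levels), factor(b, levels = levels))
  counts <- matrix(as.integer(counts), length(levels), length(levels),
                   dimnames = list(levels, levels))
  as_confusion(counts, labels)
}

as_confusion <- function(counts, labels = c("HUM", "AUT")) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0))
    fpd_stop("fpd_bad_ratings", "counts must be a square non-negative matrix")
  structure(list(counts = counts,
                 percent = 100 * counts / max(1, sum(counts)),
                 total = sum(counts),
                 axis_a = labels[1], axis_b = labels[2],
                 levels = rownames(counts) %||% as.character(
                   seq_len(nrow(counts)) - 1)),
            class = "fpd_confusion")
}

#' @export
print.fpd_confusion <- function(x, digits = 2, ...) {
  cat(sprintf("Confusion matrix: %s (rows) x %s (cols), n = %d\n",
              x$axis_a, x$axis_b, x$total))
  disp <- matrix(sprintf("%d (%.*f)", x$counts, digits, x$percent),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  print(as.data.frame(disp), right = TRUE)
  invisible(x)
}

#' Packaged confusion-matrix fixtures
#'
#' `"table3a"` is the 5x5 human-vs-automated cross-tabulation of the
#' pre-modification validation dataset (n = 2,646 feet; automated variant
#' AUT1); `"table3b"` the post-modification dataset (n = 2,510; AUT2).
#' Rows are the human scores, columns the automated scores.
#'
#' @param name fixture name.
#' @return An `fpd_confusion`.
#' @export
fpd_fixture <- function(name = c("table3a", "table3b")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "fpdscore")
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  as_confusion(m, labels = c("HUM", if (name == "table3a") "AUT1" else "AUT2"))
}

# ---- coincidence matrix and difference functions -----------------------

#' Coincidence matrix of paired ordinal ratings
#'
#' For two complete raters the coincidence matrix is `counts + t(counts)`;
#' in general every ordered within-unit pair of values contributes
#' `1/(m_u - 1)` where `m_u` is the number of values in the unit.
#'
#' @param x an `fpd_confusion`, or a ratings data frame with columns
#'   `unit`, `rater`, `value`.
#' @param levels category set for ratings input (default: sorted unique
#'   observed values).
#' @return A list: `o` (symmetric K x K), `n_c` (marginals), `n`
#'   (pairable total), `levels`.
#' @export
coincidence_matrix <- function(x, levels = NULL) {
  if (inherits(x, "fpd_confusion")) {
    o <- x$counts + t(x$counts)
    lev <- x$levels
  } else {
    df <- as.data.frame(x)
    stopifnot(all(c("unit", "value") %in% names(df)))
    df <- df[!is.na(df$value), ]
    if (is.null(levels)) levels <- sort(unique(df$value))
    K <- length(levels)
    o <- matrix(0, K, K, dimnames = list(levels, levels))
    for (u in split(df$value, df$unit)) {
      m <- length(u)
      if (m < 2) next                      # unit needs >= 2 values to pair
      iv <- match(u, levels)
      for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
        o[iv[i], iv[j]] <- o[iv[i], iv[j]] + 1 / (m - 1)
    }
    lev <- as.character(levels)
  }
  list(o = o, n_c = rowSums(o), n = sum(o), levels = lev)
}

# Squared difference function delta^2 for a metric, given coincidence
# marginals n_c (needed by the ordinal metric). Categories are taken at
# their ordinal positions; interval uses the numeric level values.
delta_sq <- function(metric, n_c, level_values = NULL) {
  K <- length(n_c)
  d2 <- matrix(0, K, K)
  if (metric == "nominal") {
    d2 <- 1 - diag(K)
  } else if (metric == "interval") {
    v <- if (is.null(level_values)) seq_len(K) else level_values
    d2 <- outer(v, v, function(a, b) (a - b)^2)
  } else if (metric == "ordinal") {
    for (c in seq_len(K)) for (k in seq_len(K)) {
      if (c == k) next
      lo <- min(c, k); hi <- max(c, k)
      d2[c, k] <- (sum(n_c[lo:hi]) - (n_c[c] + n_c[k]) / 2)^2
    }
  } else fpd_stop("fpd_bad_config", "unknown metric '%s'", metric)
  d2
}

alpha_from_coincidence <- function(o, n_c, metric, level_values = NULL) {
  n <- sum(n_c)
  d2 <- delta_sq(metric, n_c, level_values)
  Do <- sum(o * d2) / n
  De <- sum(outer(n_c, n_c) * d2) / (n * (n - 1))
  if (De <= 0) return(NA_real_)
  1 - Do / De
}

#' Krippendorff's alpha with bootstrap confidence interval
#'
#' Computes `alpha = 1 - Do/De` from the coincidence matrix of the data,
#' with the nominal, ordinal or interval difference function. The ordinal
#' squared difference between categories `c <= k` is
#' `(sum(n_g, g = c..k) - (n_c + n_k)/2)^2` over the coincidence
#' marginals. The bootstrap resamples units with replacement and reports a
#' percentile interval; it is bit-reproducible under a fixed seed.
#'
#' @param x an `fpd_confusion` (two complete raters) or ratings data frame
#'   (columns `unit`, `rater`, `value`).
#' @param metric `"ordinal"` (default), `"nominal"` or `"interval"`.
#' @param n_boot bootstrap replicates (0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @param ci confidence level of the percentile interval.
#' @param level_values numeric values of the categories for the interval
#'   metric (defaults to ordinal positions).
#' @return A list of class `fpd_alpha`: `alpha`, `metric`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `landis_koch`, `n_units`.
#' @section Degenerate data: when all values coincide the expected
#'   disagreement is zero and alpha is undefined; it is returned as `NA`
#'   with a warning of class `fpd_degenerate_ratings`.
#' @export
krippendorff_alpha <- function(x, metric = c("ordinal", "nominal",
                                             "interval"),
                               n_boot = 0L, seed = 1L, ci = 0.95,
                               level_values = NULL) {
  metric <- match.arg(metric)
  cm <- coincidence_matrix(x)
  alpha <- alpha_from_coincidence(cm$o, cm$n_c, metric, level_values)
  if (is.na(alpha))
    fpd_warn("fpd_degenerate_ratings",
             "all ratings identical: expected disagreement is 0, alpha undefined")
  res <- list(alpha = alpha, metric = metric, ci_low = NA_real_,
              ci_high = NA_real_, ci_level = ci,
              n_boot = as.integer(n_boot),
              seed = as.integer(seed),
              landis_koch = if (is.na(alpha)) NA_character_ else
                landis_koch_label(alpha),
              n_units = if (inherits(x, "fpd_confusion")) x$total else
                length(unique(as.data.frame(x)$unit)))
  if (n_boot > 0 && !is.na(alpha)) {
    boots <- bootstrap_alpha(x, metric, n_boot, seed, level_values)
    qs <- stats::quantile(boots, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                          na.rm = TRUE, names = FALSE, type = 7)
    res$ci_low <- qs[1]; res$ci_high <- qs[2]
  }
  structure(res, class = "fpd_alpha")
}

# Unit-level bootstrap. Units collapse to a small set of distinct rating
# patterns; resampling units uniformly with replacement is a multinomial
# draw over those patterns, which keeps 5,000 replicates fast.
bootstrap_alpha <- function(x, metric, n_boot, seed, level_values = NULL) {
  if (inherits(x, "fpd_confusion")) {
    K <- nrow(x$counts)
    cellcount <- as.vector(x$counts)            # pattern = (row, col) cell
    n_units <- sum(cellcount)
    # coincidence contribution of one unit in cell (c, k): +1 at o[c,k]
    # and o[k,c]
    pat_idx <- which(cellcount > 0)
    probs <- cellcount[pat_idx] / n_units
    rowof <- (pat_idx - 1) %% K + 1
    colof <- (pat_idx - 1) %/% K + 1
    with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        cnt <- as.vector(rmultinom(1, n_units, probs))
        o <- matrix(0, K, K)
        for (p in seq_along(pat_idx)) {
          o[rowof[p], colof[p]] <- o[rowof[p], colof[p]] + cnt[p]
          o[colof[p], rowof[p]] <- o[colof[p], rowof[p]] + cnt[p]
        }
        alpha_from_coincidence(o, rowSums(o), metric, level_values)
      }, numeric(1))
    })
  } else {
    df <- as.data.frame(x)
    df <- df[!is.na(df$value), ]
    levels <- sort(unique(df$value))
    K <- length(levels)
    units <- split(match(df$value, levels), df$unit)
    units <- units[vapply(units, length, 1L) >= 2]
    # per-unit coincidence contribution, flattened K x K
    contrib <- vapply(units, function(iv) {
      m <- length(iv)
      o <- matrix(0, K, K)
      for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
        o[iv[i], iv[j]] <- o[iv[i], iv[j]] + 1 / (m - 1)
      as.vector(o)
    }, numeric(K * K))
    pat <- apply(contrib, 2, paste, collapse = ",")
    groups <- split(seq_along(pat), pat)
    pat_contrib <- vapply(groups, function(ix) contrib[, ix[1]],
                          numeric(K * K))
    probs <- vapply(groups, length, 1L) / length(pat)
    with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        cnt <- as.vector(rmultinom(1, length(pat), probs))
        o <- matrix(pat_contrib %*% cnt, K, K)
        alpha_from_coincidence(o, rowSums(o), metric)
      }, numeric(1))
    })
  }
}

#' @export
print.fpd_alpha <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s): %s", x$metric,
              if (is.na(x$alpha)) "undefined (degenerate ratings)"
              else sprintf("%.4f [%s]", x$alpha, x$landis_koch)))
  if (!is.na(x$ci_low))
    cat(sprintf("  %d%% CI [%.4f, %.4f] (%d bootstraps, seed %d)",
                round(100 * x$ci_level), x$ci_low, x$ci_high,
                x$n_boot, x$seed))
  cat("\n")
  invisible(x)
}

#' Landis-Koch verbal band of an agreement coefficient
#'
#' Bands: below 0.00 poor; 0.00--0.20 slight; 0.21--0.40 fair; 0.41--0.60
#' moderate; 0.61--0.80 substantial; 0.81--1.00 almost perfect (upper
#' boundaries inclusive).
#'
#' @param alpha agreement coefficient, `<= 1`.
#' @return Character label.
#' @export
landis_koch_label <- function(alpha) {
  if (any(alpha > 1, na.rm = TRUE))
    fpd_stop("fpd_bad_config", "agreement coefficients cannot exceed 1")
  vapply(alpha, function(a) {
    if (is.na(a)) NA_character_
    else if (a < 0) "poor"
    else if (a <= 0.20) "slight"
    else if (a <= 0.40) "fair"
    else if (a <= 0.60) "moderate"
    else if (a <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

# ---- performance measures ----------------------------------------------

#' One-vs-rest performance measures from a confusion matrix
#'
#' For every level the K x K matrix is collapsed to a 2 x 2 table and
#' sensitivity, specificity, positive/negative predictive value and
#' accuracy are computed with binomial standard errors
#' `sqrt(p (1 - p) / m)` (`m` = the measure's denominator). `orientation`
#' picks which axis is the gold standard: `"gold_a"` treats the row rater
#' as gold (the conventional reading with the human on rows), `"gold_b"`
#' the column rater. Published validation tables mix the two conventions,
#' so both are first-class. Zero-denominator measures are `NA`, never 0.
#'
#' @param confusion an `fpd_confusion`.
#' @param orientation `"gold_a"` or `"gold_b"`.
#' @return A data frame of class `fpd_performance`, one row per level:
#'   `level, TP, FP, TN, FN, sensitivity, specificity, ppv, npv, accuracy`
#'   and their `se_*` columns.
#' @export
performance_measures <- function(confusion,
                                 orientation = c("gold_a", "gold_b")) {
  orientation <- match.arg(orientation)
  M <- confusion$counts
  if (nrow(M) < 2) fpd_stop("fpd_bad_ratings", "need at least 2 levels")
  if (orientation == "gold_b") M <- t(M)
  total <- sum(M)
  rows <- lapply(seq_len(nrow(M)), function(i) {
    TP <- M[i, i]
    FN <- sum(M[i, ]) - TP          # gold positive, scored negative
    FP <- sum(M[, i]) - TP          # scored positive, gold negative
    TN <- total - TP - FN - FP
    meas <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- meas(TP, TP + FN); spec <- meas(TN, TN + FP)
    ppv <- meas(TP, TP + FP); npv <- meas(TN, TN + FN)
    acc <- meas(TP + TN, total)
    se <- function(p, m) if (is.na(p) || m == 0) NA_real_ else
      sqrt(p * (1 - p) / m)
    data.frame(level = confusion$levels[i], TP = TP, FP = FP, TN = TN,
               FN = FN,
               sensitivity = sens, se_sensitivity = se(sens, TP + FN),
               specificity = spec, se_specificity = se(spec, TN + FP),
               ppv = ppv, se_ppv = se(ppv, TP + FP),
               npv = npv, se_npv = se(npv, TN + FN),
               accuracy = acc, se_accuracy = se(acc, total))
  })
  out <- do.call(rbind, rows)
  attr(out, "orientation") <- orientation
  class(out) <- c("fpd_performance", "data.frame")
  out
}

#' Per-level deviation summary of a confusion matrix
#'
#' For each level on the chosen margin: the percentage of all units in
#' that margin line scored differently by the other axis
#' (`pct_differing`), and the percentage differing by more than one level
#' (`pct_differing_gt1`), both as percentages of the grand total.
#'
#' @param confusion an `fpd_confusion`.
#' @param margin `"cols"` (condition on the column rater, e.g. the
#'   automated score) or `"rows"`.
#' @return Data frame: `level, pct_differing, pct_differing_gt1`.
#' @export
deviation_summary <- function(confusion, margin = c("cols", "rows")) {
  margin <- match.arg(margin)
  M <- confusion$counts
  if (margin == "rows") M <- t(M)
  total <- sum(M)
  K <- nrow(M)
  out <- lapply(seq_len(K), function(c) {
    colc <- M[, c]
    diff_ <- sum(colc) - M[c, c]
    gt1 <- sum(colc[abs(seq_len(K) - c) > 1])
    data.frame(level = confusion$levels[c],
               pct_differing = 100 * diff_ / total,
               pct_differing_gt1 = 100 * gt1 / total)
  })
  do.call(rbind, out)
}

#' Expand a confusion matrix to unit-level paired ratings
#'
#' @param confusion an `fpd_confusion`.
#' @return A data frame with columns `unit`, `rater`, `value`, two rows
#'   per unit.
#' @export
confusion_to_ratings <- function(confusion) {
  M <- confusion$counts
  lev <- suppressWarnings(as.numeric(confusion$levels))
  if (anyNA(lev)) lev <- seq_len(nrow(M))
  idx <- which(M > 0, arr.ind = TRUE)
  a <- rep(lev[idx[, 1]], M[idx])
  b <- rep(lev[idx[, 2]], M[idx])
  n <- length(a)
  data.frame(unit = rep(seq_len(n), 2),
             rater = rep(c(confusion$axis_a, confusion$axis_b), each = n),
             value = c(a, b))
}
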