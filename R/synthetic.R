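# Seeded synthetic foot-image generator with full ground truth.
#
# The generator renders a stylised poultry foot on a blue backdrop: a
# circular metatarsal pad, three forward toes with phalange segments plus a
# hind toe, and an irregular dark lesion occupying a target fraction of the
# pad. Presentation skew is modelled as an out-of-plane rotation about the
# vertical axis (horizontal compression by cos(theta)) and reproduces the
# two failure mechanisms documented for skewed feet: a desaturated cast
# shadow along the trailing edge (inflates the detected footpad) and
# grazing-light washout of the lesion rim (shrinks the detected
# alteration). Both effects grow with the skew angle.

#' Specification of one synthetic foot
#'
#' @param target_level severity level 0--4; the lesion area fraction is
#'   drawn uniformly inside the level's ratio band. Ignored when
#'   `target_ratio` is given.
#' @param target_ratio lesion/pad area fraction in `[0, 0.85]`.
#' @param angle_class presentation-angle class: 0 straight (< 10 deg), 1
#'   slightly skew (10--25 deg), 2 skew (> 25 deg). Ignored when
#'   `skew_deg` is given.
#' @param skew_deg explicit skew angle in degrees, `[0, 60]`.
#' @param laterality `"left"` or `"right"`.
#' @param width,height canvas size in pixels (>= 64).
#' @param noise Gaussian pixel-noise standard deviation as a fraction of
#'   the 8-bit range (0.02 emulates sensor noise; 0 = noise-free).
#' @param pseudo_lesion add a thin dark arc hugging the pad boundary (a
#'   shadow artifact that the stratified detector is meant to reject).
#' @param seed integer seed; generation is bit-reproducible.
#' @return A list of class `fpd_foot_spec`.
#' @section Errors: `fpd_infeasible_spec` for a ratio above 1 or geometry
#'   that cannot fit the canvas.
#' @export
synthetic_foot_spec <- function(target_level = NULL, target_ratio = NULL,
                                angle_class = NULL, skew_deg = NULL,
                                laterality = c("left", "right"),
                                width = 256L, height = 256L,
                                noise = 0.02, pseudo_lesion = FALSE,
                                seed = 1L) {
  laterality <- match.arg(laterality)
  if (is.null(target_ratio) && is.null(target_level)) target_level <- 0L
  if (!is.null(target_ratio)) {
    if (target_ratio > 1 || target_ratio < 0)
      fpd_stop("fpd_infeasible_spec", "target_ratio must be in [0, 1]")
    if (target_ratio > 0.85)
      fpd_stop("fpd_infeasible_spec",
               "lesion fraction > 0.85 cannot be rendered inside the pad")
  }
  if (!is.null(skew_deg) && (skew_deg < 0 || skew_deg > 60))
    fpd_stop("fpd_infeasible_spec", "skew_deg must be in [0, 60]")
  if (is.null(skew_deg) && is.null(angle_class)) angle_class <- 0L
  if (width < 64 || height < 64)
    fpd_stop("fpd_infeasible_spec", "canvas must be at least 64 x 64")
  structure(list(target_level = target_level, target_ratio = target_ratio,
                 angle_class = angle_class, skew_deg = skew_deg,
                 laterality = laterality, width = as.integer(width),
                 height = as.integer(height), noise = noise,
                 pseudo_lesion = isTRUE(pseudo_lesion),
                 seed = as.integer(seed)),
            class = "fpd_foot_spec")
}

# Ratio bands of the severity levels the generator samples from.
.level_ratio_bands <- list(`0` = c(0, 0),
                           `1` = c(0.012, 0.098),
                           `2` = c(0.102, 0.248),
                           `3` = c(0.252, 0.498),
                           `4` = c(0.502, 0.800))

# Angle ranges sampled per class (degrees).
.angle_class_bands <- list(`0` = c(0, 8), `1` = c(10.5, 24.5),
                           `2` = c(25.5, 45))

# Palette: luminances chosen so lesions sit well below the AUT1/AUT2
# darkness thresholds and the shadow is desaturated (classified as foot).
.palette <- list(background = c(40, 90, 200),
                 skin = c(215, 170, 150),
                 toe = c(210, 165, 145),
                 lesion_dark = c(50, 25, 20),
                 shadow = c(70, 75, 85))

lum_of <- function(rgb) 0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3]

# Colour whose luminance is `t` times skin luminance, on the line between
# the dark lesion colour and skin.
lesion_colour <- function(t) {
  p <- .palette
  l1 <- lum_of(p$lesion_dark) / lum_of(p$skin)
  u <- pmin(1, pmax(0, (t - l1) / (1 - l1)))
  sapply(seq_along(u), function(i)
    p$lesion_dark + u[i] * (p$skin - p$lesion_dark))
}

# distance grids (0-based pixel coordinates)
grid_rc <- function(H, W) {
  list(r = matrix(0:(H - 1), H, W), c = matrix(0:(W - 1), H, W, byrow = TRUE))
}

capsule_mask <- function(H, W, p0, p1, halfwidth) {
  g <- grid_rc(H, W)
  v <- p1 - p0
  L2 <- sum(v * v)
  t <- ((g$r - p0[1]) * v[1] + (g$c - p0[2]) * v[2]) / max(L2, 1e-9)
  t <- pmin(1, pmax(0, t))
  dr <- g$r - (p0[1] + t * v[1])
  dc <- g$c - (p0[2] + t * v[2])
  dr * dr + dc * dc <= halfwidth^2
}

#' Render a synthetic foot image with ground truth
#'
#' @param spec an [synthetic_foot_spec()].
#' @return A list with `image` (an `fpd_image`) and `truth`, a list of
#'   class `fpd_truth`: `foot` / `footpad` / `lesion` masks, `toe_segments`
#'   (list of masks), `true_ratio`, `true_level`, `skew_deg`,
#'   `angle_class`, `laterality`. The truth excludes rendering artifacts
#'   (shadow, noise): it is what a perfect detector should recover.
#' @export
generate_foot <- function(spec) {
  stopifnot(inherits(spec, "fpd_foot_spec"))
  with_seed(spec$seed, render_foot(spec))
}

render_foot <- function(spec) {
  H <- spec$height; W <- spec$width
  p <- .palette

  # resolve target ratio and skew angle
  ratio <- spec$target_ratio
  if (is.null(ratio)) {
    band <- .level_ratio_bands[[as.character(spec$target_level)]]
    if (is.null(band))
      fpd_stop("fpd_infeasible_spec", "target_level must be 0..4")
    ratio <- if (band[2] == 0) 0 else runif(1, band[1], band[2])
  }
  theta <- spec$skew_deg
  if (is.null(theta)) {
    band <- .angle_class_bands[[as.character(spec$angle_class)]]
    if (is.null(band))
      fpd_stop("fpd_infeasible_spec", "angle_class must be 0, 1 or 2")
    theta <- runif(1, band[1], band[2])
  }
  angle_class <- if (theta <= 10) 0L else if (theta <= 25) 1L else 2L

  # ---- canonical geometry (right foot, no skew) ----
  R0 <- 0.17 * min(H, W)
  pc <- c(0.60 * H, 0.50 * W)           # pad centre (row, col), 0-based
  g <- grid_rc(H, W)
  pad <- (g$r - pc[1])^2 + (g$c - pc[2])^2 <= R0^2

  toe_w <- max(5, round(0.030 * W)) / 2          # capsule halfwidth
  toe_len <- 0.40 * H
  toe_angles <- c(-38, -4, 32) * pi / 180        # from vertical-up
  toe_segments <- list()
  toes <- matrix(FALSE, H, W)
  for (a in toe_angles) {
    dirv <- c(-cos(a), sin(a))                   # (drow, dcol), up-ish
    base <- pc + (R0 - 1) * dirv
    nseg <- 3L
    for (s in seq_len(nseg)) {
      q0 <- base + (s - 1) / nseg * toe_len * dirv
      q1 <- base + s / nseg * toe_len * dirv
      seg <- capsule_mask(H, W, q0, q1, toe_w)
      toe_segments[[length(toe_segments) + 1L]] <- seg
      toes <- toes | seg
    }
  }
  # hind toe, pointing down
  hb <- pc + (R0 - 1) * c(1, 0.15)
  hind <- capsule_mask(H, W, hb, hb + 0.12 * H * c(1, 0.2), toe_w * 0.8)
  toe_segments[[length(toe_segments) + 1L]] <- hind
  toes <- toes | hind
  foot <- pad | toes

  # ---- lesion: union of discs grown to the target pad fraction ----
  pad_area <- sum(pad)
  lesion <- matrix(FALSE, H, W)
  if (ratio > 0) {
    n_blob <- if (ratio < 0.10) sample(1:3, 1) else if (ratio < 0.25)
      sample(1:2, 1) else 1L
    centers <- matrix(0, n_blob, 2)
    centers[1, ] <- pc + runif(2, -0.12, 0.12) * R0
    if (n_blob > 1)
      for (b in 2:n_blob)
        centers[b, ] <- pc + runif(2, -0.40, 0.40) * R0
    w_b <- runif(n_blob, 0.6, 1); w_b <- w_b / sum(w_b)
    scale <- sqrt(ratio * pad_area / pi)         # first guess, px
    max_r <- 0.92 * R0
    for (it in 1:4) {
      lesion <- matrix(FALSE, H, W)
      for (b in seq_len(n_blob)) {
        rb <- min(scale * sqrt(w_b[b] * n_blob), max_r)
        # clamp centre so the blob stays inside 0.97 R0
        off <- centers[b, ] - pc
        d <- sqrt(sum(off^2))
        lim <- max(0, 0.97 * R0 - rb)
        if (d > lim && d > 0) centers[b, ] <- pc + off * lim / d
        lesion <- lesion |
          ((g$r - centers[b, 1])^2 + (g$c - centers[b, 2])^2 <= rb^2)
      }
      lesion <- lesion & pad
      a <- sum(lesion)
      if (a > 0) scale <- scale * sqrt(ratio * pad_area / a)
    }
  }

  # luminance profile of the lesion: dark core, lighter rim
  les_t <- NULL
  if (any(lesion)) {
    dmax <- sqrt(max(edt_sq(lesion)))
    dn <- 1 - sqrt(edt_sq(lesion)) / max(dmax, 1)  # 0 core .. 1 rim
    les_t <- 0.30 + 0.25 * dn                      # luminance / skin
  }

  # pseudo-lesion: thin dark arc hugging the pad boundary (span 70 deg)
  pseudo <- matrix(FALSE, H, W)
  if (spec$pseudo_lesion) {
    radial <- sqrt((g$r - pc[1])^2 + (g$c - pc[2])^2)
    ang <- atan2(g$c - pc[2], -(g$r - pc[1]))      # 0 = up
    a0 <- runif(1, -pi, pi)
    dang <- abs(((ang - a0 + pi) %% (2 * pi)) - pi)
    pseudo <- radial > R0 - 2.5 & radial <= R0 - 0.5 & dang <= 35 * pi / 180
  }

  # ---- composite canonical image ----
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(p$background[ch], H, W)
    m[pad] <- p$skin[ch]
    m[toes & !pad] <- p$toe[ch]
    img[, , ch] <- m
  }

  # grazing-light washout of the lesion rim; like the cast shadow it only
  # appears once the foot leaves the camera's depth-of-focus cone (~8 deg)
  washout <- 0.8 * max(0, sin(theta * pi / 180) - sin(8 * pi / 180))
  if (any(lesion)) {
    tt <- pmin(0.95, les_t[lesion] + washout)
    cols <- lesion_colour(tt)                      # 3 x npix
    for (ch in 1:3) {
      m <- img[, , ch]; m[lesion] <- cols[ch, ]; img[, , ch] <- m
    }
  }
  if (any(pseudo)) {
    tt <- pmin(0.95, 0.55 + washout)
    cols <- lesion_colour(rep(tt, sum(pseudo)))
    for (ch in 1:3) {
      m <- img[, , ch]; m[pseudo] <- cols[ch, ]; img[, , ch] <- m
    }
  }

  # ---- skew: horizontal compression by cos(theta) ----
  squash <- function(M, fill) {
    cx <- (W - 1) / 2
    src <- round(cx + ((0:(W - 1)) - cx) / cos(theta * pi / 180))
    ok <- src >= 0 & src <= W - 1
    out <- matrix(fill, nrow(M), W)
    out[, ok] <- M[, src[ok] + 1]
    out
  }
  if (theta > 0.01) {
    for (ch in 1:3) img[, , ch] <- squash(img[, , ch], p$background[ch])
    foot <- squash(foot, FALSE); pad <- squash(pad, FALSE)
    lesion <- squash(lesion, FALSE); pseudo <- squash(pseudo, FALSE)
    toe_segments <- lapply(toe_segments, squash, fill = FALSE)
  }

  # ---- cast shadow along the trailing (right) edge ----
  sh_w <- round(0.28 * R0 * max(0, sin(theta * pi / 180) - sin(8 * pi / 180)))
  if (sh_w > 0) {
    shadow <- matrix(FALSE, H, W)
    for (s in seq_len(sh_w))
      shadow[, (1 + s):W] <- shadow[, (1 + s):W] | foot[, 1:(W - s)]
    shadow <- shadow & !foot
    for (ch in 1:3) {
      m <- img[, , ch]; m[shadow] <- p$shadow[ch]; img[, , ch] <- m
    }
  }

  # ---- laterality: canonical geometry is a right foot ----
  if (spec$laterality == "left") {
    flip <- function(M) M[, W:1, drop = FALSE]
    for (ch in 1:3) img[, , ch] <- flip(img[, , ch])
    foot <- flip(foot); pad <- flip(pad); lesion <- flip(lesion)
    pseudo <- flip(pseudo)
    toe_segments <- lapply(toe_segments, flip)
  }

  # ---- sensor noise ----
  if (spec$noise > 0)
    img <- img + array(rnorm(H * W * 3, 0, spec$noise * 255), c(H, W, 3))
  img <- array(as.integer(pmin(255, pmax(0, round(img)))), c(H, W, 3))

  true_ratio <- if (sum(pad) > 0) sum(lesion) / sum(pad) else 0
  truth <- structure(list(
    foot = foot, footpad = pad, lesion = lesion,
    pseudo_lesion = pseudo,
    toe_segments = toe_segments,
    true_ratio = true_ratio,
    true_level = classify_score(true_ratio, has_lesion = any(lesion)),
    skew_deg = theta, angle_class = angle_class,
    laterality = spec$laterality), class = "fpd_truth")

  id <- sprintf("synthetic_%s_%d", spec$laterality, spec$seed)
  list(image = rgb_image(img, id = id, laterality = spec$laterality),
       truth = truth)
}

#' Generate a flock of synthetic feet
#'
#' Draws per-foot specifications i.i.d. from configurable marginals and
#' renders each foot. Default level marginals follow the human-score
#' margin of the large post-modification validation dataset; the default
#' probability of a straight presentation is 0.772 for right feet and
#' 0.424 for left feet, reflecting the slaughter-line mechanics that leave
#' the left foot hanging skew.
#'
#' @param n number of feet.
#' @param level_marginals probabilities of severity levels 0--4 (sum 1).
#' @param straight_prob named vector: probability of a straight (class-0)
#'   presentation for `left` and `right` feet.
#' @param class1_given_skew probability that a skewed presentation is only
#'   slightly skew (class 1 rather than class 2).
#' @param laterality_mix probability that a foot is a left foot.
#' @param width,height,noise forwarded to [synthetic_foot_spec()].
#' @param seed master seed; per-foot seeds are split deterministically, so
#'   generation is order-independent.
#' @param dir if non-`NULL`, images and bilevel truth masks are written as
#'   PNGs under `dir` and the manifest gains `image_path`.
#' @param keep_images keep rendered images in the returned object (memory
#'   heavy for large `n`; they can always be re-rendered from the specs).
#' @return A list of class `fpd_flock`: `specs` (list), `manifest` (data
#'   frame: `foot_id, laterality, angle_class, skew_deg, true_level,
#'   true_ratio`, plus `image_path` when written), and `images`/`truths`
#'   when `keep_images = TRUE`.
#' @export
generate_flock <- function(n,
                           level_marginals = c(0.0167, 0.1096, 0.6602,
                                               0.1932, 0.0203),
                           straight_prob = c(left = 0.424, right = 0.772),
                           class1_given_skew = 0.894,
                           laterality_mix = 0.5,
                           width = 256L, height = 256L, noise = 0.02,
                           seed = 1L, dir = NULL, keep_images = FALSE) {
  if (abs(sum(level_marginals) - 1) > 1e-6)
    fpd_stop("fpd_bad_config", "level_marginals must sum to 1")
  if (n < 0) fpd_stop("fpd_bad_config", "n must be >= 0")
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  specs <- vector("list", n)
  rows <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  truths <- if (keep_images) vector("list", n) else NULL
  for (i in seq_len(n)) {
    si <- split_seed(seed, i)
    draw <- with_seed(si, {
      lat <- if (runif(1) < laterality_mix) "left" else "right"
      lvl <- sample(0:4, 1, prob = level_marginals)
      straight <- runif(1) < straight_prob[[lat]]
      acl <- if (straight) 0L else if (runif(1) < class1_given_skew) 1L else 2L
      list(lat = lat, lvl = lvl, acl = acl)
    })
    sp <- synthetic_foot_spec(target_level = draw$lvl,
                              angle_class = draw$acl,
                              laterality = draw$lat,
                              width = width, height = height, noise = noise,
                              seed = split_seed(si, 7))
    out <- generate_foot(sp)
    specs[[i]] <- sp
    fid <- sprintf("foot_%04d_%s", i, draw$lat)
    row <- data.frame(foot_id = fid, laterality = draw$lat,
                      angle_class = out$truth$angle_class,
                      skew_deg = out$truth$skew_deg,
                      true_level = out$truth$true_level,
                      true_ratio = out$truth$true_ratio)
    if (!is.null(dir)) {
      ip <- file.path(dir, paste0(fid, ".png"))
      write_png(out$image, ip)
      write_png(out$truth$footpad, file.path(dir, paste0(fid, "_pad.png")))
      write_png(out$truth$lesion, file.path(dir, paste0(fid, "_lesion.png")))
      row$image_path <- ip
    }
    rows[[i]] <- row
    if (keep_images) {
      images[[i]] <- out$image
      truths[[i]] <- out$truth
    }
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(foot_id = character(), laterality = character(),
               angle_class = integer(), skew_deg = numeric(),
               true_level = integer(), true_ratio = numeric())
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(specs = specs, manifest = manifest,
                 images = images, truths = truths, seed = seed),
            class = "fpd_flock")
}
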