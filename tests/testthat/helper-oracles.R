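# Independent oracles and small fixture builders used across the suite.

# Brute-force largest inscribed circle: for every foreground pixel compute
# the exact minimum distance to any background pixel (image border counts
# as background), take the row-major-first maximum. No distance transform.
brute_inscribed_circle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  fg <- which(pad, arr.ind = TRUE)
  bg <- which(!pad, arr.ind = TRUE)
  if (nrow(fg) == 0) return(NULL)
  best <- -1; bi <- bj <- NA
  ord <- order(fg[, 1], fg[, 2])          # row-major scan
  for (i in ord) {
    d2 <- min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2)
    if (d2 > best) { best <- d2; bi <- fg[i, 1]; bj <- fg[i, 2] }
  }
  list(center = c(row = bi - 2L, col = bj - 2L), radius = sqrt(best))
}

# Brute-force Krippendorff's alpha: explicit loops over value pairs, no
# coincidence matrix. `ratings` is a data frame unit/rater/value.
brute_alpha <- function(ratings, metric = "ordinal") {
  df <- ratings[!is.na(ratings$value), ]
  units <- split(df$value, df$unit)
  units <- units[vapply(units, length, 1L) >= 2]
  vals <- unlist(units, use.names = FALSE)
  lev <- sort(unique(vals))
  n_c <- vapply(lev, function(l) sum(vals == l), numeric(1))
  d2 <- function(a, b) {
    ia <- match(a, lev); ib <- match(b, lev)
    if (metric == "nominal") return(as.numeric(a != b))
    if (metric == "interval") return((a - b)^2)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(n_c[lo:hi]) - (n_c[ia] + n_c[ib]) / 2)^2
  }
  n <- length(vals)
  Do <- 0
  for (u in units) {
    m <- length(u)
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
      Do <- Do + d2(u[i], u[j]) / (m - 1)
  }
  Do <- Do / n
  De <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    De <- De + d2(vals[i], vals[j])
  De <- De / (n * (n - 1))
  if (De <= 0) return(NA_real_)
  1 - Do / De
}

# Random blobby mask for oracle-equivalence properties.
random_mask <- function(H, W, n_blobs = 3, seed = 1) {
  fpdscore:::with_seed(seed, {
    m <- matrix(FALSE, H, W)
    for (b in seq_len(n_blobs)) {
      r0 <- runif(1, 0.2, 0.8) * H
      c0 <- runif(1, 0.2, 0.8) * W
      rad <- runif(1, 0.08, 0.3) * min(H, W)
      m <- m | fpdscore:::circle_mask(H, W, c(r0, c0), rad)
    }
    m
  })
}

# Flat blue frame of the generator's backdrop colour.
blue_frame <- function(H = 100, W = 100) {
  rgb_image(array(rep(c(40L, 90L, 200L), each = H * W), c(H, W, 3)),
            id = "blue")
}

# Straight, noise-free synthetic foot; the workhorse fixture.
quiet_foot <- function(..., seed = 1) {
  generate_foot(synthetic_foot_spec(..., angle_class = 0, noise = 0,
                                    seed = seed))
}
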