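# Binary-mask utilities: components, hole filling, disc morphology via the
# Euclidean distance transform, and the largest inscribed circle.
#
# Masks are plain logical matrices, same H x W as their source image.
# Coordinates reported to users are 0-based (row, col), origin top-left.

mask_area <- function(mask) sum(mask)

# Squared EDT: distance from each true pixel to the nearest false pixel,
# with everything outside the image treated as false.
edt_sq <- function(mask) edt_sq_cpp(mask)

label_components <- function(mask, connectivity = 8L)
  label_components_cpp(mask, as.integer(connectivity))

largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Fill interior holes: complement components (4-connectivity) not touching
# the image border are holes.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Disc-structuring-element morphology through the EDT: erosion keeps pixels
# farther than r from background, dilation keeps pixels within r of the set.
erode_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  edt_sq(mask) > r * r
}

dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  # distance to the mask itself; the outside of the image is not mask
  edt_sq_cpp(!mask, outside_background = FALSE) <= r * r
}

open_disc <- function(mask, r) dilate_disc(erode_disc(mask, r), r)

# Largest inscribed circle of a mask: centre at the row-major argmax of the
# EDT, radius the maximal distance. Ties broken by first occurrence in
# row-major (reading) order.
inscribed_circle <- function(mask) {
  d2 <- edt_sq(mask)
  best <- -1
  bi <- bj <- NA_integer_
  H <- nrow(d2); W <- ncol(d2)
  # row-major scan; matrices are column-major so walk explicitly
  mx <- max(d2)
  if (mx <= 0) return(NULL)
  hits <- which(d2 == mx, arr.ind = TRUE)
  ord <- order(hits[, 1], hits[, 2])   # row-major first occurrence
  bi <- hits[ord[1], 1]; bj <- hits[ord[1], 2]
  list(center = c(row = bi - 1L, col = bj - 1L), radius = sqrt(mx))
}

# Filled circle mask (pixel centres within radius of centre, 0-based centre).
circle_mask <- function(H, W, center, radius) {
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Second-moment elongation of a pixel set: sqrt of the ratio of the
# covariance eigenvalues (>= 1; Inf for degenerate/collinear sets).
component_elongation <- function(idx_rc) {
  if (nrow(idx_rc) < 3) return(Inf)
  cv <- stats::cov(idx_rc)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9) return(Inf)
  sqrt(ev[1] / ev[2])
}
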