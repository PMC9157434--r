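# RGB raster container and minimal PNG I/O.
#
# Images are integer arrays H x W x 3 (8-bit per channel), row-major,
# origin top-left, 0-based pixel coordinates in all reported geometry.

#' Construct an RGB foot image
#'
#' @param pixels integer array `H x W x 3`, values in `[0, 255]`.
#' @param id opaque identifier string.
#' @param laterality one of `"left"`, `"right"`, `"unknown"`.
#' @return An object of class `fpd_image`.
#' @export
rgb_image <- function(pixels, id = "img", laterality = "unknown") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    fpd_stop("fpd_bad_image", "pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L)
    fpd_stop("fpd_bad_image", "image must be at least 64 x 64 (got %d x %d)",
             d[1], d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    fpd_stop("fpd_bad_image", "channel values must be in [0, 255]")
  laterality <- match.arg(laterality, c("left", "right", "unknown"))
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = d),
         id = as.character(id), laterality = laterality),
    class = "fpd_image"
  )
}

#' @export
print.fpd_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fpd_image '%s' %dx%d, laterality=%s>\n",
              x$id, d[1], d[2], x$laterality))
  invisible(x)
}

#' @export
dim.fpd_image <- function(x) dim(x$pixels)

#' Mirror an image left-right
#'
#' Flips the column order of an image (and swaps the recorded laterality).
#' Used by the laterality-invariance checks: scoring is purely geometric,
#' so a mirrored foot must receive the same severity level.
#'
#' @param image an `fpd_image`.
#' @return The mirrored `fpd_image`.
#' @export
mirror_image <- function(image) {
  px <- image$pixels[, dim(image$pixels)[2]:1, , drop = FALSE]
  lat <- switch(image$laterality, left = "right", right = "left", "unknown")
  rgb_image(px, id = image$id, laterality = lat)
}

# Rec.601 luma, the working definition of pixel luminance (0..255).
luminance <- function(image) {
  px <- if (inherits(image, "fpd_image")) image$pixels else image
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# Hue (degrees, 0..360) and saturation (0..1) matrices of an image.
image_hsv <- function(image) {
  px <- image$pixels
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# ---- PNG codec ---------------------------------------------------------
#
# Self-contained baseline PNG support (8-bit grey / RGB / RGBA, no
# interlacing) built on base R's zlib bindings. No imaging package in the
# dependency stack provides raster file I/O, so the few dozen lines live
# here; TIFF input is not supported.

# R's bitwShiftR zero-fills, i.e. shifts are unsigned; -306674912L is the
# CRC-32 polynomial 0xEDB88320 as a signed 32-bit value.
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        cc <- n
        for (k in 1:8) {
          cc <- if (bitwAnd(cc, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(cc, 1L))
          else bitwShiftR(cc, 1L)
        }
        t[n + 1] <- cc
      }
      tab <<- t
    }
    tab
  }
})

# CRC-32 over a raw vector; returns a double in [0, 2^32).
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1])
  }
  crcd <- as.double(bitwXor(crc, -1L))
  if (crcd < 0) crcd <- crcd + 2^32
  crcd
}

u32_bytes <- function(x) {
  x <- as.double(x)
  as.raw(c(floor(x / 2^24) %% 256, floor(x / 2^16) %% 256,
           floor(x / 2^8) %% 256, x %% 256))
}

bytes_u32 <- function(b) {
  sum(as.double(b) * c(2^24, 2^16, 2^8, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, u32_bytes(crc32(body)))
}

#' Write an image or mask as a PNG file
#'
#' Writes 8-bit greyscale (matrix input; logical masks become 0/255
#' bilevel) or 8-bit RGB (`fpd_image` or `H x W x 3` array input),
#' non-interlaced, scanline filter 0.
#'
#' @param x an `fpd_image`, an `H x W x 3` array, or a numeric/logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(x, path) {
  if (inherits(x, "fpd_image")) x <- x$pixels
  if (is.logical(x)) x <- matrix(as.integer(x) * 255L, nrow(x), ncol(x))
  if (is.matrix(x)) {
    H <- nrow(x); W <- ncol(x); ctype <- 0L
    scan <- t(x)                       # W x H, column = one image row
    raw_rows <- rbind(0L, matrix(as.integer(scan), W, H))
  } else {
    d <- dim(x); H <- d[1]; W <- d[2]; ctype <- 2L
    # interleave RGB per pixel within each scanline
    inter <- aperm(x, c(3, 2, 1))      # 3 x W x H
    raw_rows <- rbind(0L, matrix(as.integer(inter), 3L * W, H))
  }
  payload <- as.raw(pmin(pmax(as.vector(raw_rows), 0L), 255L))
  ihdr <- c(u32_bytes(W), u32_bytes(H), as.raw(c(8L, ctype, 0L, 0L, 0L)))
  idat <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read a PNG file
#'
#' Supports baseline 8-bit greyscale, RGB and RGBA PNGs without
#' interlacing. An alpha channel is dropped with a warning.
#'
#' @param path file path.
#' @param id,laterality metadata for the returned image; `laterality`
#'   defaults to a guess from the file name (`_left`/`_right` suffix).
#' @return An `fpd_image` for colour input, a numeric matrix for greyscale.
#' @export
read_png <- function(path, id = NULL, laterality = NULL) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(bytes) < 8 || !identical(bytes[1:8], sig))
    fpd_stop("fpd_bad_png", "not a PNG file: %s", path)
  pos <- 9L
  idat <- raw(0); W <- H <- depth <- ctype <- interlace <- NULL
  while (pos + 7 <= length(bytes)) {
    len <- bytes_u32(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      W <- bytes_u32(data[1:4]); H <- bytes_u32(data[5:8])
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(W)) fpd_stop("fpd_bad_png", "missing IHDR in %s", path)
  if (depth != 8L || interlace != 0L || !(ctype %in% c(0L, 2L, 4L, 6L)))
    fpd_stop("fpd_bad_png",
             "unsupported PNG (need 8-bit, non-interlaced grey/RGB/RGBA)")
  nch <- c(`0` = 1L, `2` = 3L, `4` = 2L, `6` = 4L)[as.character(ctype)]
  raw_dat <- memDecompress(idat, type = "gzip")
  stride <- W * nch
  dat <- matrix(as.integer(raw_dat), nrow = stride + 1L, ncol = H)
  out <- matrix(0L, stride, H)
  prev <- integer(stride)
  bpp <- nch
  for (r in seq_len(H)) {
    ft <- dat[1, r]
    line <- dat[-1, r]
    if (ft == 0L) {
      cur <- line
    } else if (ft == 2L) {
      cur <- (line + prev) %% 256L
    } else {
      cur <- integer(stride)
      left <- integer(bpp); upleft <- integer(bpp)
      for (i in seq_len(stride)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        b <- prev[i]
        cc <- if (i > bpp) prev[i - bpp] else 0L
        add <- switch(as.character(ft),
                      `1` = a,
                      `3` = (a + b) %/% 2L,
                      `4` = paeth(a, b, cc),
                      fpd_stop("fpd_bad_png", "bad filter type %d", ft))
        cur[i] <- (line[i] + add) %% 256L
      }
    }
    out[, r] <- cur
    prev <- cur
  }
  if (is.null(laterality)) {
    laterality <- if (grepl("left", basename(path))) "left"
    else if (grepl("right", basename(path))) "right" else "unknown"
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (nch == 1L) return(matrix(as.numeric(out), H, W, byrow = TRUE))
  if (nch == 2L) {
    fpd_warn("fpd_alpha_ignored", "alpha channel ignored in %s", path)
    return(matrix(as.numeric(out[seq(1, stride, by = 2), ]), H, W,
                  byrow = TRUE))
  }
  if (nch == 4L) {
    fpd_warn("fpd_alpha_ignored", "alpha channel ignored in %s", path)
    keep <- rep(c(TRUE, TRUE, TRUE, FALSE), W)
    out <- out[keep, , drop = FALSE]
    nch <- 3L
  }
  arr <- array(0L, c(H, W, 3))
  cube <- array(as.integer(out), c(3L, W, H))   # channel x col x row
  arr <- aperm(cube, c(3, 2, 1))
  rgb_image(arr, id = id, laterality = laterality)
}
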