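#' Raster containers for seed images
#'
#' The pipeline uses three light-weight raster types, all stored row-by-column
#' so that `x[r, c]` addresses the pixel in image row `r` (top to bottom) and
#' column `c` (left to right), with pixel centres at integer coordinates:
#'
#' * `color_image`: integer array `height x width x 3` with channels R, G, B
#'   in `[0, 255]`.
#' * `gray_image`: integer matrix with intensities in `[0, 255]`.
#' * `binary_mask`: integer matrix with values in `{0, 1}` (1 = foreground).
#'
#' @param x For `color_image()` a numeric array `h x w x 3`; for
#'   `gray_image()` and `binary_mask()` a numeric matrix.
#' @return An object of the corresponding class.
#' @examples
#' img <- color_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' extract_red_band(img)[1, 1]
#' @name rasters
NULL

#' @rdname rasters
#' @export
color_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("color_image requires an h x w x 3 array", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop("channel values must be finite and in [0, 255]", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = c("color_image", "array"))
}

#' @rdname rasters
#' @export
gray_image <- function(x) {
  if (!is.matrix(x)) stop("gray_image requires a matrix", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop("intensities must be finite and in [0, 255]", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = c("gray_image", "matrix"))
}

#' @rdname rasters
#' @export
binary_mask <- function(x) {
  if (!is.matrix(x)) stop("binary_mask requires a matrix", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("mask values must be 0 or 1", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = c("binary_mask", "matrix"))
}

img_dim <- function(x) dim(x)[1:2]

stopifnot_same_dim <- function(a, b) {
  if (!identical(img_dim(a), img_dim(b)))
    stop("dimension mismatch: ", paste(img_dim(a), collapse = "x"), " vs ",
         paste(img_dim(b), collapse = "x"), call. = FALSE)
}

#' @export
print.color_image <- function(x, ...) {
  cat("<color_image> ", nrow(x), " x ", ncol(x), " px, RGB\n", sep = "")
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat("<gray_image> ", nrow(x), " x ", ncol(x), " px, range [",
      min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x), " x ", ncol(x), " px, ",
      sum(x), " foreground\n", sep = "")
  invisible(x)
}

#' Read a single-seed colour image
#'
#' Reads an RGB image from a PNG or an uncompressed 24-bit BMP file (the two
#' capture formats supported for seed photographs) into a [color_image].
#' The format is chosen from the file signature, not the extension.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return A [color_image].
#' @export
read_seed_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 2L && magic[1] == as.raw(0x42) && magic[2] == as.raw(0x4d))
    return(read_bmp24(path))
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
  if (length(magic) >= 4L && identical(magic[1:4], png_sig)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    return(color_image(round(a[, , 1:3, drop = FALSE] * 255)))
  }
  stop("unsupported image format (need PNG or 24-bit BMP): ", path, call. = FALSE)
}

# Minimal uncompressed 24-bit BMP reader (BITMAPINFOHEADER, bottom-up or
# top-down rows, BGR byte order, rows padded to 4 bytes).
read_bmp24 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  s32 <- function(i) { v <- u32(i); if (v >= 2^31) v - 2^32 else v }
  if (u16(1) != 0x4d42) stop("not a BMP file", call. = FALSE)
  offset <- u32(11) + 1L
  w <- s32(19); h_raw <- s32(23)
  bpp <- u16(29); compression <- u32(31)
  if (bpp != 24L || compression != 0L)
    stop("only uncompressed 24-bit BMP images are supported", call. = FALSE)
  h <- abs(h_raw); bottom_up <- h_raw > 0
  stride <- ((w * 3 + 3) %/% 4) * 4
  px <- as.integer(raw[offset:(offset + stride * h - 1L)])
  arr <- array(0L, dim = c(h, w, 3L))
  for (row in seq_len(h)) {
    base <- (row - 1L) * stride
    line <- px[base + seq_len(w * 3)]
    r_img <- if (bottom_up) h - row + 1L else row
    arr[r_img, , 1] <- line[seq(3, w * 3, by = 3)]
    arr[r_img, , 2] <- line[seq(2, w * 3, by = 3)]
    arr[r_img, , 3] <- line[seq(1, w * 3, by = 3)]
  }
  color_image(arr)
}

#' Write rasters as PNG
#'
#' Masks are written with foreground as 255 and background as 0; colour
#' images are written as 8-bit RGB.
#'
#' @param x A [binary_mask] or [color_image].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  png::writePNG(unclass(x) * 1.0, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
write_image_png <- function(x, path) {
  png::writePNG(unclass(x) / 255, target = path)
  invisible(path)
}

#' Read a mask written by [write_mask_png()]
#'
#' Any pixel with intensity above 127 is treated as foreground.
#'
#' @param path Path to a PNG mask.
#' @return A [binary_mask].
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask((a > 0.5) * 1L)
}
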