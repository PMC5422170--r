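#' Segmentation configuration
#'
#' Controls the dual-band segmentation pipeline of [segment_seed()].
#'
#' @param smooth_ksize Odd box-filter width in pixels applied to each band
#'   before thresholding. `1` disables smoothing. Default `3`.
#' @param red_polarity,hue_polarity `"bright"`, `"dark"`, or `"auto"` — which
#'   side of the Otsu threshold is seed. `"auto"` picks the side that places
#'   fewer pixels on the image border (a single seed is an interior object).
#' @param component `"largest"` keeps only the largest 8-connected foreground
#'   component after hole filling (removes residual noise blobs); `"all"`
#'   keeps everything.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(smooth_ksize = 3L,
                       red_polarity = c("auto", "bright", "dark"),
                       hue_polarity = c("auto", "bright", "dark"),
                       component = c("largest", "all")) {
  smooth_ksize <- as.integer(smooth_ksize)
  if (smooth_ksize < 1L || smooth_ksize %% 2L == 0L)
    stop("smooth_ksize must be a positive odd integer", call. = FALSE)
  structure(list(smooth_ksize = smooth_ksize,
                 red_polarity = match.arg(red_polarity),
                 hue_polarity = match.arg(hue_polarity),
                 component = match.arg(component)),
            class = "seg_config")
}

#' Read a segmentation configuration from YAML or JSON
#'
#' Accepts a file with any subset of the [seg_config()] fields
#' (`smooth_ksize`, `red_polarity`, `hue_polarity`, `component`);
#' unspecified fields keep their defaults. The format is chosen by
#' extension (`.json` is JSON, anything else is parsed as YAML).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A [seg_config()].
#' @export
read_seg_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(seg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown segmentation config fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(seg_config, vals[intersect(names(vals), known)])
}

#' Extract the red band of a colour image
#'
#' @param img A [color_image].
#' @return A [gray_image] holding the R channel.
#' @export
extract_red_band <- function(img) {
  stopifnot(inherits(img, "color_image"))
  gray_image(matrix(img[, , 1], nrow = nrow(img)))
}

#' Extract the hue band of a colour image
#'
#' Hue is the HSV hue angle in `[0, 360)` degrees, linearly rescaled to
#' integers in `[0, 255]`. Achromatic pixels (R = G = B), whose hue is
#' undefined, map to 0.
#'
#' @param img A [color_image].
#' @return A [gray_image].
#' @export
extract_hue_band <- function(img) {
  stopifnot(inherits(img, "color_image"))
  h <- grDevices::rgb2hsv(r = as.vector(img[, , 1]),
                          g = as.vector(img[, , 2]),
                          b = as.vector(img[, , 3]),
                          maxColorValue = 255)[1, ]
  gray_image(matrix(as.integer(round(h * 255)), nrow = nrow(img)))
}

#' Box-mean smoothing with edge replication
#'
#' One pass of a `k x k` box mean; pixels outside the image are replicated
#' from the nearest edge pixel and the result is rounded to the nearest
#' integer. A `1 x 1` kernel (or a constant image) returns the input
#' unchanged.
#'
#' @param img A [gray_image].
#' @param ksize Odd kernel width, default 3.
#' @return A [gray_image].
#' @export
smooth_image <- function(img, ksize = 3L) {
  stopifnot(inherits(img, "gray_image"))
  ksize <- as.integer(ksize)
  if (ksize < 1L || ksize %% 2L == 0L)
    stop("ksize must be a positive odd integer", call. = FALSE)
  if (ksize == 1L) return(img)
  m <- unclass(img)
  r <- (ksize - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  cidx <- pmin(pmax(seq(1L - r, nc + r), 1L), nc)
  pad <- m[ridx, cidx, drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (dr in 0:(ksize - 1L)) for (dc in 0:(ksize - 1L))
    acc <- acc + pad[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  gray_image(round(acc / (ksize * ksize)))
}

#' Otsu's threshold on the 256-bin histogram
#'
#' Returns the threshold `t` in `[0, 255]` maximising the between-class
#' variance of the split `{<= t}` / `{> t}`; ties are broken by the smallest
#' `t`. A constant image has no meaningful split and is an error.
#'
#' @param img A [gray_image].
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- tabulate(as.vector(unclass(img)) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) stop("degenerate histogram", call. = FALSE)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * levels)
  mu_total <- sum0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- sum0 / w0
  mu1 <- (mu_total - sum0) / w1
  sigma_b <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  as.integer(which.max(sigma_b) - 1L)   # which.max takes the first maximum
}

#' Threshold a grey image into a binary mask
#'
#' @param img A [gray_image].
#' @param t Threshold in `[0, 255]`.
#' @param polarity `"bright"`: pixels `> t` become foreground;
#'   `"dark"`: pixels `<= t` become foreground.
#' @return A [binary_mask].
#' @export
binarize <- function(img, t, polarity = c("bright", "dark")) {
  stopifnot(inherits(img, "gray_image"))
  polarity <- match.arg(polarity)
  if (t < 0 || t > 255) stop("threshold must be in [0, 255]", call. = FALSE)
  m <- unclass(img)
  binary_mask(if (polarity == "bright") (m > t) * 1L else (m <= t) * 1L)
}

#' Pixelwise OR of two masks
#'
#' @param a,b [binary_mask]s of equal dimensions.
#' @return A [binary_mask].
#' @export
mask_or <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stopifnot_same_dim(a, b)
  binary_mask((unclass(a) | unclass(b)) * 1L)
}

#' Fill enclosed holes in a mask
#'
#' Background regions that cannot be reached from the image border by
#' 4-connected background steps are set to foreground (foreground is
#' treated as 8-connected, the standard dual convention). Foreground never
#' shrinks.
#'
#' @param m A [binary_mask].
#' @return A [binary_mask].
#' @export
fill_holes <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  out <- EBImage::fillHull(unclass(m))
  binary_mask(matrix(as.integer(out > 0), nrow = nrow(m)))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(unclass(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Keep only the largest 8-connected foreground component
#'
#' Ties between equally large components are broken by the smallest
#' top-left pixel in row-major order.
#'
#' @param m A [binary_mask] with at least one foreground pixel.
#' @return A [binary_mask].
#' @export
largest_component <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  if (sum(m) == 0L) stop("no foreground", call. = FALSE)
  lab <- label_components8(m)
  k <- max(lab)
  if (k == 1L) return(m)
  sizes <- tabulate(lab[lab > 0], nbins = k)
  idx <- which(lab > 0, arr.ind = TRUE)
  rowmajor <- (idx[, 1] - 1) * ncol(m) + idx[, 2]
  first_px <- vapply(seq_len(k), function(l) min(rowmajor[lab[lab > 0] == l]), numeric(1))
  best <- order(-sizes, first_px)[1]
  binary_mask((lab == best) * 1L)
}

#' Mask a colour image (AND with a binary mask)
#'
#' Foreground pixels are copied from `img`; background pixels are set to
#' black `(0, 0, 0)`.
#'
#' @param img A [color_image].
#' @param m A [binary_mask] of equal dimensions.
#' @return A [color_image].
#' @export
mask_apply <- function(img, m) {
  stopifnot(inherits(img, "color_image"), inherits(m, "binary_mask"))
  stopifnot_same_dim(img, m)
  out <- unclass(img)
  mm <- unclass(m)
  for (ch in 1:3) out[, , ch] <- out[, , ch] * mm
  color_image(out)
}

band_to_mask <- function(band, polarity, ksize) {
  sm <- smooth_image(band, ksize)
  t <- otsu_threshold(sm)
  if (polarity != "auto")
    return(list(mask = binarize(sm, t, polarity), threshold = t))
  bright <- binarize(sm, t, "bright")
  dark <- binarize(sm, t, "dark")
  border <- function(x) {
    x <- unclass(x)
    sum(x[1, ]) + sum(x[nrow(x), ]) + sum(x[, 1]) + sum(x[, ncol(x)])
  }
  list(mask = if (border(bright) <= border(dark)) bright else dark,
       threshold = t)
}

#' Segment a single paddy seed from a colour image
#'
#' The dual-band pipeline: the red and hue bands are each smoothed,
#' Otsu-thresholded and binarised; the two binary images are combined with a
#' pixelwise OR; enclosed holes are filled; only the largest 8-connected
#' component is kept (single-seed assumption); and the original image is
#' masked with the result.
#'
#' @param img A [color_image].
#' @param cfg A [seg_config()].
#' @return A list of class `seed_segmentation` with elements `mask`
#'   (final [binary_mask]), `image` (masked [color_image]), and the
#'   per-band thresholds `red_threshold`, `hue_threshold`.
#' @examples
#' sil <- make_silhouette(seed_spec(rng_seed = 1))
#' img <- render_image(sil$mask, noise_sd = 0)
#' seg <- segment_seed(img)
#' mask_iou(seg$mask, sil$mask)
#' @export
segment_seed <- function(img, cfg = seg_config()) {
  stopifnot(inherits(img, "color_image"), inherits(cfg, "seg_config"))
  red <- band_to_mask(extract_red_band(img), cfg$red_polarity, cfg$smooth_ksize)
  hue <- band_to_mask(extract_hue_band(img), cfg$hue_polarity, cfg$smooth_ksize)
  m <- fill_holes(mask_or(red$mask, hue$mask))
  if (cfg$component == "largest") m <- largest_component(m)
  structure(list(mask = m,
                 image = mask_apply(img, m),
                 red_threshold = red$threshold,
                 hue_threshold = hue$threshold),
            class = "seed_segmentation")
}

#' @export
print.seed_segmentation <- function(x, ...) {
  cat("<seed_segmentation> ", nrow(x$mask), " x ", ncol(x$mask), " px, ",
      sum(x$mask), " foreground px (red t=", x$red_threshold,
      ", hue t=", x$hue_threshold, ")\n", sep = "")
  invisible(x)
}

#' Intersection-over-union of two masks
#'
#' @param a,b [binary_mask]s of equal dimensions.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot_same_dim(a, b)
  inter <- sum(unclass(a) & unclass(b))
  uni <- sum(unclass(a) | unclass(b))
  if (uni == 0L) return(1)
  inter / uni
}
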