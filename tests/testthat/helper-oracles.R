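# Independent brute-force oracles and programmatic fixtures. These are
# deliberately written without reference to the package internals they
# check.

# Exhaustive Otsu: evaluate the between-class variance of every threshold
# 0..255 directly from the definition.
oracle_otsu <- function(values) {
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Border flood fill over 4-connected background; returns the hole-filled
# mask.
oracle_fill_holes <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  reach <- matrix(FALSE, nr, nc)
  queue <- list()
  push <- function(r, c) {
    if (r >= 1 && r <= nr && c >= 1 && c <= nc && !reach[r, c] && m[r, c] == 0) {
      reach[r, c] <<- TRUE
      queue[[length(queue) + 1L]] <<- c(r, c)
    }
  }
  for (r in seq_len(nr)) { push(r, 1); push(r, nc) }
  for (c in seq_len(nc)) { push(1, c); push(nr, c) }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  out <- m
  out[m == 0 & !reach] <- 1L
  out
}

# All-pairs longest chord by direct double maximisation.
oracle_longest_chord <- function(pts) {
  pts <- unique(pts)
  d <- as.matrix(dist(pts))
  max(d)
}

# Convex-hull check by the half-plane ("all points on one side") test:
# every hull edge must support the full point set, every hull vertex must
# be one of the input points, and no three consecutive hull vertices may
# be collinear.
oracle_check_hull <- function(pts, hull) {
  pts <- unique(pts)
  h <- nrow(hull)
  if (h <= 2) return(TRUE)
  key <- function(m) paste(m[, 1], m[, 2])
  if (!all(key(hull) %in% key(pts))) return(FALSE)
  for (i in seq_len(h)) {
    p <- hull[i, ]; q <- hull[if (i == h) 1 else i + 1, ]
    cross <- (q[1] - p[1]) * (pts[, 2] - p[2]) - (q[2] - p[2]) * (pts[, 1] - p[1])
    if (any(cross > 1e-9) && any(cross < -1e-9)) return(FALSE)
  }
  for (i in seq_len(h)) {
    a <- hull[if (i == 1) h else i - 1, ]; b <- hull[i, ]
    c2 <- hull[if (i == h) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (c2[2] - a[2]) - (b[2] - a[2]) * (c2[1] - a[1])
    if (abs(cr) < 1e-9) return(FALSE)
  }
  TRUE
}

# Gaussian class-conditional log posterior evaluated directly from the
# density formula (no shared code with the package's classifier).
oracle_bayes_label <- function(x, means, covs, priors, classes) {
  lp <- vapply(seq_along(classes), function(j) {
    d <- x - means[[j]]
    S <- covs[[j]]
    log(priors[j]) - 0.5 * determinant(S, logarithm = TRUE)$modulus -
      0.5 * t(d) %*% solve(S, d)
  }, numeric(1))
  classes[which.max(lp)]
}

# Rasterisation of an axis-aligned ellipse at pixel centres, independent
# of the package's polygon rasteriser. The semi-axes are grown by half a
# pixel so the pixel-centre outline estimates the nominal ellipse without
# the half-pixel inward bias of a strict centre-inside digitisation.
ellipse_mask <- function(a, b, margin = 4) {
  nr <- 2 * ceiling(b) + 2 * margin + 1
  nc <- 2 * ceiling(a) + 2 * margin + 1
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  binary_mask((((cols - cx) / (a + 0.5))^2 +
               ((rows - cy) / (b + 0.5))^2 < 1) * 1L)
}

random_blob_mask <- function(seed, size = 31) {
  set.seed(seed)
  m <- matrix(0L, size, size)
  cy <- (size + 1) / 2
  a <- runif(1, size / 5, size / 2.6); b <- runif(1, size / 6, a)
  ang <- runif(1, 0, pi)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  x <- (cols - cy) * cos(ang) + (rows - cy) * sin(ang)
  y <- -(cols - cy) * sin(ang) + (rows - cy) * cos(ang)
  binary_mask(((x / a)^2 + (y / b)^2 < 1) * 1L)
}

random_spec <- function() {
  seed_spec(body_semi_major = runif(1, 52, 68),
            body_semi_minor = runif(1, 24, 29),
            tip_length = runif(1, 24, 30),
            tip_width = runif(1, 16.5, 19),
            notch_depth_K = runif(1, 5.2, 6.8),
            notch_depth_L = runif(1, 3.5, 4.7),
            notch_angle = runif(1, 39, 45),
            rotation = runif(1, 0, 360))
}
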