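#' Specification of a synthetic seed silhouette
#'
#' The synthetic silhouette is an ellipse body (the husk outline) with a
#' protruding triangular chaff tip flanked by two wedge-shaped notches —
#' the morphology the key-point features measure. All structural
#' quantities are set in continuous coordinates, so every feature the
#' pipeline extracts has a closed-form ground truth.
#'
#' Construction, in body coordinates (x along the major axis):
#' the tip apex sits at `(a + tip_length, 0)`; the contour leaves the
#' ellipse at shoulder points at parametric angle `notch_angle` above and
#' below the axis; each notch apex lies at exact perpendicular distance
#' `notch_depth_K` / `notch_depth_L` inside the straight hull bridge from
#' its shoulder to the tip apex, positioned so the two apexes are exactly
#' `tip_width` apart.
#'
#' @param body_semi_major,body_semi_minor Ellipse semi-axes in pixels
#'   (major > minor).
#' @param tip_length Protrusion of the tip apex beyond the ellipse end, px.
#' @param tip_width Distance between the two notch apexes (the chaff-tip
#'   width `LK`), px.
#' @param notch_depth_K,notch_depth_L Perpendicular notch depths, px
#'   (upper and lower notch; the extractor labels the deeper one `K`).
#' @param notch_angle Half-angle of the V-shaped notches in degrees (the
#'   notch mouth is `2 * tan(notch_angle) * depth` wide). Sharp notches
#'   (around 40-45) keep the concavity apex well localised on the pixel
#'   grid.
#' @param rotation Rotation of the silhouette in the image plane, degrees.
#' @param center Optional `(row, col)` placement of the body centre.
#' @param rng_seed Provenance tag stored with the spec; the construction
#'   itself is deterministic.
#' @return A list of class `seed_spec`.
#' @export
seed_spec <- function(body_semi_major = 60, body_semi_minor = 26.5,
                      tip_length = 27, tip_width = 17.7,
                      notch_depth_K = 6.0, notch_depth_L = 4.05,
                      notch_angle = 42, rotation = 0,
                      center = NULL, rng_seed = NULL) {
  if (body_semi_major <= body_semi_minor || body_semi_minor <= 0)
    stop("need body_semi_major > body_semi_minor > 0", call. = FALSE)
  if (notch_depth_K < 0 || notch_depth_L < 0)
    stop("notch depths must be >= 0", call. = FALSE)
  if (tip_length >= body_semi_major)
    stop("tip_length must be smaller than body_semi_major", call. = FALSE)
  structure(list(body_semi_major = body_semi_major,
                 body_semi_minor = body_semi_minor,
                 tip_length = tip_length, tip_width = tip_width,
                 notch_depth_K = notch_depth_K, notch_depth_L = notch_depth_L,
                 notch_angle = notch_angle, rotation = rotation,
                 center = center, rng_seed = rng_seed),
            class = "seed_spec")
}

# Continuous polygon (counter-clockwise, y up) plus the analytic ground
# truth implied by the construction.
#
# Body: ellipse with semi-axes (a, b). Chaff tip: apex T = (a + tip_length,
# 0), joined to the ellipse by the two tangent segments from T (the
# flanks). A V-shaped notch of the requested perpendicular depth is cut
# into each flank; its mouth is collinear with the flank, so the
# convex-hull supporting line over the pocket is exactly the tangent line
# and the deficiency maximum is the notch apex at exactly the constructed
# depth. The shared mouth position is solved so the two apexes are
# `tip_width` apart.
seed_polygon <- function(spec, arc_points = 200L) {
  a <- spec$body_semi_major; b <- spec$body_semi_minor
  tl <- spec$tip_length
  no_tip <- tl <= 0 && spec$notch_depth_K <= 0 && spec$notch_depth_L <= 0
  if (no_tip) {
    ang <- seq(0, 2 * pi, length.out = arc_points + 1L)[-(arc_points + 1L)]
    poly <- cbind(x = a * cos(ang), y = b * sin(ang))
    truth <- list(len_AB = 2 * a, len_CD = 2 * b,
                  len_LK = NA_real_, h_c = NA_real_,
                  d_K = NA_real_, d_L = NA_real_, phi = NA_real_)
    return(list(poly = poly, truth = truth))
  }
  if (tl <= 0) stop("a tipped silhouette needs tip_length > 0", call. = FALSE)
  # The flanks joining the husk outline to the tip apex are the tangent
  # segments from the apex to the ellipse, so each flank is a genuine
  # supporting (convex-hull) edge and the perpendicular depth of a notch
  # cut into it is measured against exactly that line. The tangent from
  # (a + tl, 0) touches the ellipse at parametric angle acos(a / (a + tl)).
  theta <- acos(a / (a + tl))
  E1 <- c(a * cos(theta), b * sin(theta))
  E2 <- c(E1[1], -E1[2])
  Tp <- c(a + tl, 0)
  half_angle <- spec$notch_angle * pi / 180
  if (half_angle <= 0 || half_angle >= pi / 2)
    stop("notch_angle (V half-angle) must be in (0, 90) degrees", call. = FALSE)
  d_up <- spec$notch_depth_K; d_lo <- spec$notch_depth_L
  mouth_up <- 2 * tan(half_angle) * d_up
  mouth_lo <- 2 * tan(half_angle) * d_lo
  side <- function(E, depth, mouth) {
    v <- Tp - E
    len <- sqrt(sum(v^2))
    vhat <- v / len
    nvec <- c(-vhat[2], vhat[1])
    if (sum(nvec * (-(E + Tp) / 2)) < 0) nvec <- -nvec  # inward normal
    list(E = E, vhat = vhat, nvec = nvec, len = len, depth = depth,
         mouth = mouth)
  }
  up <- side(E1, d_up, mouth_up)
  lo <- side(E2, d_lo, mouth_lo)
  apex <- function(s, m) s$E + (m + s$mouth / 2) * s$vhat + s$depth * s$nvec
  gap <- function(m) sqrt(sum((apex(up, m) - apex(lo, m))^2)) - spec$tip_width
  m_lo <- 1.5
  m_hi <- min(up$len - up$mouth, lo$len - lo$mouth) - 1.5
  if (m_hi <= m_lo || gap(m_lo) < 0 || gap(m_hi) > 0)
    stop("non-simple polygon from extreme parameters (tip_width infeasible)",
         call. = FALSE)
  m <- stats::uniroot(gap, c(m_lo, m_hi), tol = 1e-10)$root
  N1 <- apex(up, m); N2 <- apex(lo, m)
  if (N1[2] <= 1 || N2[2] >= -1)
    stop("non-simple polygon from extreme parameters (notch crosses the axis)",
         call. = FALSE)
  U1 <- up$E + m * up$vhat;  U2 <- up$E + (m + up$mouth) * up$vhat
  V1 <- lo$E + m * lo$vhat;  V2 <- lo$E + (m + lo$mouth) * lo$vhat
  ang <- seq(theta, 2 * pi - theta, length.out = arc_points)
  arc <- cbind(x = a * cos(ang), y = b * sin(ang))
  # CCW: upper shoulder -> arc over the tail -> lower shoulder -> lower
  # notch -> tip apex -> upper notch -> close
  poly <- rbind(arc, V1, N2, V2, Tp, U2, N1, U1)
  dist_point_line <- function(p, l1, l2) {
    v <- l2 - l1
    abs((p[1] - l1[1]) * v[2] - (p[2] - l1[2]) * v[1]) / sqrt(sum(v^2))
  }
  ang_between <- function(v1, v2) {
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  x_m <- tl / 2   # midpoint of the chord (-a,0) -- (a+tl,0)
  truth <- list(
    len_AB = 2 * a + tl,
    len_CD = 2 * b * sqrt(1 - (x_m / a)^2),
    len_LK = spec$tip_width,
    h_c = dist_point_line(Tp, N1, N2),
    d_K = max(d_up, d_lo),
    d_L = min(d_up, d_lo),
    phi = ang_between(Tp - N1, Tp - N2)
  )
  list(poly = poly, truth = truth)
}

# Offset the smooth and convex vertices of a CCW simple polygon by `r`
# along the outward angle bisector, leaving reflex vertices (the notch
# apexes) in place. Rationale: a boundary pixel on a straight or gently
# curved stretch sits on average half a pixel inside the continuous
# outline, so shifting those stretches out by half a pixel makes the
# traced pixel-centre contour an unbiased estimate of the original
# boundary there. The deepest-pixel estimate of a reflex wedge tip, in
# contrast, is already approximately unbiased — the innermost foreground
# pixel overshoots the deepest background pixel by about as much as that
# pixel stops short of the continuous apex — so reflex vertices are not
# moved.
offset_polygon <- function(poly, r = 0.5) {
  n <- nrow(poly)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n)[-1], 1L)
  e_in <- poly - poly[prv, , drop = FALSE]    # edge arriving at vertex
  e_out <- poly[nxt, , drop = FALSE] - poly   # edge leaving vertex
  norm_of <- function(e) {
    len <- sqrt(rowSums(e^2))
    cbind(e[, 2], -e[, 1]) / len              # outward normal for CCW
  }
  n_in <- norm_of(e_in); n_out <- norm_of(e_out)
  m <- n_in + n_out
  len <- sqrt(rowSums(m^2))
  if (any(len < 1e-9))
    stop("degenerate polygon vertex (reversal spur)", call. = FALSE)
  cross <- e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1]
  shift <- r * m / len
  shift[cross < 0, ] <- 0   # reflex vertices stay put
  poly + shift
}

# Even-odd rasterisation of a polygon at integer pixel centres; vectorised
# over pixels, looping over edges.
rasterize_polygon <- function(px, py, nrow_img, ncol_img) {
  r0 <- max(1L, floor(min(py)) - 1L); r1 <- min(nrow_img, ceiling(max(py)) + 1L)
  c0 <- max(1L, floor(min(px)) - 1L); c1 <- min(ncol_img, ceiling(max(px)) + 1L)
  rows <- r0:r1; cols <- c0:c1
  qy <- rep(rows, times = length(cols))
  qx <- rep(cols, each = length(rows))
  inside <- rep(FALSE, length(qx))
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    yi <- py[i]; yj <- py[j]
    if (yi != yj) {
      cross <- (yi > qy) != (yj > qy)
      if (any(cross)) {
        xint <- px[i] + (qy[cross] - yi) * (px[j] - px[i]) / (yj - yi)
        flip <- qx[cross] < xint
        idx <- which(cross)[flip]
        inside[idx] <- !inside[idx]
      }
    }
    j <- i
  }
  m <- matrix(0L, nrow_img, ncol_img)
  m[cbind(qy[inside], qx[inside])] <- 1L
  m
}

#' Rasterise a synthetic seed silhouette
#'
#' Builds the continuous polygon for a [seed_spec()], rotates and places
#' it, and rasterises it at integer pixel centres (a pixel is foreground
#' when its centre falls inside the polygon).
#'
#' @param spec A [seed_spec()].
#' @param canvas Optional `(nrow, ncol)` canvas size; by default the
#'   canvas is fitted to the silhouette with a 6-pixel margin. Use
#'   `c(480, 640)` for a full capture-frame scene.
#' @param arc_points Number of vertices used to sample the ellipse arc.
#' @return A list with `mask` (a [binary_mask]), `truth` (named list of
#'   ground-truth feature values: `len_AB`, `len_CD`, `len_LK`, `h_c`,
#'   `d_K`, `d_L`, `phi`; tip entries are `NA` for a plain ellipse), and
#'   `spec`.
#' @examples
#' sil <- make_silhouette(seed_spec(notch_depth_K = 8, notch_depth_L = 5))
#' sil$truth$d_K
#' @export
make_silhouette <- function(spec, canvas = NULL, arc_points = 200L) {
  stopifnot(inherits(spec, "seed_spec"))
  sp <- seed_polygon(spec, arc_points)
  rot <- spec$rotation * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  xy <- offset_polygon(sp$poly, 0.5) %*% t(R)
  if (is.null(canvas)) {
    margin <- 6
    w <- diff(range(xy[, 1])); h <- diff(range(xy[, 2]))
    canvas <- c(ceiling(h) + 2 * margin + 1, ceiling(w) + 2 * margin + 1)
    # place the bounding-box centre at the canvas centre
    px <- xy[, 1] - (max(xy[, 1]) + min(xy[, 1])) / 2 + (canvas[2] + 1) / 2
    py <- (max(xy[, 2]) + min(xy[, 2])) / 2 - xy[, 2] + (canvas[1] + 1) / 2
  } else {
    center <- spec$center %||% c((canvas[1] + 1) / 2, (canvas[2] + 1) / 2)
    px <- xy[, 1] + center[2]
    py <- center[1] - xy[, 2]
  }
  if (min(px) < 1.5 || max(px) > canvas[2] - 0.5 ||
      min(py) < 1.5 || max(py) > canvas[1] - 0.5)
    stop("silhouette does not fit the canvas", call. = FALSE)
  mask <- binary_mask(rasterize_polygon(px, py, canvas[1], canvas[2]))
  list(mask = mask, truth = sp$truth, spec = spec)
}

#' Render a silhouette as a two-tone colour image with optional noise
#'
#' Foreground pixels are painted `seed_color`, background `bg_color`;
#' independent Gaussian noise with standard deviation `noise_sd` is added
#' per channel and the result is clipped to `[0, 255]`.
#'
#' @param mask A [binary_mask] (the image shares its dimensions).
#' @param seed_color,bg_color RGB triplets in `[0, 255]`; must differ.
#' @param noise_sd Per-channel Gaussian noise standard deviation.
#' @param rng_seed Optional seed for the noise (the global RNG is left
#'   untouched when given).
#' @return A [color_image].
#' @export
render_image <- function(mask, seed_color = c(139, 90, 43),
                         bg_color = c(46, 64, 148), noise_sd = 0,
                         rng_seed = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (all(seed_color == bg_color)) stop("colors must be distinct", call. = FALSE)
  m <- unclass(mask)
  arr <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) arr[, , ch] <- ifelse(m == 1L, seed_color[ch], bg_color[ch])
  if (noise_sd > 0) {
    noise <- if (is.null(rng_seed)) stats::rnorm(length(arr), 0, noise_sd)
             else with_seed(rng_seed, stats::rnorm(length(arr), 0, noise_sd))
    arr <- arr + noise
  }
  color_image(pmin(pmax(round(arr), 0), 255))
}

#' Define a synthetic seed variety
#'
#' A variety is a population over [seed_spec()] parameters: each sampled
#' seed draws every parameter from an independent normal distribution.
#'
#' @param name Variety label.
#' @param means Named list of parameter means (any subset of the
#'   [seed_spec()] structural parameters; unnamed ones use the
#'   `seed_spec()` defaults).
#' @param sds Named list of parameter standard deviations (default 0 for
#'   parameters not mentioned).
#' @return A list of class `variety_spec`.
#' @export
variety_spec <- function(name, means = list(), sds = list()) {
  if (any(unlist(sds) < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(name = name, means = means, sds = sds),
            class = "variety_spec")
}

#' Three default synthetic varieties
#'
#' Emulates three similar-but-distinct seed populations of increasing
#' kernel size and chaff-tip prominence; their feature-space class means
#' are separated by well over six pooled within-class standard deviations,
#' so a sound classifier should separate them almost perfectly.
#'
#' @return A list of three [variety_spec()] objects.
#' @export
default_varieties <- function() {
  sds <- list(body_semi_major = 0.8, body_semi_minor = 0.5,
              tip_length = 0.5, tip_width = 0.3,
              notch_depth_K = 0.15, notch_depth_L = 0.12,
              notch_angle = 0.5, rotation = 45)
  list(
    variety_spec("V1", list(body_semi_major = 54, body_semi_minor = 24.5,
                            tip_length = 25, tip_width = 17,
                            notch_depth_K = 5.5, notch_depth_L = 3.7,
                            notch_angle = 41, rotation = 0), sds),
    variety_spec("V2", list(body_semi_major = 60, body_semi_minor = 26.5,
                            tip_length = 27, tip_width = 17.7,
                            notch_depth_K = 6.0, notch_depth_L = 4.05,
                            notch_angle = 42, rotation = 0), sds),
    variety_spec("V3", list(body_semi_major = 66, body_semi_minor = 28.5,
                            tip_length = 29, tip_width = 18.4,
                            notch_depth_K = 6.5, notch_depth_L = 4.4,
                            notch_angle = 43, rotation = 0), sds)
  )
}

draw_spec <- function(vs) {
  base <- formals(seed_spec)
  param_names <- c("body_semi_major", "body_semi_minor", "tip_length",
                   "tip_width", "notch_depth_K", "notch_depth_L",
                   "notch_angle", "rotation")
  vals <- lapply(param_names, function(p) {
    mu <- vs$means[[p]] %||% eval(base[[p]])
    sd <- vs$sds[[p]] %||% 0
    stats::rnorm(1, mu, sd)
  })
  names(vals) <- param_names
  do.call(seed_spec, vals)
}

#' Sample labelled feature vectors from synthetic varieties
#'
#' Draws seed silhouettes from each variety's parameter distributions,
#' runs the full geometry and feature pipeline on every rasterised mask,
#' and returns the labelled feature table. Draws whose geometry fails
#' (e.g. no detectable concavities) are resampled; the resample count is
#' attached as attribute `"resampled"`, and a failure rate above 50% is an
#' error.
#'
#' @param varieties A [variety_spec()] or list of them.
#' @param n Seeds per variety.
#' @param rng_seed Seed for the parameter draws.
#' @return A tibble with the [seed_feature_names] columns and `label`.
#' @examples
#' pop <- sample_population(default_varieties()[1:2], n = 3, rng_seed = 1)
#' dplyr::count(pop, label)
#' @export
sample_population <- function(varieties, n, rng_seed = 1L) {
  if (inherits(varieties, "variety_spec")) varieties <- list(varieties)
  stopifnot(n >= 1)
  with_seed(rng_seed, {
    resampled <- 0L
    rows <- vector("list", length(varieties) * n)
    ri <- 0L
    for (vs in varieties) {
      got <- 0L
      while (got < n) {
        feat <- tryCatch({
          spec <- draw_spec(vs)
          sil <- make_silhouette(spec)
          extract_features(build_seed_geometry(sil$mask))
        }, error = function(e) NULL)
        if (is.null(feat)) {
          resampled <- resampled + 1L
          if (resampled > length(varieties) * n)
            stop("degenerate variety spec: failure rate above 50%", call. = FALSE)
          next
        }
        got <- got + 1L; ri <- ri + 1L
        feat$label <- vs$name
        rows[[ri]] <- feat
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "resampled") <- resampled
    out
  })
}
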