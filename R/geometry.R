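#' Geometry configuration
#'
#' @param min_depth Minimum convexity deficiency, in pixels, for a hull
#'   pocket to count as a chaff-tip concavity (suppresses rasterisation
#'   jitter). Default 1.0.
#' @param hull_tol Collinearity tolerance, in pixels, used when grouping
#'   hull vertices into concavity bridges: rasterising a straight outline
#'   stretch produces staircase hull vertices that deviate from the true
#'   supporting line by under a pixel, and would otherwise split one
#'   concavity bridge at arbitrary staircase positions. Vertices whose
#'   removal changes the hull by less than `hull_tol` are absorbed into
#'   their neighbours' edge. Default 1.0.
#' @return A list of class `geom_config`.
#' @export
geom_config <- function(min_depth = 1.0, hull_tol = 1.0) {
  stopifnot(is.numeric(min_depth), min_depth >= 0,
            is.numeric(hull_tol), hull_tol >= 0)
  structure(list(min_depth = min_depth, hull_tol = hull_tol),
            class = "geom_config")
}

row_major_key <- function(pts, width = 1e6) pts[, 1] * width + pts[, 2]

#' Longest chord (diameter) of a contour
#'
#' Finds the pair of contour points at maximal Euclidean distance — the
#' seed's long axis. Squared distances are computed in integer arithmetic,
#' so ties are exact; tied pairs are resolved by the lexicographically
#' smallest `(A, B)` in row-major order with `A <= B`.
#'
#' @param contour A `seed_contour` (or any `n x 2` point matrix) with at
#'   least two distinct points.
#' @return A list with points `A`, `B` (numeric length-2, `(row, col)`) and
#'   `length` (pixels).
#' @export
longest_chord <- function(contour) {
  pts <- unique(unclass(contour)[, 1:2, drop = FALSE])
  if (nrow(pts) < 2L) stop("contour must contain at least two distinct points", call. = FALSE)
  # the diameter is attained at convex-hull vertices; restrict the search
  cand <- pts
  if (nrow(pts) > 3L) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    if (length(h) >= 2L) cand <- pts[h, , drop = FALSE]
  }
  d2 <- outer(cand[, 1], cand[, 1], "-")^2 + outer(cand[, 2], cand[, 2], "-")^2
  best <- max(d2)
  hits <- which(d2 == best, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  ka <- row_major_key(cand[hits[, 1], , drop = FALSE])
  kb <- row_major_key(cand[hits[, 2], , drop = FALSE])
  swap <- ka > kb
  lo <- ifelse(swap, kb, ka); hi <- ifelse(swap, ka, kb)
  pick <- order(lo, hi)[1]
  i <- hits[pick, 1]; j <- hits[pick, 2]
  if (row_major_key(cand[i, , drop = FALSE]) > row_major_key(cand[j, , drop = FALSE])) {
    tmp <- i; i <- j; j <- tmp
  }
  list(A = as.numeric(cand[i, ]), B = as.numeric(cand[j, ]),
       length = sqrt(best))
}

#' Perpendicular chord of the contour polygon
#'
#' Intersects the line through `A + frac * (B - A)`, perpendicular to `AB`,
#' with the closed contour polygon and returns the two intersection points
#' spanning the maximal cut. `frac = 1/2` yields the perpendicular bisector
#' chord `CD`; `frac = 1/5` and `4/5` yield the auxiliary chords `P1P2` and
#' `P3P4`.
#'
#' @param contour A closed `seed_contour`.
#' @param A,B Chord endpoints as `(row, col)`.
#' @param frac Position along `AB` in `(0, 1)`.
#' @return A list with points `Pa`, `Pb` and `length` (pixels).
#' @export
perpendicular_chord <- function(contour, A, B, frac) {
  stopifnot(frac > 0, frac < 1)
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  A <- as.numeric(A); B <- as.numeric(B)
  d <- B - A
  len <- sqrt(sum(d^2))
  if (len == 0) stop("A and B must be distinct", call. = FALSE)
  u <- d / len                       # along AB
  nvec <- c(-u[2], u[1])             # perpendicular
  P0 <- A + frac * d
  rel <- sweep(pts, 2, P0)
  a <- rel %*% u                     # signed offset from the cut line
  b <- rel %*% nvec                  # coordinate along the cut line
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  hits <- numeric(0)
  for (i in seq_len(n)) {
    j <- nxt[i]
    ai <- a[i]; aj <- a[j]
    if (ai == 0) hits <- c(hits, b[i])
    if ((ai < 0 && aj > 0) || (ai > 0 && aj < 0)) {
      t <- ai / (ai - aj)
      hits <- c(hits, b[i] + t * (b[j] - b[i]))
    }
  }
  if (length(hits) < 2L) stop("no intersection with contour", call. = FALSE)
  lo <- min(hits); hi <- max(hits)
  list(Pa = as.numeric(P0 + lo * nvec),
       Pb = as.numeric(P0 + hi * nvec),
       length = hi - lo)
}

#' Convex hull of a contour
#'
#' Hull vertices are returned in contour-traversal order (clockwise in image
#' coordinates), with collinear points excluded.
#'
#' @param contour A `seed_contour`.
#' @return An `h x 2` matrix of hull vertices with attribute
#'   `contour_index` giving each vertex's first position in the contour.
#' @export
convex_hull <- function(contour) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  upts <- unique(pts)
  if (nrow(upts) <= 2L) {
    idx <- match(row_major_key(upts), row_major_key(pts))
    return(structure(upts, contour_index = idx))
  }
  h <- grDevices::chull(upts[, 2], upts[, 1])
  hull_pts <- upts[h, , drop = FALSE]
  # chull() can retain points lying exactly on a hull edge; the contract
  # excludes collinear non-vertices, so drop them until none remain
  repeat {
    k <- nrow(hull_pts)
    if (k <= 3L) break
    prv <- c(k, seq_len(k - 1L)); nxt <- c(seq_len(k)[-1], 1L)
    cross <- (hull_pts[, 1] - hull_pts[prv, 1]) *
               (hull_pts[nxt, 2] - hull_pts[prv, 2]) -
             (hull_pts[, 2] - hull_pts[prv, 2]) *
               (hull_pts[nxt, 1] - hull_pts[prv, 1])
    drop <- which(cross == 0)
    if (length(drop) == 0L) break
    hull_pts <- hull_pts[-drop[1], , drop = FALSE]
  }
  # keep chull's cyclic order (a valid convex polygon), but rotate it to
  # start at the vertex met first along the contour and run it in contour
  # direction, so consecutive hull vertices delimit contour arcs
  idx <- match(row_major_key(hull_pts), row_major_key(pts))
  k <- nrow(hull_pts)
  rot <- ((which.min(idx) - 1L) + seq_len(k) - 1L) %% k + 1L
  s <- idx[rot]
  if (k > 2L && sum(diff(s) > 0) < sum(diff(s) < 0))
    rot <- rot[c(1L, k:2L)]
  structure(hull_pts[rot, , drop = FALSE],
            contour_index = idx[rot],
            dimnames = list(NULL, c("row", "col")))
}

point_segment_distance <- function(pts, s1, s2) {
  v <- s2 - s1
  vv <- sum(v^2)
  rel <- sweep(pts, 2, s1)
  if (vv == 0) return(sqrt(rowSums(rel^2)))
  t <- pmin(pmax((rel %*% v) / vv, 0), 1)
  foot <- cbind(s1[1] + t * v[1], s1[2] + t * v[2])
  sqrt(rowSums((pts - foot)^2))
}

#' Locate the two chaff-tip concavities
#'
#' For every pair of consecutive convex-hull vertices, the maximum
#' perpendicular deficiency of the intervening contour arc from the hull
#' edge is computed; the two deepest pockets are the chaff-tip concavities.
#' `R_K` is the deeper one (`d_K >= d_L`); ties are broken by earlier
#' contour position, as is the choice of apex within an arc.
#'
#' @param contour A `seed_contour`.
#' @param hull Output of [convex_hull()] (computed if omitted).
#' @param cfg A [geom_config()]; pockets shallower than `min_depth` are
#'   ignored.
#' @return A list `list(R_K =, R_L =)` of `concave_region` objects, each
#'   with fields `hull_start`, `hull_end` (bridge endpoints in contour
#'   order), `apex`, `depth`, and `arc` (the arc's point matrix).
#' @export
# Drop hull vertices that deviate from their neighbours' chord by less
# than `tol` (iteratively, shallowest first): these are rasterisation
# staircase artefacts on straight or gently curved outline stretches, and
# keeping them would fragment concavity bridges at arbitrary positions.
simplify_hull_indices <- function(hull, tol) {
  pts <- unclass(hull)[, 1:2, drop = FALSE]
  keep <- seq_len(nrow(pts))
  if (tol <= 0) return(keep)
  repeat {
    k <- length(keep)
    if (k <= 3L) break
    dev <- vapply(seq_len(k), function(i) {
      p <- pts[keep[if (i == 1L) k else i - 1L], ]
      q <- pts[keep[if (i == k) 1L else i + 1L], ]
      point_segment_distance(matrix(pts[keep[i], ], 1), p, q)
    }, numeric(1))
    i_min <- which.min(dev)
    if (dev[i_min] >= tol) break
    keep <- keep[-i_min]
  }
  keep
}

find_concaves <- function(contour, hull = convex_hull(contour),
                          cfg = geom_config()) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  idx <- attr(hull, "contour_index")
  idx <- idx[simplify_hull_indices(hull, cfg$hull_tol)]
  h <- length(idx)
  if (h < 2L) stop("concavities not found", call. = FALSE)
  regions <- list()
  for (k in seq_len(h)) {
    i1 <- idx[k]
    i2 <- if (k < h) idx[k + 1] else idx[1] + n
    if (i2 - i1 < 2L) next
    arc_idx <- ((i1:i2 - 1L) %% n) + 1L
    arc_idx <- arc_idx[-c(1L, length(arc_idx))]
    arc <- pts[arc_idx, , drop = FALSE]
    s1 <- as.numeric(pts[i1, ]); s2 <- as.numeric(pts[((i2 - 1L) %% n) + 1L, ])
    d <- point_segment_distance(arc, s1, s2)
    dmax <- max(d)
    if (dmax <= cfg$min_depth) next
    apex_i <- which.max(d)   # first maximum = earliest arc position
    regions[[length(regions) + 1L]] <- structure(
      list(hull_start = s1, hull_end = s2,
           apex = as.numeric(arc[apex_i, ]),
           depth = dmax, arc = arc, start_index = i1),
      class = "concave_region")
  }
  if (length(regions) < 2L) stop("concavities not found", call. = FALSE)
  depths <- vapply(regions, `[[`, numeric(1), "depth")
  starts <- vapply(regions, `[[`, numeric(1), "start_index")
  ord <- order(-depths, starts)
  list(R_K = regions[[ord[1]]], R_L = regions[[ord[2]]])
}

#' Depth of a concave region
#'
#' The maximum perpendicular distance from the region's contour arc to the
#' hull bridge `hull_start`–`hull_end`; equals the stored `depth`.
#'
#' @param r A `concave_region`.
#' @return Depth in pixels.
#' @export
concave_depth <- function(r) {
  stopifnot(inherits(r, "concave_region"))
  max(point_segment_distance(r$arc, r$hull_start, r$hull_end))
}

signed_line_distance <- function(pts, p1, p2) {
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  rel <- sweep(pts, 2, p1)
  (rel[, 1] * v[2] - rel[, 2] * v[1]) / len
}

#' Chaff-tip width and height
#'
#' The chaff-tip width is the distance between the two concavity apexes
#' `L` and `K`; the height is the maximum perpendicular distance from the
#' tip arc to the line `LK`, where the tip arc is the contour arc between
#' the apexes lying on the opposite side of `LK` from the silhouette
#' centroid.
#'
#' @param contour A `seed_contour`.
#' @param r_k,r_l The two `concave_region`s from [find_concaves()].
#' @return A list with `LK_len` and `h_c` (pixels).
#' @export
chaff_tip_metrics <- function(contour, r_k, r_l) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  K <- r_k$apex; L <- r_l$apex
  if (all(K == L)) stop("concavity apexes coincide", call. = FALSE)
  LK_len <- sqrt(sum((K - L)^2))
  centroid <- colMeans(pts)
  n <- nrow(pts)
  iK <- which(pts[, 1] == K[1] & pts[, 2] == K[2])[1]
  iL <- which(pts[, 1] == L[1] & pts[, 2] == L[2])[1]
  lo <- min(iK, iL); hi <- max(iK, iL)
  arc1 <- pts[seq(lo, hi), , drop = FALSE]
  arc2 <- pts[c(seq(hi, n), seq(1L, lo)), , drop = FALSE]
  s_c <- signed_line_distance(matrix(centroid, 1), L, K)[1]
  opp <- function(arc) {
    s <- signed_line_distance(arc, L, K)
    if (s_c >= 0) max(-s) else max(s)
  }
  h1 <- opp(arc1); h2 <- opp(arc2)
  list(LK_len = LK_len, h_c = max(0, max(h1, h2)))
}

#' Interior angle of the chaff tip
#'
#' The angle, in degrees and folded into `[0, 180]`, between the direction
#' vectors `K_d - K` and `L_d - L` (apex towards the tip-side bridge
#' endpoint of each concavity).
#'
#' @param r_k,r_l `concave_region`s whose `hull_end` fields hold `K_d` and
#'   `L_d` (see [build_seed_geometry()], which orients them tipward).
#' @return Angle in degrees.
#' @export
interior_angle <- function(r_k, r_l) {
  v1 <- r_k$hull_end - r_k$apex
  v2 <- r_l$hull_end - r_l$apex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length direction vector", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

orient_region_tipward <- function(r, tip) {
  d_start <- sum((r$hull_start - tip)^2)
  d_end <- sum((r$hull_end - tip)^2)
  if (d_start < d_end) {
    tmp <- r$hull_start; r$hull_start <- r$hull_end; r$hull_end <- tmp
  }
  r
}

#' Full key-point geometry of a seed silhouette
#'
#' Runs the whole shape-analysis chain on a single-seed mask: contour
#' tracing, longest chord `AB` with midpoint `O`, the perpendicular bisector
#' chord `CD` and the auxiliary perpendicular chords `P1P2` (1/5 of `AB`)
#' and `P3P4` (4/5), the convex hull, the two chaff-tip concavities with
#' depths `d_K >= d_L`, the chaff-tip width `LK` and height `h_c`, and the
#' interior angle `phi`. `A` is oriented to the chaff-tip end of the chord
#' (the endpoint nearer the midpoint of the two concavity apexes), and each
#' concavity's `hull_end` (`K_d`, `L_d`) is the bridge endpoint nearer the
#' tip.
#'
#' @param m A [binary_mask] containing one seed.
#' @param cfg A [geom_config()].
#' @return A `seed_geometry` list with named points (`A`, `B`, `O`, `C`,
#'   `D`, `P1`–`P4`), scalars (`len_AB`, `len_CD`, `CO_half`, `DO_half`,
#'   `len_LK`, `h_c`, `d_K`, `d_L`, `phi`), the hull, the two
#'   `concave_region`s, and the traced contour.
#' @examples
#' sil <- make_silhouette(seed_spec(rng_seed = 7))
#' g <- build_seed_geometry(sil$mask)
#' extract_features(g)
#' @export
build_seed_geometry <- function(m, cfg = geom_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("geometry stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  contour <- stage("trace_contour", trace_contour(m))
  chord <- stage("longest_chord", longest_chord(contour))
  hull <- stage("convex_hull", convex_hull(contour))
  conc <- stage("find_concaves", find_concaves(contour, hull, cfg))
  apex_mid <- (conc$R_K$apex + conc$R_L$apex) / 2
  A <- chord$A; B <- chord$B
  if (sum((B - apex_mid)^2) < sum((A - apex_mid)^2)) { tmp <- A; A <- B; B <- tmp }
  conc$R_K <- orient_region_tipward(conc$R_K, A)
  conc$R_L <- orient_region_tipward(conc$R_L, A)
  cd <- stage("perpendicular_chord", perpendicular_chord(contour, A, B, 1 / 2))
  p12 <- stage("perpendicular_chord", perpendicular_chord(contour, A, B, 1 / 5))
  p34 <- stage("perpendicular_chord", perpendicular_chord(contour, A, B, 4 / 5))
  tip <- stage("chaff_tip_metrics", chaff_tip_metrics(contour, conc$R_K, conc$R_L))
  phi <- stage("interior_angle", interior_angle(conc$R_K, conc$R_L))
  O <- (A + B) / 2
  structure(list(
    A = A, B = B, O = O,
    C = cd$Pa, D = cd$Pb,
    P1 = p12$Pa, P2 = p12$Pb, P3 = p34$Pa, P4 = p34$Pb,
    len_AB = chord$length, len_CD = cd$length,
    len_P1P2 = p12$length, len_P3P4 = p34$length,
    CO_half = sqrt(sum((cd$Pa - O)^2)), DO_half = sqrt(sum((cd$Pb - O)^2)),
    len_LK = tip$LK_len, h_c = tip$h_c,
    d_K = conc$R_K$depth, d_L = conc$R_L$depth, phi = phi,
    hull = hull, R_K = conc$R_K, R_L = conc$R_L,
    contour = contour
  ), class = "seed_geometry")
}

#' @export
print.seed_geometry <- function(x, ...) {
  cat("<seed_geometry>\n",
      sprintf("  AB %.2f px, CD %.2f px, LK %.2f px, h_c %.2f px\n",
              x$len_AB, x$len_CD, x$len_LK, x$h_c),
      sprintf("  d_K %.2f px, d_L %.2f px, phi %.1f deg\n",
              x$d_K, x$d_L, x$phi), sep = "")
  invisible(x)
}

#' Export a seed geometry as JSON
#'
#' Writes the named key points and scalar features (not the full contour)
#' for external audit.
#'
#' @param g A `seed_geometry`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(g, path) {
  stopifnot(inherits(g, "seed_geometry"))
  keep <- c("A", "B", "O", "C", "D", "P1", "P2", "P3", "P4",
            "len_AB", "len_CD", "len_P1P2", "len_P3P4", "CO_half", "DO_half",
            "len_LK", "h_c", "d_K", "d_L", "phi")
  jsonlite::write_json(g[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
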