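test_that("longest chord matches hand values and the all-pairs oracle", {
  two <- structure(rbind(c(0, 0), c(3, 4)), class = c("seed_contour", "matrix"))
  lc <- longest_chord(two)
  expect_equal(lc$length, 5)

  ell <- trace_contour(ellipse_mask(60, 25))
  lc_ell <- longest_chord(ell)
  expect_lt(abs(lc_ell$length - 120), 1)
  expect_equal(lc_ell$length, oracle_longest_chord(unclass(ell)))

  circ <- trace_contour(ellipse_mask(40, 39.99))
  lc_c <- longest_chord(circ)
  expect_lt(abs(lc_c$length - 80), 1)
  expect_equal(lc_c$length, oracle_longest_chord(unclass(circ)))

  single <- structure(rbind(c(2, 2)), class = c("seed_contour", "matrix"))
  expect_error(longest_chord(single), "two distinct points")
})

test_that("longest chord ties break lexicographically in row-major order", {
  # a unit square: all four sides tie at sqrt(2) diagonals; the smallest
  # (A, B) pair in row-major order is (1,1)-(2,2)
  sq <- structure(rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1)),
                  class = c("seed_contour", "matrix"))
  lc <- longest_chord(sq)
  expect_equal(lc$A, c(1, 1))
  expect_equal(lc$B, c(2, 2))
})

test_that("perpendicular chords of a digitized ellipse match the analytic widths", {
  ell <- trace_contour(ellipse_mask(60, 25))
  lc <- longest_chord(ell)
  cd <- perpendicular_chord(ell, lc$A, lc$B, 1 / 2)
  expect_lt(abs(cd$length - 50), 1)
  p12 <- perpendicular_chord(ell, lc$A, lc$B, 1 / 5)
  expect_lt(abs(p12$length - 2 * 25 * 0.8), 1)

  circ <- trace_contour(ellipse_mask(40, 39.99))
  lcc <- longest_chord(circ)
  dd <- perpendicular_chord(circ, lcc$A, lcc$B, 1 / 2)
  expect_lt(abs(dd$length - 80), 1)
})

test_that("convex hull excludes collinear points and satisfies half-plane checks", {
  sq <- structure(rbind(c(0, 0), c(0, 5), c(0, 10), c(5, 10), c(10, 10),
                        c(10, 5), c(10, 0), c(5, 0)),
                  class = c("seed_contour", "matrix"))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4L)
  expect_setequal(h[, 1] * 100 + h[, 2], c(0, 10, 1010, 1000))

  set.seed(33)
  for (i in 1:10) {
    pts <- matrix(sample(0:40, 100, replace = TRUE), ncol = 2)
    ct <- structure(pts, class = c("seed_contour", "matrix"))
    h <- convex_hull(ct)
    expect_true(oracle_check_hull(pts, unclass(h)))
  }

  line <- structure(cbind(1:5, 2 * (1:5)), class = c("seed_contour", "matrix"))
  expect_equal(nrow(convex_hull(line)), 2L)
})

test_that("hull vertices follow contour traversal order", {
  m <- random_blob_mask(5)
  ct <- trace_contour(m)
  h <- convex_hull(ct)
  idx <- attr(h, "contour_index")
  expect_true(all(diff(idx) > 0))
})

test_that("concavity detection finds constructed notches and rejects convex shapes", {
  expect_error(find_concaves(trace_contour(ellipse_mask(30, 14))),
               "concavities not found")

  sil <- make_silhouette(seed_spec(notch_depth_K = 6.5, notch_depth_L = 4,
                                   rng_seed = 1))
  ct <- trace_contour(sil$mask)
  conc <- find_concaves(ct)
  expect_lt(abs(conc$R_K$depth - 6.5), 1)
  expect_lt(abs(conc$R_L$depth - 4), 1)
  expect_gte(conc$R_K$depth, conc$R_L$depth)
})

test_that("concave depth equals the brute-force max over arc points", {
  set.seed(9)
  for (i in 1:6) {
    sil <- make_silhouette(random_spec())
    conc <- find_concaves(trace_contour(sil$mask))
    for (r in conc) {
      d_brute <- max(apply(r$arc, 1, function(p) {
        v <- r$hull_end - r$hull_start
        t <- sum((p - r$hull_start) * v) / sum(v^2)
        t <- min(max(t, 0), 1)
        sqrt(sum((p - (r$hull_start + t * v))^2))
      }))
      expect_equal(concave_depth(r), d_brute)
      expect_equal(r$depth, d_brute)
    }
  }
})

test_that("chaff-tip metrics use apex distance and the arc opposite the centroid", {
  r1 <- structure(list(apex = c(0, 0)), class = "concave_region")
  r2 <- structure(list(apex = c(6, 8)), class = "concave_region")
  fake <- structure(rbind(c(0, 0), c(3, 4), c(6, 8)),
                    class = c("seed_contour", "matrix"))
  out <- chaff_tip_metrics(fake, r1, r2)
  expect_equal(out$LK_len, 10)
  expect_equal(out$h_c, 0)   # all contour points collinear with LK
  expect_error(chaff_tip_metrics(fake, r1, r1), "coincide")
})

test_that("interior angle folds into [0, 180] for canonical vectors", {
  mk <- function(apex, endp) structure(list(apex = apex, hull_end = endp),
                                       class = "concave_region")
  expect_equal(interior_angle(mk(c(0, 0), c(1, 0)), mk(c(0, 0), c(0, 1))), 90)
  expect_equal(interior_angle(mk(c(0, 0), c(1, 0)), mk(c(0, 0), c(-1, 0))), 180)
  expect_equal(interior_angle(mk(c(0, 0), c(1, 0)), mk(c(0, 0), c(1, 1))), 45)
  expect_error(interior_angle(mk(c(0, 0), c(0, 0)), mk(c(0, 0), c(1, 0))),
               "zero-length")
})

test_that("full geometry recovers generator ground truth on a known seed", {
  sil <- make_silhouette(seed_spec(rng_seed = 4))
  g <- build_seed_geometry(sil$mask)
  tr <- sil$truth
  expect_lt(abs(g$d_K - tr$d_K), 1)
  expect_lt(abs(g$d_L - tr$d_L), 1)
  expect_lt(abs(g$len_LK - tr$len_LK), 1.2)
  expect_lt(abs(g$h_c - tr$h_c), 1.5)
  expect_lt(abs(g$phi - tr$phi), 2.5)
  expect_lt(abs(g$len_AB - tr$len_AB), 1.2)
  expect_lt(abs(g$len_CD - tr$len_CD), 1.2)
  expect_lte(g$len_CD, g$len_AB)
  expect_equal(g$O, (g$A + g$B) / 2)
})

test_that("geometry fails cleanly on a plain ellipse", {
  expect_error(build_seed_geometry(ellipse_mask(50, 22)),
               "find_concaves.*concavities not found")
})

test_that("geometric features are invariant to 90-degree rotation and translation", {
  sil <- make_silhouette(seed_spec(rng_seed = 8))
  g0 <- build_seed_geometry(sil$mask)
  m90 <- binary_mask(t(unclass(sil$mask))[seq_len(ncol(sil$mask)), rev(seq_len(nrow(sil$mask)))])
  g90 <- build_seed_geometry(m90)
  for (f in c("len_AB", "len_CD", "len_LK", "h_c", "d_K", "d_L")) {
    expect_lt(abs(g0[[f]] - g90[[f]]), 0.5)
  }
  expect_lt(abs(g0$phi - g90$phi), 1)

  pad <- matrix(0L, nrow(sil$mask) + 9, ncol(sil$mask) + 13)
  pad[5 + seq_len(nrow(sil$mask)), 7 + seq_len(ncol(sil$mask))] <- unclass(sil$mask)
  gt <- build_seed_geometry(binary_mask(pad))
  for (f in c("len_AB", "len_CD", "len_LK", "h_c", "d_K", "d_L", "phi")) {
    expect_equal(g0[[f]], gt[[f]])
  }
})

test_that("scaling the silhouette scales lengths and preserves the angle", {
  base <- list(body_semi_major = 56, body_semi_minor = 25, tip_length = 25,
               tip_width = 17.5, notch_depth_K = 6, notch_depth_L = 4,
               notch_angle = 42, rotation = 17)
  s <- 1.25
  scaled <- base
  for (f in c("body_semi_major", "body_semi_minor", "tip_length",
              "tip_width", "notch_depth_K", "notch_depth_L"))
    scaled[[f]] <- base[[f]] * s
  g1 <- build_seed_geometry(make_silhouette(do.call(seed_spec, base))$mask)
  g2 <- build_seed_geometry(make_silhouette(do.call(seed_spec, scaled))$mask)
  # both sides carry independent rasterisation error of up to ~0.75 px,
  # so the comparison tolerance is the sum of the two
  for (f in c("len_AB", "len_CD", "len_LK", "d_K", "d_L")) {
    expect_lt(abs(g2[[f]] - s * g1[[f]]), 1.75)
  }
  expect_lt(abs(g2$phi - g1$phi), 2.5)
})
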