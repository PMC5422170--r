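make_img <- function(r, g, b) {
  color_image(array(c(r, g, b), dim = c(dim(r), 3)))
}

test_that("band extraction copies red and converts hue as documented", {
  px <- function(r, g, b) make_img(matrix(r), matrix(g), matrix(b))
  expect_equal(extract_red_band(px(255, 0, 0))[1, 1], 255L)
  expect_equal(extract_red_band(px(10, 200, 30))[1, 1], 10L)
  expect_equal(extract_hue_band(px(0, 255, 0))[1, 1], 85L)     # 120 deg
  expect_equal(extract_hue_band(px(128, 128, 128))[1, 1], 0L)  # achromatic
  expect_equal(extract_hue_band(px(255, 0, 0))[1, 1], 0L)      # 0 deg
  dark <- make_img(matrix(0, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3))
  expect_true(all(extract_red_band(dark) == 0L))
})

test_that("box smoothing averages a 3x3 neighbourhood with edge replication", {
  const <- gray_image(matrix(7L, 4, 5))
  expect_equal(unclass(smooth_image(const)), unclass(const))
  m <- matrix(0L, 5, 5); m[3, 3] <- 9L
  sm <- smooth_image(gray_image(m))
  expect_equal(sm[3, 3], 1L)
  expect_equal(sm[1, 1], 0L)
  one <- gray_image(matrix(42L, 1, 1))
  expect_equal(smooth_image(one)[1, 1], 42L)
})

test_that("otsu threshold matches the exhaustive between-class-variance search", {
  half <- gray_image(matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10))
  t <- otsu_threshold(half)
  expect_gte(t, 10); expect_lt(t, 200)
  expect_equal(t, oracle_otsu(as.vector(unclass(half))))

  two <- gray_image(matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4))
  expect_equal(otsu_threshold(two), oracle_otsu(as.vector(unclass(two))))

  expect_error(otsu_threshold(gray_image(matrix(5L, 3, 3))), "degenerate histogram")

  set.seed(101)
  for (i in 1:20) {
    v <- sample(0:255, 64, replace = TRUE)
    img <- gray_image(matrix(v, 8, 8))
    expect_equal(otsu_threshold(img), oracle_otsu(v))
  }
})

test_that("binarize respects threshold and polarity", {
  g <- gray_image(matrix(200L))
  expect_equal(binarize(g, 127, "bright")[1, 1], 1L)
  expect_equal(binarize(g, 127, "dark")[1, 1], 0L)
  any_img <- gray_image(matrix(sample(0:255, 25), 5, 5))
  expect_true(all(binarize(any_img, 255, "bright") == 0L))
})

test_that("mask_or is an OR with the expected algebraic properties", {
  set.seed(7)
  a <- binary_mask(matrix(rbinom(36, 1, 0.4), 6, 6))
  b <- binary_mask(matrix(rbinom(36, 1, 0.4), 6, 6))
  c3 <- binary_mask(matrix(rbinom(36, 1, 0.4), 6, 6))
  zero <- binary_mask(matrix(0L, 6, 6))
  expect_equal(unclass(mask_or(zero, b)), unclass(b))
  expect_equal(unclass(mask_or(a, a)), unclass(a))
  expect_equal(unclass(mask_or(a, b)), unclass(mask_or(b, a)))
  expect_equal(unclass(mask_or(mask_or(a, b), c3)),
               unclass(mask_or(a, mask_or(b, c3))))
  disj_a <- binary_mask(rbind(c(1L, 0L), c(0L, 0L)))
  disj_b <- binary_mask(rbind(c(0L, 0L), c(0L, 1L)))
  expect_equal(sum(mask_or(disj_a, disj_b)), 2L)
  expect_error(mask_or(a, binary_mask(matrix(0L, 2, 2))), "dimension mismatch")
})

test_that("fill_holes fills border-unreachable background and is idempotent", {
  ring <- matrix(0L, 7, 7)
  ring[2:6, 2] <- 1L; ring[2:6, 6] <- 1L; ring[2, 2:6] <- 1L; ring[6, 2:6] <- 1L
  filled <- fill_holes(binary_mask(ring))
  expect_equal(sum(filled), 25L)
  solid <- binary_mask(matrix(1L, 4, 4))
  expect_equal(unclass(fill_holes(solid)), unclass(solid))
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rbinom(15 * 15, 1, 0.55), 15, 15)
    got <- fill_holes(binary_mask(m))
    expect_equal(unclass(got), unclass(oracle_fill_holes(m)))
    expect_equal(unclass(fill_holes(got)), unclass(got))
    expect_true(all(got >= m))
  }
})

test_that("largest_component keeps the biggest 8-connected blob", {
  m <- matrix(0L, 8, 8)
  m[2:6, 2:4] <- 1L        # 15 px blob
  m[7, 7] <- 1L; m[8, 8] <- 1L  # 2 px diagonal blob (8-connected)
  out <- largest_component(binary_mask(m))
  expect_equal(sum(out), 15L)
  one <- binary_mask(m * 0L + { z <- m * 0L; z[3, 3] <- 1L; z })
  expect_equal(unclass(largest_component(one)), unclass(one))
  expect_error(largest_component(binary_mask(matrix(0L, 3, 3))), "no foreground")
  # diagonal chain counts as one component
  d <- matrix(0L, 5, 5); d[1, 1] <- 1L; d[2, 2] <- 1L; d[3, 3] <- 1L
  d[5, 5] <- 0L
  expect_equal(sum(largest_component(binary_mask(d))), 3L)
})

test_that("mask_apply blanks background and keeps foreground", {
  arr <- array(sample(0:255, 2 * 3 * 3, replace = TRUE), dim = c(2, 3, 3))
  img <- color_image(arr)
  ones <- binary_mask(matrix(1L, 2, 3))
  expect_equal(unclass(mask_apply(img, ones)), unclass(img))
  zeros <- binary_mask(matrix(0L, 2, 3))
  expect_true(all(mask_apply(img, zeros) == 0L))
  k <- binary_mask(rbind(c(1L, 0L, 0L), c(0L, 0L, 1L)))
  out <- mask_apply(img, k)
  expect_equal(sum(rowSums(apply(unclass(out), c(1, 2), sum) > 0)), 2)
})

test_that("segment_seed recovers a rendered silhouette and propagates errors", {
  sil <- make_silhouette(seed_spec(rotation = 30, rng_seed = 1))
  img0 <- render_image(sil$mask, noise_sd = 0)
  seg <- segment_seed(img0, seg_config(smooth_ksize = 1))
  expect_equal(mask_iou(seg$mask, sil$mask), 1.0)

  img5 <- render_image(sil$mask, noise_sd = 5, rng_seed = 2)
  seg5 <- segment_seed(img5)
  expect_gte(mask_iou(seg5$mask, sil$mask), 0.98)

  flat <- color_image(array(60L, dim = c(20, 20, 3)))
  expect_error(segment_seed(flat), "degenerate histogram")
})

test_that("segmentation config files round-trip through YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("smooth_ksize: 5", "red_polarity: dark"), y)
  cfg <- read_seg_config(y)
  expect_equal(cfg$smooth_ksize, 5L)
  expect_equal(cfg$red_polarity, "dark")
  expect_equal(cfg$hue_polarity, "auto")

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"component": "all"}', j)
  expect_equal(read_seg_config(j)$component, "all")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("kernel: 3", bad)
  expect_error(read_seg_config(bad), "unknown segmentation config")
})

test_that("segmentation polarity auto-detection tolerates swapped colours", {
  sil <- make_silhouette(seed_spec(rng_seed = 5))
  img_a <- render_image(sil$mask, seed_color = c(139, 90, 43),
                        bg_color = c(46, 64, 148), noise_sd = 0)
  img_b <- render_image(sil$mask, seed_color = c(46, 64, 148),
                        bg_color = c(139, 90, 43), noise_sd = 0)
  cfg <- seg_config(smooth_ksize = 1)
  expect_equal(unclass(segment_seed(img_a, cfg)$mask),
               unclass(segment_seed(img_b, cfg)$mask))
})
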