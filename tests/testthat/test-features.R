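solid_image <- function(n, rgb) {
  array(rep(rgb, each = n * n), dim = c(n, n, 3))
}

test_that("mean colour features match closed forms", {
  m <- matrix(TRUE, 10, 10)
  red <- mean_color(solid_image(10, c(1, 0, 0)), m)
  expect_equal(unname(red[1:3]), c(1, 0, 0))
  expect_equal(unname(red[c("f5_mean_s", "f6_mean_v")]), c(1, 1))
  expect_equal(unname(red["f4_mean_h"]), 0)
  gray <- mean_color(solid_image(10, c(0.5, 0.5, 0.5)), m)
  expect_equal(unname(gray["f5_mean_s"]), 0)
  # two-tone half red / half blue
  img <- solid_image(10, c(1, 0, 0))
  img[, 6:10, 1] <- 0; img[, 6:10, 3] <- 1
  two <- mean_color(img, m)
  expect_equal(unname(two[1:3]), c(0.5, 0, 0.5))
  expect_error(mean_color(img, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("colour-structure entropy hits its closed-form extremes", {
  m <- matrix(TRUE, 16, 16)
  expect_equal(color_structure(solid_image(16, c(0.8, 0.2, 0.2)), m), 0)
  # 1x1 windows tiled with all 32 quantized colours in equal coverage -> 1
  hues <- (0:7 + 0.5) / 8
  combos <- expand.grid(h = hues, s = c(0.25, 0.75), v = c(0.25, 0.75))
  img32 <- array(0, dim = c(4, 8, 3))
  k <- 0
  for (i in 1:4) for (j in 1:8) {
    k <- k + 1
    img32[i, j, ] <- grDevices::col2rgb(grDevices::hsv(
      combos$h[k], combos$s[k], combos$v[k])) / 255
  }
  val <- color_structure(img32, matrix(TRUE, 4, 8), window_size = 1L)
  expect_equal(val, 1, tolerance = 1e-10)
})

test_that("colour structure matches a direct window-enumeration oracle", {
  set.seed(19)
  for (rep in 1:3) {
    n <- 14L
    img <- solid_image(n, c(0.9, 0.3, 0.2))
    patch <- matrix(runif(n * n) < 0.4, n, n)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[patch] <- c(0.2, 0.4, 0.8)[ch]
      img[, , ch] <- plane
    }
    mask <- disc_mask(n, 6, center = c(7.5, 7.5))
    got <- color_structure(img, mask, window_size = 4L)
    # oracle: enumerate every 4x4 window inside the bounding box
    bb <- which(mask, arr.ind = TRUE)
    r0 <- min(bb[, 1]); r1 <- max(bb[, 1])
    c0 <- min(bb[, 2]); c1 <- max(bb[, 2])
    idx <- which(mask, arr.ind = TRUE)
    rgb <- cbind(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
    hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
    bins <- lesionclass:::quantize_hsv32(hsv)
    binmap <- matrix(NA_integer_, n, n)
    binmap[idx] <- bins
    counts <- numeric(32)
    for (i in r0:(r1 - 3)) {
      for (j in c0:(c1 - 3)) {
        present <- unique(stats::na.omit(as.integer(binmap[i:(i + 3), j:(j + 3)])))
        counts[present] <- counts[present] + 1
      }
    }
    p <- counts[counts > 0] / sum(counts)
    expect_equal(got, -sum(p * log(p)) / log(32), tolerance = 1e-12)
  }
})

test_that("colour layout follows the DCT definition", {
  m <- matrix(TRUE, 16, 16)
  uni <- color_layout(solid_image(16, c(0.4, 0.5, 0.6)), m)
  expect_equal(unname(uni), c(0.5, 0.5)) # zero AC energy at the zero point
  # left-right gradient excites the horizontal coefficient
  img <- solid_image(16, c(0, 0, 0))
  for (ch in 1:3) img[, , ch] <- matrix(seq(0, 1, length.out = 16),
                                        16, 16, byrow = TRUE)
  gr <- color_layout(img, m)
  expect_gt(abs(gr[1] - 0.5), abs(gr[2] - 0.5))
  # seeded random ROI equals the definitional DCT oracle
  set.seed(23)
  img2 <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  got <- color_layout(img2, m)
  grid <- array(0, dim = c(8, 8, 3))
  for (ch in 1:3) {
    grid[, , ch] <- lesionclass:::block_mean_grid(img2[, , ch], 8L)
  }
  C <- oracle_dct2(to_gray(grid))
  expect_equal(unname(got), pmin(1, pmax(0, (c(C[1, 2], C[2, 1]) + 4) / 8)),
               tolerance = 1e-12)
})

test_that("shape features recover closed-form geometries", {
  disc <- disc_mask(61L, 20)
  sf <- shape_features(disc)
  expect_equal(unname(sf["f10_pc_ratio"]), 1, tolerance = 0.02)
  expect_gte(sf["f11_filled_ellipse"], 0.98)
  expect_lte(sf["f12_unfilled_ellipse"], 0.02)
  ell <- ellipse_mask_fixture(61L, a = 24, b = 12)
  expect_equal(unname(shape_features(ell)["f10_pc_ratio"]), 0.5,
               tolerance = 0.02)
  # collinear mask is degenerate
  line <- matrix(FALSE, 20, 20); line[10, 3:17] <- TRUE
  expect_error(shape_features(line), "degenerate")
})

test_that("plus-sign shape fractions match per-pixel membership counting", {
  plus <- matrix(FALSE, 41, 41)
  plus[16:26, 6:36] <- TRUE
  plus[6:36, 16:26] <- TRUE
  got <- shape_features(plus)
  # independent oracle: moments -> analytic ellipse -> exhaustive counting
  idx <- which(plus, arr.ind = TRUE)
  mu <- colMeans(idx)
  S <- crossprod(sweep(idx, 2, mu)) / nrow(idx)
  ev <- eigen(S, symmetric = TRUE)
  a <- sqrt(nrow(idx) / pi / sqrt(ev$values[2] / ev$values[1]))
  b <- nrow(idx) / pi / a
  inside <- matrix(FALSE, 41, 41)
  for (r in 1:41) for (c in 1:41) {
    u <- sum((c(r, c) - mu) * ev$vectors[, 1])
    v <- sum((c(r, c) - mu) * ev$vectors[, 2])
    inside[r, c] <- (u / a)^2 + (v / b)^2 <= 1
  }
  expect_equal(unname(got["f11_filled_ellipse"]),
               sum(plus & inside) / sum(inside), tolerance = 1e-12)
  expect_equal(unname(got["f12_unfilled_ellipse"]),
               sum(plus & !inside) / sum(plus), tolerance = 1e-12)
})

test_that("the full descriptor is finite, 12-long, and background-invariant", {
  pair <- tiny_case_pair(seed = 6L)
  for (cs in pair) {
    fv <- extract_features(cs$image, cs$truth_mask)
    expect_length(fv, 12L)
    expect_identical(names(fv), feature_names())
    expect_true(all(is.finite(fv)))
  }
  # colour features ignore pixels outside the mask
  cs <- pair$benign
  img2 <- cs$image
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[!cs$truth_mask] <- 0.1 * ch
    img2[, , ch] <- plane
  }
  f_orig <- extract_features(cs$image, cs$truth_mask)
  f_bg <- extract_features(img2, cs$truth_mask)
  expect_equal(f_orig, f_bg)
})

test_that("raising border irregularity does not improve ellipse coverage", {
  vals <- vapply(c(0.25, 0.45, 0.65), function(irr) {
    cs <- generate_case(synth_params("malignant", border_irregularity = irr,
                                     seed = 13L))
    shape_features(cs$truth_mask)["f11_filled_ellipse"]
  }, numeric(1))
  expect_true(all(diff(vals) <= 0.02)) # non-increasing up to raster jitter
})

test_that("min-max normalization follows the clamp rules", {
  X <- cbind(c(2, 4, 6), c(1, 1, 1), c(0, 5, 10))
  X12 <- cbind(X, matrix(rep(c(0, 1, 2), 9), 3, 9))
  p <- fit_normalizer(X12)
  n <- apply_normalizer(X12, p)
  expect_equal(unname(n[, 1]), c(0, 0.5, 1))
  expect_equal(unname(n[, 2]), c(0.5, 0.5, 0.5)) # constant column
  expect_equal(unname(apply_normalizer(c(-5, 1, 3, rep(1, 9)), p)[1]), 0)
  # fitting on the normalized matrix is idempotent
  p2 <- fit_normalizer(n)
  expect_equal(apply_normalizer(n, p2), n)
  expect_error(apply_normalizer(1:5, p), "expected 12")
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_normalizer(p, path)
  p3 <- read_normalizer(path)
  expect_equal(p3$min, unname(p$min))
  expect_equal(p3$max, unname(p$max))
})

test_that("feature tables round-trip as CSV", {
  pair <- tiny_case_pair(seed = 9L)
  tab <- feature_table(pair, use_truth_mask = TRUE)
  expect_identical(colnames(tab), c(feature_names(), "label"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  tab2 <- read_feature_table(path)
  expect_equal(tab2, tab, tolerance = 1e-12)
})
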