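test_that("gray conversion is luminance-weighted and normalized", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_gray(px(1, 1, 1))[1, 1], 1)
  expect_equal(to_gray(px(0, 0, 0))[1, 1], 0)
  expect_equal(to_gray(px(0.5, 0.5, 0.5))[1, 1], 0.5)
  expect_error(to_gray(matrix(0.5, 3, 3)), "RGB")
})

test_that("median filter matches the zero-padded sorted-9 definition", {
  const <- matrix(0.8, 6, 6)
  out <- median_filter3(const)
  expect_equal(out[3, 3], 0.8)
  # corner neighbourhood holds 5 padded zeros: median is 0
  expect_equal(out[1, 1], 0)
  # impulse removal
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_true(all(median_filter3(imp) == 0))
  # idempotent on the interior of piecewise-constant images
  out2 <- median_filter3(out)
  expect_equal(out2[3:4, 3:4], out[3:4, 3:4])
})

test_that("contrast stretching maps the range onto [0,1] preserving order", {
  set.seed(31)
  img <- matrix(runif(100, 0.2, 0.6), 10, 10)
  out <- stretch_contrast(img)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_identical(order(img), order(out))
  const <- matrix(0.4, 5, 5)
  expect_identical(stretch_contrast(const), const)
})

test_that("region growing matches a flood-fill oracle and its edge cases", {
  cfg <- segmentation_config(similarity_threshold = 0.2)
  # uniform image: everything joins
  uni <- matrix(0.5, 8, 8)
  expect_true(all(region_grow(uni, cbind(3L, 3L), cfg)))
  # threshold 0 with a one-pixel flat zone
  img <- matrix(seq(0, 1, length.out = 25), 5, 5)
  m <- region_grow(img, cbind(2L, 2L), segmentation_config(0))
  expect_identical(sum(m), 1L)
  expect_true(m[3, 3])
  # two-intensity disc recovered exactly
  disc <- disc_mask(31L, 10)
  img2 <- matrix(0.9, 31, 31); img2[disc] <- 0.3
  m2 <- region_grow(img2, cbind(15L, 15L), cfg)
  expect_identical(m2, disc)
  # random seeded images against the plain-R oracle, both connectivities
  set.seed(77)
  for (i in 1:5) {
    img3 <- matrix(sample(seq(0, 1, 0.25), 81, TRUE), 9, 9)
    seeds <- cbind(sample(0:8, 2L), sample(0:8, 2L))
    for (conn in c(4L, 8L)) {
      c3 <- segmentation_config(0.25, connectivity = conn)
      expect_identical(region_grow(img3, seeds, c3),
                       oracle_region_grow(img3, seeds, 0.25, conn))
    }
  }
})

test_that("region growing is invariant to seed order and validates seeds", {
  set.seed(5)
  img <- matrix(runif(64), 8, 8)
  seeds <- cbind(c(1L, 6L, 3L), c(2L, 7L, 3L))
  cfg <- segmentation_config(0.3)
  expect_identical(region_grow(img, seeds, cfg),
                   region_grow(img, seeds[3:1, ], cfg))
  expect_error(region_grow(img, cbind(9L, 1L), cfg), "bounds")
  expect_error(region_grow(img, seeds[0, , drop = FALSE], cfg), "seed")
})

test_that("mask refinement fills holes and removes small objects", {
  disc <- disc_mask(41L, 14)
  holey <- disc; holey[21, 21] <- FALSE
  cfg <- segmentation_config(opening_radius = 1L, min_object_size = 0L)
  expect_true(refine_mask(holey, cfg)[21, 21])
  # solid disc unchanged beyond a thin boundary band
  ref <- refine_mask(disc, segmentation_config(opening_radius = 2L,
                                               min_object_size = 0L))
  band <- disc_mask(41L, 17) & !disc_mask(41L, 11)
  expect_true(all(ref[!band] == disc[!band]))
  # small components dropped by the size threshold
  two <- disc_mask(41L, 12)
  two[1:2, 1:2] <- TRUE # 4-pixel speck
  out <- refine_mask(two, segmentation_config(opening_radius = 0L,
                                              min_object_size = 10L))
  expect_false(any(out[1:2, 1:2]))
  expect_true(all(out[disc_mask(41L, 12)]))
  # removing every seeded component is an error
  speck <- matrix(FALSE, 20, 20); speck[5, 5] <- TRUE
  expect_error(refine_mask(speck, segmentation_config(opening_radius = 0L,
                                                      min_object_size = 10L),
                           seeds = cbind(4L, 4L)),
               "seed")
})

test_that("segmentation recovers synthetic lesions with high overlap", {
  for (seed in c(2L, 12L, 22L)) {
    pair <- tiny_case_pair(seed = seed)
    for (cs in pair) {
      seg <- segment_lesion(cs$image, cs$poi)
      expect_gte(jaccard(seg$mask, cs$truth_mask), 0.8)
    }
  }
})

test_that("segmentation artifacts round-trip to disk", {
  dir <- withr::local_tempdir()
  cs <- tiny_case_pair(seed = 8L)$benign
  seg <- segment_lesion(cs$image, cs$poi)
  write_mask(seg$mask, file.path(dir, "m.png"))
  expect_identical(read_mask(file.path(dir, "m.png")), seg$mask)
  rep_path <- write_segmentation_report(seg, file.path(dir, "r.json"))
  rep <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
  expect_equal(rep$mask_area, seg$area)
})
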