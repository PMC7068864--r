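make_base <- function(n = 20L, d = 6L, seed = 61L) {
  set.seed(seed)
  base <- case_base("embedding")
  M <- matrix(rnorm(n * d), n, d)
  labels <- rep(c("benign", "malignant"), length.out = n)
  for (i in seq_len(n)) {
    base <- add_case(base, case_record(sprintf("c%03d", i),
                                       embedding = M[i, ],
                                       label = labels[i],
                                       recommendation_text = paste("rec", i)))
  }
  list(base = base, M = M, labels = labels)
}

test_that("case bases enforce dimension and id consistency", {
  b <- make_base()
  expect_error(add_case(b$base, case_record("x", embedding = rnorm(3),
                                            label = "benign")),
               "dimension")
  expect_error(add_case(b$base, case_record("c001", embedding = rnorm(6),
                                            label = "benign")),
               "duplicate")
  expect_error(retrieve(case_base(), rnorm(6)), "empty")
  expect_error(retrieve(b$base, rnorm(4)), "dimension")
})

test_that("retrieval is exact nearest-neighbour search with stable ties", {
  b <- make_base()
  # query equal to a stored embedding ranks it first at distance zero
  r <- retrieve(b$base, b$M[7, ], k = 3L)
  expect_identical(r$case_ids[1], "c007")
  expect_equal(r$distances[1], 0)
  # k = base size returns the whole base sorted
  rall <- retrieve(b$base, rnorm(6), k = 20L)
  expect_identical(length(rall$case_ids), 20L)
  expect_true(!is.unsorted(rall$distances))
  # brute-force ranking oracle over seeded queries
  set.seed(62)
  for (q in 1:10) {
    query <- rnorm(6)
    r <- retrieve(b$base, query, k = 5L)
    d <- sqrt(colSums((t(b$M) - query)^2))
    ids <- sprintf("c%03d", seq_len(nrow(b$M)))
    expect_identical(r$case_ids, ids[order(d, ids)][1:5])
    maj <- table(factor(b$labels[order(d, ids)][1:5],
                        levels = c("benign", "malignant")))
    expected <- if (maj[1] == maj[2]) b$labels[order(d, ids)][1]
    else names(maj)[which.max(maj)]
    expect_identical(r$predicted_label, expected)
  }
})

test_that("case bases round-trip through the JSON + CSV persistence", {
  b <- make_base(n = 12L)
  dir <- withr::local_tempdir()
  save_case_base(b$base, dir)
  b2 <- load_case_base(dir)
  query <- rnorm(6)
  r1 <- retrieve(b$base, query, k = 12L)
  r2 <- retrieve(b2, query, k = 12L)
  expect_identical(r1$case_ids, r2$case_ids)
  expect_identical(r1$distances, r2$distances)
  expect_identical(vapply(b2$records, `[[`, "", "recommendation_text"),
                   vapply(b$base$records, `[[`, "", "recommendation_text"))
})

test_that("the end-to-end pipeline classifies a benign case and reports errors", {
  presets <- list(benign = synth_params("benign"),
                  malignant = synth_params("malignant"))
  train <- generate_dataset(10L, presets, seed = 63L)
  tab <- feature_table(train, use_truth_mask = TRUE)
  knn <- lesion_knn(as.matrix(tab[, 1:12]), tab$label, k = 3L)
  cs <- generate_case(synth_params("benign", seed = 4321L))
  rep1 <- classify_image(cs$image, poi = cs$poi, classifier = knn)
  expect_identical(rep1$classical$label, "benign")
  # identical inputs give identical reports
  rep2 <- classify_image(cs$image, poi = cs$poi, classifier = knn)
  expect_identical(rep1, rep2)
  # missing POI is an explicit error
  expect_error(classify_image(cs$image, classifier = knn), "POI")
  expect_error(classify_image(cs$image), "nothing to classify")
})

test_that("feature-representation bases retrieve the right class", {
  presets <- list(benign = synth_params("benign"),
                  malignant = synth_params("malignant"))
  train <- generate_dataset(8L, presets, seed = 64L)
  base <- build_case_base(train, representation = "features")
  cs <- generate_case(synth_params("malignant", seed = 65L))
  seg <- segment_lesion(cs$image, cs$poi)
  r <- retrieve(base, extract_features(cs$image, seg$mask), k = 3L)
  expect_identical(r$predicted_label, "malignant")
})
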