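test_that("reference conv2d matches the brute-force summation oracle", {
  set.seed(41)
  for (rep in 1:20) {
    h <- sample(3:8, 1); w <- sample(3:8, 1)
    k <- sample(c(1L, 3L, 5L), 1)
    B <- matrix(rnorm(h * w), h, w)
    K <- matrix(rnorm(k * k), k, k)
    expect_equal(conv2d(B, K, flip = FALSE), oracle_cross_correlation(B, K),
                 tolerance = 1e-12)
  }
  # identity and annihilator kernels
  B <- matrix(rnorm(20), 4, 5)
  expect_equal(conv2d(B, matrix(1, 1, 1)), B)
  expect_equal(conv2d(B, matrix(0, 3, 3)), matrix(0, 4, 5))
  expect_error(conv2d(B, matrix(numeric(0), 0, 0)), "empty kernel")
})

test_that("convolution equals cross-correlation with the kernel rotated 180 degrees", {
  set.seed(42)
  for (rep in 1:10) {
    B <- matrix(rnorm(35), 5, 7)
    K <- matrix(rnorm(9), 3, 3)
    Krot <- K[3:1, 3:1]
    expect_equal(conv2d(B, K, flip = TRUE), conv2d(B, Krot, flip = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("the fast convolution kernel agrees with the reference operator", {
  set.seed(43)
  x <- array(rnorm(6 * 7 * 2 * 3), dim = c(6, 7, 2, 3))
  wgt <- array(rnorm(3 * 3 * 2 * 4), dim = c(3, 3, 2, 4))
  bias <- rnorm(4)
  y <- lesionclass:::cpp_conv_forward(x, wgt, bias)
  for (s in 1:3) {
    for (co in 1:4) {
      ref <- bias[co] + conv2d(x[, , 1, s], wgt[, , 1, co], flip = FALSE) +
        conv2d(x[, , 2, s], wgt[, , 2, co], flip = FALSE)
      expect_equal(y[, , co, s], ref, tolerance = 1e-12)
    }
  }
})

test_that("max pooling matches enumeration and keeps 25% of even planes", {
  expect_equal(maxpool(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(4, 1, 1))
  const <- matrix(0.7, 6, 6)
  expect_equal(maxpool(const), matrix(0.7, 3, 3))
  set.seed(44)
  for (rep in 1:10) {
    h <- 2L * sample(2:6, 1); w <- 2L * sample(2:6, 1)
    m <- matrix(rnorm(h * w), h, w)
    got <- maxpool(m)
    expect_equal(got, oracle_maxpool(m), tolerance = 1e-12)
    expect_identical(length(got), length(m) %/% 4L)
  }
  # floor semantics on odd trailing rows/cols
  odd <- matrix(seq_len(35), 5, 7)
  expect_equal(maxpool(odd), oracle_maxpool(odd))
})

test_that("relu, softmax and the multinomial loss follow their definitions", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(2), 2)
  expect_equal(relu(-4, leaky_slope = 0.1), -0.4)
  expect_equal(softmax(c(1, 1)), c(0.5, 0.5))
  z <- matrix(rnorm(12), 4, 3)
  p <- softmax(z)
  expect_equal(rowSums(p), rep(1, 4))
  expect_identical(apply(p, 1, which.max), apply(z, 1, which.max))
  # perfect prediction floor
  perfect <- diag(2)[c(1, 2, 2, 1), ]
  expect_equal(multinomial_log_loss(perfect, c(0, 1, 1, 0)), 0)
  # definitional oracle on a seeded batch
  set.seed(45)
  p4 <- softmax(matrix(rnorm(8), 4, 2))
  l4 <- c(0L, 1L, 0L, 1L)
  expect_equal(multinomial_log_loss(p4, l4),
               -(log(p4[1, 1]) + log(p4[2, 2]) + log(p4[3, 1]) +
                   log(p4[4, 2])) / 4)
  expect_error(multinomial_log_loss(p4, c(0L, 1L, 2L, 0L)), "label")
})

test_that("the default sixteen-layer build matches the architecture recipe", {
  spec <- build_depict_net()
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_identical(sum(kinds == "conv"), 13L)
  expect_identical(sum(kinds == "fc"), 3L)
  expect_identical(sum(kinds %in% c("conv", "fc")), 16L)
  expect_identical(sum(kinds == "maxpool"), 5L)
  convs <- spec$layers[kinds == "conv"]
  expect_true(all(vapply(convs, `[[`, 1L, "kernel") == 3L))
  expect_true(all(vapply(convs, `[[`, 1L, "stride") == 1L))
  expect_true(all(vapply(convs, function(l) isTRUE(l$zero_padding),
                         logical(1))))
  expect_true(all(vapply(convs, `[[`, 1, "bias_filler") == 0.2))
  expect_identical(vapply(convs, `[[`, 1L, "out_channels"),
                   c(64L, 64L, 128L, 128L, rep(256L, 3), rep(512L, 6)))
  fcs <- spec$layers[kinds == "fc"]
  expect_identical(vapply(fcs, `[[`, 1L, "out_channels"),
                   c(4096L, 4096L, 2L))
  expect_identical(vapply(fcs, `[[`, 1, "weight_sd"), c(0.005, 0.005, 0.01))
  expect_identical(vapply(fcs, `[[`, 1, "bias_filler"), c(1, 1, 0))
  expect_error(build_depict_net(input_shape = c(100L, 100L, 3L)),
               "divisible by 32")
})

test_that("symbolic shape propagation follows the halving/doubling schedule", {
  spec <- build_depict_net(input_shape = c(64L, 64L, 3L), K = 2L)
  sh <- network_shapes(spec)
  pools <- sh[sh$kind == "maxpool", ]
  expect_equal(pools$out_h, c(32, 16, 8, 4, 2))
  expect_equal(pools$out_c, c(64, 128, 256, 512, 512))
  last <- sh[nrow(sh), ]
  expect_equal(last$out_c, 2)
  expect_equal(last$out_h * last$out_w, 1)
})

test_that("network specs serialize to JSON and back", {
  spec <- build_depict_net(input_shape = c(64L, 64L, 3L), width_mult = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_spec(spec, path)
  spec2 <- read_network_spec(path)
  expect_equal(network_shapes(spec2), network_shapes(spec))
  expect_identical(length(spec2$layers), length(spec$layers))
})

tiny_train <- function(n_per_class = 4L, epochs = 1L, size = 32L,
                       width_mult = 0.125, seed = 21L) {
  presets <- list(
    benign = synth_params("benign", image_size = c(size, size)),
    malignant = synth_params("malignant", image_size = c(size, size)))
  cases <- generate_dataset(n_per_class, presets, seed = seed)
  d <- cases_to_tensor(cases, size)
  spec <- build_depict_net(input_shape = c(size, size, 3L),
                           width_mult = width_mult)
  net <- train_depict_net(spec, d$images, d$labels,
                          train_config(epochs = epochs, seed = seed))
  list(net = net, data = d, spec = spec)
}

test_that("training runs, returns finite losses, and descends on separable data", {
  r <- tiny_train(n_per_class = 2L, epochs = 1L)
  expect_true(all(is.finite(r$net$history)))
  r2 <- tiny_train(n_per_class = 8L, epochs = 6L)
  expect_lt(mean(tail(r2$net$history, 2)), r2$net$history[1])
  expect_error(train_depict_net(r$spec, r$data$images,
                                rep(0L, length(r$data$labels)),
                                train_config(epochs = 1L)),
               "two classes")
})

test_that("embeddings are deterministic and sized by the FC7 width", {
  r <- tiny_train(n_per_class = 2L, epochs = 1L)
  img <- r$data$images[, , , 1, drop = TRUE]
  e1 <- embed(r$net, img)
  e2 <- embed(r$net, img)
  expect_identical(e1, e2)
  expect_length(e1, round(4096 * 0.125))
  expect_error(embed(r$spec, img), "trained")
  # full default spec embeds at 4096
  full <- build_depict_net()
  fcs <- Filter(function(l) l$kind == "fc", full$layers)
  expect_identical(fcs[[2]]$out_channels, 4096L)
})

test_that("the trained forward pass is reproduced by the reference operators", {
  r <- tiny_train(n_per_class = 2L, epochs = 1L)
  img <- r$data$images[, , , 3, drop = TRUE]
  got_emb <- embed(r$net, img)
  got_prob <- predict(r$net, img, type = "prob")[1, ]
  # recompute layer by layer with conv2d / maxpool / relu / softmax
  params <- r$net$params
  cur <- (img * 255)
  cur <- array(cur, dim = c(dim(img)[1:2], 3L))
  flat <- NULL
  for (ly in r$spec$layers) {
    if (ly$kind == "conv") {
      W <- params[[ly$name]]$W; b <- params[[ly$name]]$b
      nxt <- array(0, dim = c(dim(cur)[1:2], dim(W)[4]))
      for (co in seq_len(dim(W)[4])) {
        acc <- matrix(b[co], dim(cur)[1], dim(cur)[2])
        for (ci in seq_len(dim(W)[3])) {
          acc <- acc + conv2d(cur[, , ci], W[, , ci, co], flip = FALSE)
        }
        nxt[, , co] <- acc
      }
      cur <- nxt
    } else if (ly$kind == "relu") {
      if (is.null(flat)) cur <- relu(cur) else flat <- relu(flat)
    } else if (ly$kind == "maxpool") {
      nxt <- NULL
      for (co in seq_len(dim(cur)[3])) {
        p <- maxpool(cur[, , co])
        if (is.null(nxt)) nxt <- array(0, dim = c(dim(p), dim(cur)[3]))
        nxt[, , co] <- p
      }
      cur <- nxt
    } else if (ly$kind == "fc") {
      if (is.null(flat)) flat <- as.numeric(cur)
      flat <- as.numeric(params[[ly$name]]$W %*% flat + params[[ly$name]]$b)
      if (ly$name == "fc7") ref_emb_pre <- flat
    } else if (ly$kind == "softmax") {
      flat <- softmax(flat)
    }
  }
  expect_equal(got_emb, relu(ref_emb_pre), tolerance = 1e-8)
  expect_equal(unname(got_prob), flat, tolerance = 1e-8)
})

test_that("HDF5 bundles round-trip images and labels", {
  r <- tiny_train(n_per_class = 2L, epochs = 1L)
  path <- withr::local_tempfile(fileext = ".h5")
  write_h5_bundle(r$data$images, r$data$labels, path)
  back <- read_h5_bundle(path)
  expect_equal(back$images, r$data$images, tolerance = 1e-7)
  expect_identical(back$labels, r$data$labels)
})

test_that("augmentation transforms preserve bounds and invert correctly", {
  cs <- tiny_case_pair(seed = 14L)$malignant
  img <- cs$image
  expect_identical(rotate90(img, 4L), img)
  expect_identical(rotate90(rotate90(img, 1L), 3L), img)
  expect_identical(flip_image(flip_image(img)), img)
  expect_identical(flip_image(flip_image(img, FALSE), FALSE), img)
  small <- rescale_image(img, c(32L, 32L))
  expect_identical(dim(small), c(32L, 32L, 3L))
  expect_true(all(small >= 0 & small <= 1))
  crop <- crop_image(img, 8L, 8L, 48L, 48L)
  expect_identical(dim(crop), c(48L, 48L, 3L))
  tr <- translate_image(img, dr = 3L, dc = -2L, fill = 0)
  expect_identical(dim(tr), dim(img))
  expect_equal(tr[10, 10, 1], img[7, 12, 1])
})
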