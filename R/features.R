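# Twelve-dimensional colour/shape descriptor of a segmented lesion.
#
# Feature order is fixed:
#   f1-f3  mean R, G, B over the ROI
#   f4-f6  mean H, S, V over the ROI (hue averaged circularly)
#   f7     colour-structure scalar: normalized entropy of the MPEG-7-style
#          structure histogram (8x8 sliding window, 32-bin HSV quantization)
#   f8-f9  colour-layout pair: first two non-DC zigzag coefficients of the
#          2-D DCT of the 8x8 mean-luminance grid of the ROI bounding box,
#          squashed to [0,1] by a fixed affine map
#   f10    principal-component ratio sqrt(minor/major covariance eigenvalue)
#   f11    filled-fitted-ellipse coverage |ROI & E| / |E|
#   f12    unfilled-fitted-ellipse escape |ROI \ E| / |ROI|
# where E is the moment-matched ellipse (same area as the ROI, axes from the
# second central moments).

FEATURE_NAMES <- c("f1_mean_r", "f2_mean_g", "f3_mean_b",
                   "f4_mean_h", "f5_mean_s", "f6_mean_v",
                   "f7_color_structure",
                   "f8_color_layout_ac1", "f9_color_layout_ac2",
                   "f10_pc_ratio", "f11_filled_ellipse",
                   "f12_unfilled_ellipse")

#' Fixed column names of the 12-feature descriptor
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() FEATURE_NAMES

assert_roi <- function(image, mask) {
  assert_rgb(image)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  invisible(NULL)
}

roi_hsv <- function(image, mask) {
  idx <- which(mask)
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  list(rgb = rgb, hsv = hsv)
}

#' Mean colour features (f1-f6)
#'
#' Channel means over the ROI in RGB and HSV. Hue is an angle, so it is
#' averaged as a vector mean on the unit circle; a degenerate (zero-length)
#' hue resultant yields hue 0.
#'
#' @param image RGB array in `[0, 1]`.
#' @param mask logical ROI mask.
#' @return Named numeric vector `f1..f6`.
#' @export
mean_color <- function(image, mask) {
  assert_roi(image, mask)
  x <- roi_hsv(image, mask)
  ang <- 2 * pi * x$hsv[, 1]
  s <- mean(sin(ang)); c <- mean(cos(ang))
  hue <- if (sqrt(s^2 + c^2) < 1e-12) 0 else (atan2(s, c) / (2 * pi)) %% 1
  out <- c(colMeans(x$rgb), hue, mean(x$hsv[, 2]), mean(x$hsv[, 3]))
  names(out) <- FEATURE_NAMES[1:6]
  out
}

# 32-bin HSV quantization: 8 hue x 2 saturation x 2 value bins (1..32).
quantize_hsv32 <- function(hsv) {
  hbin <- pmin(7L, as.integer(floor(hsv[, 1] * 8)))
  sbin <- as.integer(hsv[, 2] >= 0.5)
  vbin <- as.integer(hsv[, 3] >= 0.5)
  hbin + 8L * sbin + 16L * vbin + 1L
}

#' Colour-structure scalar (f7)
#'
#' Slides an 8x8 window (stride 1) over the ROI bounding box and counts, per
#' quantized colour (fixed 32-bin HSV quantization), the number of windows
#' containing at least one ROI pixel of that colour. The feature is the
#' entropy of that structure histogram normalized by `log(32)`, so a
#' single-colour ROI scores 0 and a maximally even structure scores 1.
#' Windows smaller than 8x8 are used when the bounding box itself is smaller.
#'
#' @inheritParams mean_color
#' @param window_size sliding-window side length (default 8).
#' @return Scalar in `[0, 1]`.
#' @export
color_structure <- function(image, mask, window_size = 8L) {
  assert_roi(image, mask)
  bb <- which(mask, arr.ind = TRUE)
  r0 <- min(bb[, 1]); r1 <- max(bb[, 1])
  c0 <- min(bb[, 2]); c1 <- max(bb[, 2])
  bh <- r1 - r0 + 1L; bw <- c1 - c0 + 1L
  wy <- min(window_size, bh); wx <- min(window_size, bw)

  sub_mask <- mask[r0:r1, c0:c1, drop = FALSE]
  idx <- which(sub_mask)
  rgb <- cbind(image[r0:r1, c0:c1, 1][idx],
               image[r0:r1, c0:c1, 2][idx],
               image[r0:r1, c0:c1, 3][idx])
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  bins <- quantize_hsv32(hsv)

  counts <- numeric(32L)
  for (b in unique(bins)) {
    ind <- matrix(0, bh, bw)
    ind[idx[bins == b]] <- 1
    # windows containing >= 1 pixel of colour b, via a summed-area table
    cs <- matrix(apply(ind, 2L, cumsum), bh, bw)
    if (bw > 1L) for (j in 2:bw) cs[, j] <- cs[, j - 1L] + cs[, j]
    sat <- rbind(0, cbind(0, cs))
    ny <- bh - wy + 1L; nx <- bw - wx + 1L
    i <- seq_len(ny); j <- seq_len(nx)
    tot <- sat[i + wy, j + wx, drop = FALSE] -
      sat[i, j + wx, drop = FALSE] -
      sat[i + wy, j, drop = FALSE] + sat[i, j, drop = FALSE]
    counts[b] <- sum(tot > 0)
  }
  p <- counts[counts > 0]
  p <- p / sum(p)
  ent <- -sum(p * log(p))
  ent / log(32)
}

# Orthonormal DCT-II matrix of order n.
dct_matrix <- function(n) {
  T <- matrix(0, n, n)
  for (u in 0:(n - 1)) {
    cu <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    T[u + 1, ] <- cu * cos(pi * (2 * (0:(n - 1)) + 1) * u / (2 * n))
  }
  T
}

# Block-average a matrix onto an n x n grid.
block_mean_grid <- function(m, n = 8L) {
  gi <- pmin(n, as.integer(floor((seq_len(nrow(m)) - 0.5) * n / nrow(m))) + 1L)
  gj <- pmin(n, as.integer(floor((seq_len(ncol(m)) - 0.5) * n / ncol(m))) + 1L)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    tj <- gj[j]
    num[, tj] <- num[, tj] + vapply(split(m[, j], gi), sum, numeric(1))
    den[, tj] <- den[, tj] + vapply(split(rep(1, nrow(m)), gi), sum, numeric(1))
  }
  num / den
}

#' Colour-layout pair (f8, f9)
#'
#' The ROI bounding box is reduced to an 8x8 grid of mean colours (pixels
#' inside the box but outside the ROI are replaced by the ROI's mean colour
#' first, so the descriptor only sees the lesion); the grid's luminance is
#' transformed by an orthonormal 2-D DCT and the first two non-DC
#' coefficients in zigzag order (horizontal AC(0,1), then vertical AC(1,0))
#' are squashed to `[0, 1]` by the fixed affine map `(coef + 4) / 8`
#' (zero point 0.5), clamped.
#'
#' @inheritParams mean_color
#' @return Named numeric vector `(f8, f9)`.
#' @export
color_layout <- function(image, mask) {
  assert_roi(image, mask)
  bb <- which(mask, arr.ind = TRUE)
  r0 <- min(bb[, 1]); r1 <- max(bb[, 1])
  c0 <- min(bb[, 2]); c1 <- max(bb[, 2])
  if ((r1 - r0 + 1L) < 8L || (c1 - c0 + 1L) < 8L) {
    stop("ROI bounding box smaller than 8 x 8", call. = FALSE)
  }
  grid <- array(0, dim = c(8L, 8L, 3L))
  sub_mask <- mask[r0:r1, c0:c1]
  for (ch in 1:3) {
    plane <- image[r0:r1, c0:c1, ch]
    plane[!sub_mask] <- mean(plane[sub_mask])
    grid[, , ch] <- block_mean_grid(plane, 8L)
  }
  lum <- to_gray(grid)
  T <- dct_matrix(8L)
  C <- T %*% lum %*% t(T)
  out <- clip01((c(C[1, 2], C[2, 1]) + 4) / 8)
  names(out) <- FEATURE_NAMES[8:9]
  out
}

# Moment-matched ellipse of a mask: centroid, orthonormal axes, semi-axes
# scaled so the ellipse area equals the mask area.
fit_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 5L) stop("mask too small for an ellipse fit", call. = FALSE)
  mu <- colMeans(idx)
  d <- sweep(idx, 2L, mu)
  S <- crossprod(d) / n
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= 1e-9) {
    stop("degenerate (collinear) mask: ellipse fit undefined", call. = FALSE)
  }
  ratio <- sqrt(ev$values[2] / ev$values[1])
  a <- sqrt(n / pi / ratio)   # major semi-axis
  b <- sqrt(n / pi * ratio)   # minor semi-axis
  list(center = mu, axes = ev$vectors, a = a, b = b, ratio = ratio, area = n)
}

ellipse_mask <- function(fit, dims) {
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2]) - fit$center[1]
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) -
    fit$center[2]
  u <- rows * fit$axes[1, 1] + cols * fit$axes[2, 1]
  v <- rows * fit$axes[1, 2] + cols * fit$axes[2, 2]
  (u / fit$a)^2 + (v / fit$b)^2 <= 1
}

#' Shape features (f10-f12)
#'
#' Fits an ellipse to the ROI from its second central moments (axes from the
#' covariance eigenvectors, scaled to the same area as the ROI) and returns:
#' `f10` the principal-component ratio `sqrt(minor/major eigenvalue)` (1 for
#' a circle, towards 0 for elongated shapes); `f11` the fraction of the
#' fitted ellipse covered by the ROI; `f12` the fraction of ROI pixels
#' escaping the ellipse. Compact near-elliptical lesions score `f11 -> 1`,
#' `f12 -> 0`; irregular borders lower `f11` and raise `f12`.
#'
#' @param mask logical ROI mask with at least 5 pixels.
#' @return Named numeric vector `(f10, f11, f12)`.
#' @export
shape_features <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  fit <- fit_ellipse(mask)
  emask <- ellipse_mask(fit, dim(mask))
  f11 <- sum(mask & emask) / max(1L, sum(emask))
  f12 <- sum(mask & !emask) / sum(mask)
  out <- c(fit$ratio, f11, f12)
  names(out) <- FEATURE_NAMES[10:12]
  out
}

#' Extract the full 12-feature descriptor
#'
#' Composition of [mean_color()], [color_structure()], [color_layout()] and
#' [shape_features()], in the fixed feature order.
#'
#' @inheritParams mean_color
#' @return Named numeric vector of length 12 (unnormalized).
#' @export
extract_features <- function(image, mask) {
  out <- c(mean_color(image, mask),
           f7_color_structure = unname(color_structure(image, mask)),
           color_layout(image, mask),
           shape_features(mask))
  names(out) <- FEATURE_NAMES
  out
}

#' Fit a min-max feature normalizer
#'
#' Learns per-feature minima and maxima from a training feature matrix so
#' training columns map onto `[0, 1]`.
#'
#' @param feature_matrix numeric matrix (rows = cases, 12 columns) with at
#'   least 2 rows.
#' @return An object of class `normalization_params`.
#' @export
fit_normalizer <- function(feature_matrix) {
  feature_matrix <- as.matrix(feature_matrix)
  stopifnot(nrow(feature_matrix) >= 2L)
  structure(list(min = apply(feature_matrix, 2L, min),
                 max = apply(feature_matrix, 2L, max)),
            class = "normalization_params")
}

#' Apply a min-max normalizer
#'
#' Maps each feature affinely so the training range becomes `[0, 1]`; values
#' outside the training range are clamped, and features constant in training
#' map to 0.5.
#'
#' @param x numeric vector (length 12) or matrix (12 columns).
#' @param params a `normalization_params` object.
#' @return Normalized vector or matrix in `[0, 1]`.
#' @export
apply_normalizer <- function(x, params) {
  stopifnot(inherits(params, "normalization_params"))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(m) != length(params$min)) {
    stop(sprintf("expected %d features, got %d", length(params$min), ncol(m)),
         call. = FALSE)
  }
  rng <- params$max - params$min
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- if (rng[j] <= .Machine$double.eps) 0.5
    else clip01((m[, j] - params$min[j]) / rng[j])
  }
  if (vec) { v <- out[1, ]; names(v) <- colnames(x) %||% names(x); v }
  else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / restore normalizer parameters as JSON
#'
#' @param params a `normalization_params` object.
#' @param path JSON file path.
#' @export
write_normalizer <- function(params, path) {
  jsonlite::write_json(list(min = params$min, max = params$max), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = as.numeric(x$min), max = as.numeric(x$max)),
            class = "normalization_params")
}

#' Build a labelled feature table from synthetic cases
#'
#' Segments each case from its POIs (or uses the ground-truth mask when
#' `use_truth_mask = TRUE`), extracts the 12-feature descriptor, and stacks
#' the rows into a data frame with a trailing `label` column.
#'
#' @param cases list of `synthetic_case` objects.
#' @param config [segmentation_config()] used when segmenting.
#' @param use_truth_mask bypass segmentation and use the generator's mask.
#' @return Data frame with the 12 feature columns plus `label`.
#' @export
feature_table <- function(cases, config = segmentation_config(),
                          use_truth_mask = FALSE) {
  rows <- lapply(cases, function(cs) {
    mask <- if (use_truth_mask) cs$truth_mask
    else segment_lesion(cs$image, cs$poi, config)$mask
    extract_features(cs$image, mask)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out$label <- unname(vapply(cases, function(cs) cs$label, character(1)))
  out
}

#' Read / write labelled feature tables as CSV
#'
#' The fixed 12-column header ([feature_names()]) plus a `label` column.
#'
#' @param table data frame as produced by [feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(identical(colnames(table)[1:12], FEATURE_NAMES))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(colnames(out)[1:12], FEATURE_NAMES)) {
    stop("not a 12-feature table: unexpected header", call. = FALSE)
  }
  out
}
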