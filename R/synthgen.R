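# Synthetic dermoscopy-like image generator.
#
# Lesions are star-shaped regions around a centre: the boundary radius is an
# ellipse radius modulated by smooth periodic noise,
#   r(theta) = r_ellipse(theta) * (1 + irregularity * eta(theta)),
# rasterized by the radial inequality, which keeps every mask connected and
# hole-free. Colour heterogeneity is a seeded Voronoi partition of the lesion
# interior. Benign presets are near-elliptical and single-coloured; malignant
# presets have irregular borders and several luminance-matched colour patches
# (heterogeneous in hue, similar in gray value, so gray-based region growing
# still recovers the whole lesion).

#' Parameters for the synthetic lesion generator
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param image_size integer `(h, w)`, both at least 32.
#' @param border_irregularity radial perturbation amplitude as a fraction of
#'   the local ellipse radius; benign presets keep it at most 0.05, malignant
#'   presets at least 0.25.
#' @param n_color_patches number of Voronoi colour patches inside the lesion
#'   (1 for benign presets, at least 3 for malignant).
#' @param lesion_palette list of RGB triples in `[0, 1]`, one per patch
#'   (recycled if fewer than `n_color_patches`).
#' @param skin_tone RGB triple for the background.
#' @param noise_sd standard deviation of additive per-channel Gaussian noise.
#' @param seed integer seed; identical parameter sets (including the seed)
#'   reproduce bit-identical cases.
#' @param radius_frac mean lesion radius as a fraction of the shorter image
#'   side.
#' @param axis_ratio minor/major axis ratio of the base ellipse; `NULL` draws
#'   it from the preset's range.
#' @param n_poi number of points of interest returned with the case.
#' @return An object of class `synth_params`.
#' @seealso [generate_case()], [generate_dataset()]
#' @export
synth_params <- function(class_label = c("benign", "malignant"),
                         image_size = c(64L, 64L),
                         border_irregularity = NULL,
                         n_color_patches = NULL,
                         lesion_palette = NULL,
                         skin_tone = c(0.87, 0.72, 0.62),
                         noise_sd = 0.02,
                         seed = 1L,
                         radius_frac = 0.28,
                         axis_ratio = NULL,
                         n_poi = NULL) {
  class_label <- match.arg(class_label)
  if (is.null(border_irregularity)) {
    border_irregularity <- if (class_label == "benign") 0.03 else 0.30
  }
  if (is.null(n_color_patches)) {
    n_color_patches <- if (class_label == "benign") 1L else 4L
  }
  if (is.null(lesion_palette)) {
    lesion_palette <- if (class_label == "benign") {
      list(c(0.50, 0.32, 0.20))
    } else {
      # four hues with near-equal luminance (~0.30)
      list(c(0.45, 0.25, 0.15),  # brown
           c(0.25, 0.30, 0.35),  # blue-gray
           c(0.50, 0.22, 0.18),  # reddish
           c(0.35, 0.28, 0.22))  # dark tan
    }
  }
  if (is.null(axis_ratio)) {
    axis_ratio <- if (class_label == "benign") 0.8 else 0.7
  }
  if (is.null(n_poi)) n_poi <- if (class_label == "benign") 1L else 3L

  if (class_label == "benign" &&
      (border_irregularity > 0.05 || n_color_patches != 1L)) {
    stop("benign presets require border_irregularity <= 0.05 and ",
         "n_color_patches = 1", call. = FALSE)
  }
  if (class_label == "malignant" &&
      (border_irregularity < 0.25 || n_color_patches < 3L)) {
    stop("malignant presets require border_irregularity >= 0.25 and ",
         "n_color_patches >= 3", call. = FALSE)
  }
  stopifnot(length(image_size) == 2L, all(image_size >= 32L),
            border_irregularity >= 0, n_color_patches >= 1L,
            noise_sd >= 0, radius_frac > 0,
            axis_ratio > 0, axis_ratio <= 1, n_poi >= 1L)

  structure(list(class_label = class_label,
                 image_size = as.integer(image_size),
                 border_irregularity = border_irregularity,
                 n_color_patches = as.integer(n_color_patches),
                 lesion_palette = lesion_palette,
                 skin_tone = skin_tone,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 radius_frac = radius_frac,
                 axis_ratio = axis_ratio,
                 n_poi = as.integer(n_poi)),
            class = "synth_params")
}

# Smooth periodic radial perturbation, zero mean, max |eta| = 1.
radial_noise_profile <- function() {
  k <- 2:6
  amp <- stats::rnorm(length(k)) / k
  phase <- stats::runif(length(k), 0, 2 * pi)
  function(theta) {
    eta <- rowSums(vapply(seq_along(k),
                          function(i) amp[i] * cos(k[i] * theta + phase[i]),
                          numeric(length(theta))))
    m <- max(abs(eta), 1e-12)
    eta / m
  }
}

#' Generate one synthetic lesion case
#'
#' Draws a lesion with the boundary model described in the package vignette,
#' colours it by a seeded Voronoi partition of its interior, composites it on
#' a skin-tone background, adds Gaussian noise, and returns the image together
#' with its ground-truth mask, points of interest, and label.
#'
#' @param params a [synth_params()] object.
#' @return An object of class `synthetic_case`: a list with elements `image`
#'   (`h x w x 3` array in `[0, 1]`), `truth_mask` (logical matrix, one
#'   connected hole-free component), `poi` (integer matrix of 0-based
#'   `(row, col)` seeds, all inside the mask; the first is the mask centroid),
#'   `label`, and `params`.
#' @export
generate_case <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  with_seed(params$seed, {
    R <- params$radius_frac * min(h, w)
    if (R * (1 + params$border_irregularity) >= min(h, w) / 2 - 2) {
      stop("lesion radius exceeds the image frame", call. = FALSE)
    }
    # centre jittered inside the central 20% so the centroid stays central
    cr <- (h - 1) / 2 + stats::runif(1, -0.1, 0.1) * h
    cc <- (w - 1) / 2 + stats::runif(1, -0.1, 0.1) * w
    phi <- stats::runif(1, 0, pi)
    ar <- params$axis_ratio
    a <- R / sqrt(ar); b <- R * sqrt(ar)   # keeps a*b = R^2
    eta <- radial_noise_profile()

    rows <- matrix(0:(h - 1), h, w)
    cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
    dr <- rows - cr; dc <- cols - cc
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(dr, dc)
    tp <- theta - phi
    r_ell <- (a * b) / sqrt((b * cos(tp))^2 + (a * sin(tp))^2)
    mod <- pmax(0.3, 1 + params$border_irregularity * eta(as.vector(theta)))
    r_bound <- r_ell * matrix(mod, h, w)
    mask <- dist <= r_bound

    # Voronoi colour patches over the lesion interior
    idx <- which(mask, arr.ind = TRUE)
    npatch <- params$n_color_patches
    sites <- idx[sample.int(nrow(idx), npatch), , drop = FALSE]
    pal <- params$lesion_palette
    pal_idx <- ((seq_len(npatch) - 1L) %% length(pal)) + 1L
    d2 <- vapply(seq_len(npatch), function(i) {
      (idx[, 1] - sites[i, 1])^2 + (idx[, 2] - sites[i, 2])^2
    }, numeric(nrow(idx)))
    nearest <- max.col(-d2, ties.method = "first")

    image <- array(rep(params$skin_tone, each = h * w), dim = c(h, w, 3L))
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[idx] <- vapply(nearest, function(i) pal[[pal_idx[i]]][ch],
                           numeric(1))
      image[, , ch] <- plane
    }
    if (params$noise_sd > 0) {
      image <- image + array(stats::rnorm(h * w * 3, sd = params$noise_sd),
                             dim = c(h, w, 3L))
    }
    image <- clip01(image)

    # POIs: centroid first, extras uniform inside the mask
    cen <- round(colMeans(idx)) # (row, col), 1-based
    if (!mask[cen[1], cen[2]]) cen <- c(round(cr) + 1L, round(cc) + 1L)
    poi <- matrix(cen - 1L, 1L, 2L)
    if (params$n_poi > 1L) {
      extra <- idx[sample.int(nrow(idx), params$n_poi - 1L), , drop = FALSE]
      poi <- rbind(poi, extra - 1L)
    }
    colnames(poi) <- c("row", "col")
    structure(list(image = image, truth_mask = mask,
                   poi = matrix(as.integer(poi), nrow(poi), 2L,
                                dimnames = list(NULL, c("row", "col"))),
                   label = params$class_label, params = params),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s, %d x %d, mask area %d px, %d POI(s)\n",
              x$label, nrow(x$truth_mask), ncol(x$truth_mask),
              sum(x$truth_mask), nrow(x$poi)))
  invisible(x)
}

#' Generate a balanced synthetic dataset
#'
#' @param n_per_class number of cases per class (at least 1).
#' @param presets named list with elements `benign` and `malignant`, each a
#'   [synth_params()] object used as the class template. Defaults to the
#'   package presets at 64 x 64.
#' @param seed master seed; per-case seeds are derived from it
#'   deterministically, so the whole dataset is a pure function of
#'   `(n_per_class, presets, seed)`.
#' @return A list of `2 * n_per_class` `synthetic_case` objects, the benign
#'   cases first.
#' @export
generate_dataset <- function(n_per_class,
                             presets = list(benign = synth_params("benign"),
                                            malignant = synth_params("malignant")),
                             seed = 1L) {
  stopifnot(n_per_class >= 1L,
            inherits(presets$benign, "synth_params"),
            inherits(presets$malignant, "synth_params"))
  cases <- vector("list", 2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    pb <- presets$benign
    pb$seed <- derive_seed(seed, i)
    cases[[i]] <- generate_case(pb)
    pm <- presets$malignant
    pm$seed <- derive_seed(seed, n_per_class + i)
    cases[[n_per_class + i]] <- generate_case(pm)
  }
  cases
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per case (plus its ground-truth mask) and a manifest CSV
#' with columns `filename`, `label`, `poi_row`, `poi_col` (first POI) and
#' `seed`.
#'
#' @param cases list of `synthetic_case` objects.
#' @param dir output directory, created if missing.
#' @return The manifest as a data frame, invisibly.
#' @export
write_dataset <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(filename = character(0), label = character(0),
                         poi_row = integer(0), poi_col = integer(0),
                         seed = integer(0))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    fn <- sprintf("case_%04d_%s.png", i, cs$label)
    write_image(cs$image, file.path(dir, fn))
    write_mask(cs$truth_mask, file.path(dir, sub("\\.png$", "_mask.png", fn)))
    manifest <- rbind(manifest, data.frame(
      filename = fn, label = cs$label,
      poi_row = cs$poi[1, 1], poi_col = cs$poi[1, 2],
      seed = cs$params$seed))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
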