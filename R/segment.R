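# POI-seeded lesion segmentation.
#
# Fixed preprocessing order: gray conversion -> 3x3 zero-padded median
# filter -> contrast stretch -> region growing from the POIs -> morphological
# refinement. Similarity during growing is measured against the originating
# seed's gray value (not a running region mean), which makes the result
# independent of pixel visit order and of the ordering of the seed list.

#' Segmentation configuration
#'
#' @param similarity_threshold maximum absolute gray-value distance (in
#'   `[0, 1]`) between a candidate pixel and the gray value of the seed it is
#'   grown from.
#' @param connectivity pixel neighbourhood, 4 or 8.
#' @param opening_radius radius (pixels) of the disc structuring element used
#'   when filling holes during refinement; 0 disables morphology.
#' @param min_object_size connected components smaller than this many pixels
#'   are discarded during refinement.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(similarity_threshold = 0.15,
                                connectivity = 8L,
                                opening_radius = 2L,
                                min_object_size = 64L) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            connectivity %in% c(4L, 8L),
            opening_radius >= 0, min_object_size >= 0)
  structure(list(similarity_threshold = similarity_threshold,
                 connectivity = as.integer(connectivity),
                 opening_radius = as.integer(opening_radius),
                 min_object_size = as.integer(min_object_size)),
            class = "segmentation_config")
}

#' Convert an RGB image to gray values
#'
#' Luminance-weighted combination (ITU-R BT.601 weights 0.299, 0.587, 0.114,
#' which sum to one, so constant gray inputs are preserved).
#'
#' @param image `h x w x 3` array in `[0, 1]`.
#' @return `h x w` matrix in `[0, 1]`.
#' @export
to_gray <- function(image) {
  assert_rgb(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(g, dim(image)[1], dim(image)[2])
}

#' 3x3 median filter with zero padding
#'
#' Each output pixel is the median (5th smallest) of the nine values in its
#' 3x3 neighbourhood; neighbourhoods reaching past the border are filled with
#' zeros, so border pixels of a bright image are darkened — the documented
#' behaviour of the filter, kept as specified.
#'
#' @param image single-channel matrix.
#' @return Filtered matrix of the same size.
#' @export
median_filter3 <- function(image) {
  assert_gray(image)
  h <- nrow(image); w <- ncol(image)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- image
  neigh <- matrix(0, h * w, 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    neigh[, k] <- as.vector(pad[(1L + di):(h + di), (1L + dj):(w + dj)])
  }
  matrix(apply(neigh, 1L, function(v) sort.int(v, partial = 5L)[5L]), h, w)
}

#' Stretch gray values to the full [0, 1] range
#'
#' Affine rescaling so the output minimum is 0 and maximum is 1; a constant
#' image is returned unchanged. Pixel rank order is preserved.
#'
#' @param image single-channel matrix.
#' @export
stretch_contrast <- function(image) {
  assert_gray(image)
  lo <- min(image); hi <- max(image)
  if (hi - lo <= .Machine$double.eps) return(image)
  (image - lo) / (hi - lo)
}

#' Region growing from seed points
#'
#' Grows a region from each point of interest: a pixel belongs to the mask iff
#' it is reachable from some seed through a connected path of pixels whose
#' gray distance to that seed's value is at most the similarity threshold.
#' The result is the union over seeds and is deterministic regardless of seed
#' order or visit order.
#'
#' @param image single-channel matrix in `[0, 1]`.
#' @param seeds integer matrix of 0-based `(row, col)` seed coordinates.
#' @param config a [segmentation_config()].
#' @return Logical mask matrix; every seed pixel is inside it.
#' @export
region_grow <- function(image, seeds, config = segmentation_config()) {
  assert_gray(image)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) stop("at least one seed is required", call. = FALSE)
  if (any(seeds[, 1] < 0 | seeds[, 1] >= nrow(image) |
          seeds[, 2] < 0 | seeds[, 2] >= ncol(image))) {
    stop("seed out of image bounds", call. = FALSE)
  }
  storage.mode(seeds) <- "integer"
  cpp_region_grow(image, seeds, config$similarity_threshold,
                  config$connectivity)
}

# Component labelling on a logical mask (1..n labels, 0 background).
label_components <- function(mask, connectivity = 8L) {
  cpp_label_components(mask, as.integer(connectivity))
}

#' Morphological refinement of a segmentation mask
#'
#' Fills interior holes up to the opening scale (opening of the complement
#' with a disc structuring element, equivalently a closing of the mask),
#' then removes connected components smaller than `min_object_size`.
#'
#' @param mask logical matrix from [region_grow()].
#' @param config a [segmentation_config()].
#' @param seeds optional 0-based seed matrix; if given, an error is raised
#'   when refinement removes every seed-containing component.
#' @return Refined logical mask.
#' @export
refine_mask <- function(mask, config = segmentation_config(), seeds = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  out <- mask
  if (config$opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * config$opening_radius + 1L,
                                shape = "disc")
    m <- EBImage::Image(matrix(as.numeric(out), nrow(out), ncol(out)))
    out <- EBImage::imageData(EBImage::closing(m, brush)) > 0.5
  }
  if (config$min_object_size > 0) {
    lab <- label_components(out, config$connectivity)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= config$min_object_size)
    out <- matrix(lab %in% keep, nrow(out), ncol(out))
  }
  if (!is.null(seeds)) {
    seeds <- as.matrix(seeds)
    if (!any(out[cbind(seeds[, 1] + 1L, seeds[, 2] + 1L)])) {
      stop("refinement removed every seed-containing component",
           call. = FALSE)
    }
  }
  out
}

#' Full POI-seeded lesion segmentation
#'
#' Runs the fixed preprocessing chain (gray conversion, 3x3 median filter,
#' contrast stretch), grows the region of interest from the supplied points
#' of interest, and refines it morphologically.
#'
#' @param image RGB array in `[0, 1]`.
#' @param poi integer matrix of 0-based `(row, col)` points of interest.
#' @param config a [segmentation_config()].
#' @return A list of class `segmentation_result` with elements `mask`
#'   (logical matrix), `gray` (the preprocessed gray image), `poi`, `config`
#'   and `area` (mask pixel count).
#' @export
segment_lesion <- function(image, poi, config = segmentation_config()) {
  if (is.null(poi) || nrow(as.matrix(poi)) == 0L) {
    stop("segmentation requires at least one point of interest (POI)",
         call. = FALSE)
  }
  gray <- stretch_contrast(median_filter3(to_gray(image)))
  mask <- region_grow(gray, poi, config)
  mask <- refine_mask(mask, config, seeds = poi)
  structure(list(mask = mask, gray = gray, poi = as.matrix(poi),
                 config = config, area = sum(mask)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d, area %d px, %d seed(s), threshold %.3f\n",
              nrow(x$mask), ncol(x$mask), x$area, nrow(x$poi),
              x$config$similarity_threshold))
  invisible(x)
}

#' Write a JSON segmentation report
#'
#' @param result a `segmentation_result`.
#' @param path output JSON path.
#' @export
write_segmentation_report <- function(result, path) {
  jsonlite::write_json(list(
    seeds = apply(result$poi, 1L, function(r) list(row = r[1], col = r[2])),
    similarity_threshold = result$config$similarity_threshold,
    connectivity = result$config$connectivity,
    mask_area = result$area), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Jaccard overlap between two masks
#'
#' @param a,b logical matrices of equal size.
#' @return `|a & b| / |a | b|` (1 when both are empty).
#' @export
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
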