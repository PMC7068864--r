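#' @useDynLib lesionclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Images are plain base-R arrays in [0,1]:
#   gray  -> h x w matrix
#   RGB   -> h x w x 3 array
# Coordinates are 0-based (row, col), origin top-left, matching the rest of
# the pipeline (POIs, masks, seeds).

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_rgb <- function(x, what = "image") {
  if (!is_rgb_image(x)) {
    stop(sprintf("%s must be an h x w x 3 RGB array in [0,1]", what),
         call. = FALSE)
  }
  invisible(x)
}

assert_gray <- function(x, what = "image") {
  if (!is_gray_image(x)) {
    stop(sprintf("%s must be an h x w single-channel matrix", what),
         call. = FALSE)
  }
  invisible(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Read an RGB image from a PNG or JPEG file
#'
#' @param path file path; format inferred from the extension.
#' @return An `h x w x 3` numeric array with values in `[0, 1]`. Gray input
#'   images are replicated across the three channels; an alpha channel, if
#'   present, is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = as.array(EBImage::imageData(
      EBImage::transpose(EBImage::readImage(path)))),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] >= 4L) x <- x[, , 1:3, drop = FALSE]
  clip01(x[, , 1:3, drop = FALSE])
}

#' Write an image to an 8-bit PNG file
#'
#' Values are clipped to `[0, 1]` before quantization, so a float image
#' synthesized in `[0, 1]` round-trips losslessly up to 8-bit precision.
#'
#' @param image gray matrix or RGB array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG back to a logical matrix
#'
#' @param path PNG path.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All generator determinism contracts rest on this helper.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item seed from a master seed, kept within 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

apply_channels <- function(image, f) {
  if (is_gray_image(image)) return(f(image))
  planes <- lapply(seq_len(dim(image)[3]), function(ch) f(image[, , ch]))
  array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
}

#' Label-preserving data augmentation transforms
#'
#' Classical augmentation operations used to enlarge image training sets:
#' quarter-turn rotation, horizontal/vertical flips, rescaling, cropping and
#' translation. All of them preserve the class label and keep pixel values
#' within image bounds; rotating four quarter turns is the identity.
#'
#' @param image gray matrix or RGB array.
#' @param k number of counter-clockwise quarter turns (`rotate90`).
#' @param horizontal flip left-right if `TRUE`, else top-bottom (`flip_image`).
#' @param size target `(h, w)` for `rescale_image` (nearest-neighbour).
#' @param top,left,height,width 0-based crop window for `crop_image`.
#' @param dr,dc translation offsets in pixels (positive = down/right); exposed
#'   areas are filled with `fill`.
#' @param fill fill value for exposed pixels.
#' @return The transformed image, same container type as the input.
#' @name augmentation
NULL

#' @rdname augmentation
#' @export
rotate90 <- function(image, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  out <- image
  for (i in seq_len(k)) out <- apply_channels(out, rot1)
  out
}

#' @rdname augmentation
#' @export
flip_image <- function(image, horizontal = TRUE) {
  f <- if (horizontal) function(m) m[, ncol(m):1, drop = FALSE]
  else function(m) m[nrow(m):1, , drop = FALSE]
  apply_channels(image, f)
}

#' @rdname augmentation
#' @export
rescale_image <- function(image, size) {
  stopifnot(length(size) == 2L, all(size >= 1))
  f <- function(m) {
    ri <- pmin(nrow(m), pmax(1L, round((seq_len(size[1]) - 0.5) *
                                         nrow(m) / size[1] + 0.5)))
    ci <- pmin(ncol(m), pmax(1L, round((seq_len(size[2]) - 0.5) *
                                         ncol(m) / size[2] + 0.5)))
    m[ri, ci, drop = FALSE]
  }
  apply_channels(image, f)
}

#' @rdname augmentation
#' @export
crop_image <- function(image, top, left, height, width) {
  d <- dim(image)
  stopifnot(top >= 0, left >= 0, top + height <= d[1], left + width <= d[2])
  f <- function(m) m[(top + 1):(top + height), (left + 1):(left + width),
                     drop = FALSE]
  apply_channels(image, f)
}

#' @rdname augmentation
#' @export
translate_image <- function(image, dr = 0L, dc = 0L, fill = 0) {
  f <- function(m) {
    out <- matrix(fill, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dr
    src_c <- seq_len(ncol(m)) - dc
    ok_r <- src_r >= 1 & src_r <= nrow(m)
    ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
    out
  }
  apply_channels(image, f)
}
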