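#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of pixel intensities with rows as the
#' vertical (y) axis and columns as the horizontal (x) axis. All geometry in
#' the package uses 0-based coordinates: `x` is the column index minus one,
#' `y` is the row index minus one. Angles are measured counter-clockwise from
#' the positive x axis in this frame, in the range `[0, pi)` for ridge
#' orientations.
#'
#' @param pixels numeric matrix of intensities (conventionally 0-255 for raw
#'   images, or mean-0/variance-1 after [normalize_image()]).
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("image intensities must be finite")
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

assert_image_size <- function(img, min_side = 32L) {
  if (nrow(img) < min_side || ncol(img) < min_side) {
    stop(sprintf("image must be at least %d x %d pixels", min_side, min_side))
  }
  invisible(img)
}

#' Skeleton image container
#'
#' Binary ridge skeleton: `pixels` is a 0/1 matrix with unit-width ridges,
#' `mask` the foreground segmentation it lives in (skeleton is a subset of
#' the mask).
#'
#' @param pixels binary (0/1 or logical) matrix, ridge = 1.
#' @param mask logical matrix of the same dimensions; defaults to all-TRUE.
#' @return an object of class `skeleton_image` with elements `pixels`, `mask`.
#' @export
skeleton_image <- function(pixels, mask = NULL) {
  pixels <- matrix(as.integer(as.logical(pixels)), nrow(pixels), ncol(pixels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(mask), dim(pixels)))
  if (any(pixels == 1L & !mask)) stop("skeleton pixels must lie inside the mask")
  structure(list(pixels = pixels, mask = mask), class = "skeleton_image")
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> %d x %d px, %d ridge px, %d mask px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), sum(x$mask)))
  invisible(x)
}
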