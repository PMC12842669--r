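#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix (rows = vertical axis y, increasing
#' downward; columns = horizontal axis x) carrying a `depth` attribute that
#' records the intensity convention:
#'
#' * `"uint8"` — integer-valued pixels in \[0, 255\] (the canonical on-disk
#'   representation of an 8-bit radiograph);
#' * `"unit"`  — real pixels in \[0, 1\] (after fixed-range min-max scaling);
#' * `"standardized"` — unbounded real pixels (after Z-scoring or pre-clip
#'   histogram standardization).
#'
#' All public crop windows are reported as 0-based inclusive index ranges in
#' this row/column convention.
#'
#' @param pixels numeric matrix, height x width, both dimensions >= 1.
#' @param depth one of `"uint8"`, `"unit"`, `"standardized"`.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, depth = c("uint8", "unit", "standardized")) {
  depth <- match.arg(depth)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing pixel values", call. = FALSE)
  if (depth == "uint8") {
    if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels))) {
      stop("uint8 image must contain only integers in [0, 255]", call. = FALSE)
    }
    storage.mode(pixels) <- "double"
  }
  if (depth == "unit" && any(pixels < 0 | pixels > 1)) {
    stop("unit-depth image must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, depth = depth, class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, depth = %s\n", nrow(x), ncol(x), img_depth(x)))
  invisible(x)
}

#' Image depth accessor
#' @param image a [gray_image()].
#' @return The depth tag of the image.
#' @export
img_depth <- function(image) {
  d <- attr(image, "depth")
  if (is.null(d)) "uint8" else d
}

#' @rdname gray_image
#' @param x object to test.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

# strip class/attrs, keep a plain matrix
as_pixel_matrix <- function(image) {
  m <- unclass(image)
  attr(m, "depth") <- NULL
  m
}

assert_depth <- function(image, depth, what) {
  if (!is_gray_image(image)) {
    stop(sprintf("%s expects a gray_image", what), call. = FALSE)
  }
  if (img_depth(image) != depth) {
    stop(sprintf("%s expects a %s-depth image, got %s", what, depth, img_depth(image)),
         call. = FALSE)
  }
  invisible(image)
}

#' Quantize a real-valued image to uint8
#'
#' Clips to \[0, 255\] then rounds half away from zero (so 0.5 -> 1, 121.5 ->
#' 122), the convention used for all 8-bit outputs of the normalization
#' pipeline.
#'
#' @param image a [gray_image()] of any depth.
#' @return A uint8 [gray_image()].
#' @export
quantize_uint8 <- function(image) {
  m <- as_pixel_matrix(image)
  m <- pmin(pmax(m, 0), 255)
  gray_image(trunc(m + 0.5), depth = "uint8")  # m >= 0 after clipping
}
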