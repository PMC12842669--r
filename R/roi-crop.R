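#' Percentile crop specification
#'
#' Mass fractions bounding the retained window on each axis. The defaults
#' keep the central 5th–95th percentile of horizontal intensity mass
#' (dropping low-density lateral background) and the 15th–95th percentile of
#' vertical mass (dropping the bright neck/shoulder band above the clavicle).
#'
#' @param x_lo,x_hi,y_lo,y_hi mass fractions, `0 <= lo < hi <= 1` per axis.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(x_lo = 0.05, x_hi = 0.95, y_lo = 0.15, y_hi = 0.95) {
  for (axis in list(c(x_lo, x_hi), c(y_lo, y_hi))) {
    if (!(axis[1] >= 0 && axis[1] < axis[2] && axis[2] <= 1)) {
      stop("crop_spec needs 0 <= lo < hi <= 1 on each axis", call. = FALSE)
    }
  }
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
            class = "crop_spec")
}

#' Axis-marginal grayscale-sum profile
#'
#' The horizontal profile has one entry per column (sum of that column's
#' intensities); the vertical profile has one entry per row. Either profile
#' sums to the total intensity mass of the image.
#'
#' @param image a [gray_image()].
#' @param axis `"horizontal"` (column-wise) or `"vertical"` (row-wise).
#' @return Non-negative numeric vector.
#' @export
axis_profile <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  m <- as_pixel_matrix(image)
  if (axis == "horizontal") colSums(m) else rowSums(m)
}

#' Normalized cumulative mass of a profile
#'
#' `mass_cdf(p)[i] = sum(p[1:i]) / sum(p)`; non-decreasing with final entry
#' exactly 1 (the full sum divided by itself). An all-zero profile carries no
#' positional information and raises a degenerate-input error so the caller
#' can choose a fallback.
#'
#' @param profile non-negative numeric vector with at least one positive entry.
#' @return Numeric vector in \[0, 1\].
#' @export
mass_cdf <- function(profile) {
  if (length(profile) == 0L) stop("empty profile", call. = FALSE)
  if (any(profile < 0)) stop("profile entries must be non-negative", call. = FALSE)
  total <- sum(profile)
  if (total <= 0) {
    stop("degenerate profile: all entries are zero", call. = FALSE)
  }
  cdf <- cumsum(profile) / total
  cdf[length(cdf)] <- 1  # exact by construction (total/total)
  cdf
}

#' Percentile window on a mass CDF
#'
#' Retains exactly the indices `i` with `lo < cdf[i] <= hi` (half-open in
#' mass: on a uniform profile this keeps exactly the central `hi - lo`
#' fraction of bins) and returns the 0-based inclusive `(first, last)` range
#' of the retained set. An empty retained set is the fallback condition,
#' reported as `NULL` rather than an error so batch callers can keep the full
#' axis extent.
#'
#' @param cdf output of [mass_cdf()].
#' @param lo,hi mass fractions, `lo < hi`.
#' @return Integer vector `c(first, last)` (0-based inclusive), or `NULL` if
#'   no index is retained (fallback condition).
#' @export
percentile_window <- function(cdf, lo, hi) {
  stopifnot(lo < hi)
  keep <- which(cdf > lo & cdf <= hi)
  if (length(keep) == 0L) return(NULL)
  c(first = min(keep) - 1L, last = max(keep) - 1L)
}

#' CDF-guided percentile crop
#'
#' Step 1 of the adaptive pipeline. Both axis windows are computed from the
#' original image's profiles (not re-profiled after cropping one axis): the
#' horizontal profile is cut at `(x_lo, x_hi]` mass and the vertical profile
#' at `(y_lo, y_hi]`. A degenerate axis (all-zero profile or empty retained
#' set) falls back to its full extent and sets `fallback_used`; cropping is a
#' pure selection and never alters retained pixel values.
#'
#' @param image a [gray_image()].
#' @param spec a [crop_spec()].
#' @return A `crop_result` list with elements `window` (named integer vector
#'   `x_first, x_last, y_first, y_last`, 0-based inclusive), `image` (the
#'   cropped [gray_image()]) and `fallback_used` (logical).
#' @export
cdf_crop <- function(image, spec = crop_spec()) {
  stopifnot(is_gray_image(image), inherits(spec, "crop_spec"))
  h <- nrow(image); w <- ncol(image)

  window_for <- function(profile, lo, hi, n) {
    win <- tryCatch(percentile_window(mass_cdf(profile), lo, hi),
                    error = function(e) NULL)
    if (is.null(win)) list(win = c(0L, n - 1L), fallback = TRUE)
    else list(win = unname(win), fallback = FALSE)
  }

  wx <- window_for(axis_profile(image, "horizontal"), spec$x_lo, spec$x_hi, w)
  wy <- window_for(axis_profile(image, "vertical"),   spec$y_lo, spec$y_hi, h)

  rows <- (wy$win[1] + 1L):(wy$win[2] + 1L)
  cols <- (wx$win[1] + 1L):(wx$win[2] + 1L)
  cropped <- gray_image(as_pixel_matrix(image)[rows, cols, drop = FALSE],
                        depth = img_depth(image))
  structure(list(
    window = c(x_first = wx$win[1], x_last = wx$win[2],
               y_first = wy$win[1], y_last = wy$win[2]),
    image = cropped,
    fallback_used = wx$fallback || wy$fallback
  ), class = "crop_result")
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> window x [%d, %d], y [%d, %d]%s\n",
              x$window["x_first"], x$window["x_last"],
              x$window["y_first"], x$window["y_last"],
              if (x$fallback_used) " (fallback)" else ""))
  invisible(x)
}
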