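#' Target moments for histogram standardization
#'
#' The defaults, stored at full precision, are the fixed target statistics of
#' the adaptive pipeline: mean `0.4776 * 255 = 121.788` (printed rounded as
#' 121.8) and standard deviation `0.2238 * 255 = 57.069` (printed 57.1),
#' derived from normal-cohort chest radiographs.
#'
#' @param mu_target target mean intensity on the 0–255 scale.
#' @param sigma_target target standard deviation, `> 0`.
#' @return A `standardization_params` list.
#' @export
standardization_params <- function(mu_target = 0.4776 * 255,
                                   sigma_target = 0.2238 * 255) {
  if (!(sigma_target > 0)) stop("sigma_target must be > 0", call. = FALSE)
  structure(list(mu_target = mu_target, sigma_target = sigma_target),
            class = "standardization_params")
}

#' Fixed-range min-max scaling
#'
#' Divides every pixel by 255, mapping the 8-bit range onto \[0, 1\]. The
#' range is fixed, not per-image min/max, so a constant image maps to a
#' constant (no degenerate division) and the transform is strictly monotone.
#'
#' @param image a uint8 [gray_image()].
#' @return A unit-depth [gray_image()].
#' @export
minmax_scale <- function(image) {
  assert_depth(image, "uint8", "minmax_scale()")
  gray_image(as_pixel_matrix(image) / 255, depth = "unit")
}

#' Global dataset intensity statistics for Z-score normalization
#'
#' Pools ALL pixels of all listed images and returns their mean and
#' population (divide-by-N) standard deviation. These dataset-level
#' statistics parameterize [zscore_apply()]; fit them on the training
#' partition only.
#'
#' @param images a `dataset_manifest` (paths are read with [read_gray()]) or
#'   a list of [gray_image()]s.
#' @return A `dataset_stats` list with `mu_global`, `sigma_global`, `n_images`.
#' @export
zscore_fit <- function(images) {
  if (inherits(images, "dataset_manifest")) {
    images <- lapply(images$path, read_gray)
  }
  if (!is.list(images) || length(images) == 0L) {
    stop("zscore_fit() needs at least one image", call. = FALSE)
  }
  # single pass over pooled pixels: sum, sum of squares, count
  s <- 0; s2 <- 0; n <- 0
  for (img in images) {
    m <- as_pixel_matrix(img)
    s <- s + sum(m); s2 <- s2 + sum(m^2); n <- n + length(m)
  }
  mu <- s / n
  sigma <- sqrt(max(s2 / n - mu^2, 0))
  structure(list(mu_global = mu, sigma_global = sigma, n_images = length(images)),
            class = "dataset_stats")
}

#' Apply dataset-level Z-score normalization
#'
#' `pixel -> (pixel - mu_global) / sigma_global`; the output depth is
#' `standardized` (unbounded reals, zero pooled mean and unit pooled variance
#' over the fitted dataset). A strictly monotone map, so pixel rank order is
#' preserved.
#'
#' @param image a [gray_image()].
#' @param stats a `dataset_stats` from [zscore_fit()].
#' @return A standardized-depth [gray_image()].
#' @export
zscore_apply <- function(image, stats) {
  stopifnot(inherits(stats, "dataset_stats"))
  if (!(stats$sigma_global > 0)) {
    stop("degenerate dataset: global standard deviation is zero", call. = FALSE)
  }
  gray_image((as_pixel_matrix(image) - stats$mu_global) / stats$sigma_global,
             depth = "standardized")
}

# per-image mean and population sd
image_moments <- function(m) {
  mu <- mean(m)
  list(mu = mu, sigma = sqrt(mean((m - mu)^2)))
}

#' Per-image histogram standardization
#'
#' The core intensity transform of the adaptive pipeline: with `mu_orig` /
#' `sigma_orig` the image's own mean and population standard deviation, each
#' pixel maps to
#'
#'   `(I - mu_orig) / sigma_orig * sigma_target + mu_target`
#'
#' so that (before clipping) the output has exactly the target moments. A
#' constant image (`sigma_orig == 0`) maps uniformly to `mu_target`. With
#' `clip = TRUE` (default) the result is clipped to \[0, 255\]; clipping can
#' perturb the realized moments on images with heavy tails. The transform
#' cancels any positive affine intensity change of its input and is
#' idempotent pre-clipping.
#'
#' @param image a [gray_image()].
#' @param params a [standardization_params()].
#' @param clip clip the output to \[0, 255\]?
#' @return A standardized-depth [gray_image()] (real-valued; quantize with
#'   [quantize_uint8()] for 8-bit output).
#' @export
histogram_standardize <- function(image, params = standardization_params(),
                                  clip = TRUE) {
  stopifnot(is_gray_image(image), inherits(params, "standardization_params"))
  m <- as_pixel_matrix(image)
  mom <- image_moments(m)
  out <- if (mom$sigma > 0) {
    (m - mom$mu) / mom$sigma * params$sigma_target + params$mu_target
  } else {
    array(params$mu_target, dim = dim(m))
  }
  if (clip) out <- pmin(pmax(out, 0), 255)
  gray_image(out, depth = "standardized")
}

#' Normalization method specification
#'
#' Bundles a method tag with the parameters it needs:
#' * `scaling`   — fixed-range min-max scaling ([minmax_scale()]);
#' * `zscore`    — dataset-level Z-score ([zscore_fit()] / [zscore_apply()]);
#' * `adaptive`  — CDF crop then histogram standardization (the full
#'   pipeline, [adaptive_normalize()]);
#' * `crop_only` — the crop stage alone (ablation row B);
#' * `hist_only` — histogram standardization on the full frame (ablation
#'   row C).
#'
#' @param method method tag.
#' @param crop a [crop_spec()] (used by `adaptive` / `crop_only`).
#' @param standardize a [standardization_params()] (used by `adaptive` /
#'   `hist_only`).
#' @param output_size optional `c(height, width)` to resize to after
#'   normalization.
#' @param per_image_zscore use per-image instead of dataset-level statistics
#'   for `zscore` (explicit opt-in; the benchmark default is dataset-level).
#' @return A `normalization_spec` list.
#' @export
normalization_spec <- function(method = c("scaling", "zscore", "adaptive",
                                          "crop_only", "hist_only"),
                               crop = crop_spec(),
                               standardize = standardization_params(),
                               output_size = NULL,
                               per_image_zscore = FALSE) {
  method <- match.arg(method)
  if (!is.null(output_size)) {
    stopifnot(length(output_size) == 2L, all(output_size >= 1))
  }
  structure(list(method = method, crop = crop, standardize = standardize,
                 output_size = output_size, per_image_zscore = per_image_zscore),
            class = "normalization_spec")
}

maybe_resize <- function(image, output_size) {
  if (is.null(output_size)) return(image)
  resize_bilinear(image, output_size[1], output_size[2])
}

#' The full adaptive normalization pipeline
#'
#' Pipeline order: CDF-guided percentile crop ([cdf_crop()]) -> histogram
#' standardization with per-ROI moments ([histogram_standardize()]) ->
#' optional bilinear resize -> clip and quantize to uint8 (round half away
#' from zero). The crop window is returned for auditability.
#'
#' @param image a uint8 [gray_image()].
#' @param spec a [normalization_spec()] with `method = "adaptive"`.
#' @return List with `image` (uint8 [gray_image()]) and `crop` (the
#'   `crop_result`).
#' @export
adaptive_normalize <- function(image, spec = normalization_spec("adaptive")) {
  assert_depth(image, "uint8", "adaptive_normalize()")
  stopifnot(inherits(spec, "normalization_spec"), spec$method == "adaptive")
  cr <- cdf_crop(image, spec$crop)
  std <- histogram_standardize(cr$image, spec$standardize, clip = TRUE)
  out <- quantize_uint8(maybe_resize(std, spec$output_size))
  list(image = out, crop = cr)
}

#' Ablation variants of the adaptive pipeline
#'
#' `crop_only` applies the percentile crop and optional resize with no
#' intensity change (any model-input scaling happens later); `hist_only`
#' applies histogram standardization to the full frame, then the optional
#' resize. `hist_only` is identical to `adaptive` run with a full-extent
#' crop.
#'
#' @param image a uint8 [gray_image()].
#' @param spec a [normalization_spec()] with method `crop_only` or `hist_only`.
#' @return A uint8 [gray_image()].
#' @export
ablation_variant <- function(image, spec) {
  assert_depth(image, "uint8", "ablation_variant()")
  stopifnot(inherits(spec, "normalization_spec"))
  switch(spec$method,
    crop_only = {
      cr <- cdf_crop(image, spec$crop)
      quantize_uint8(maybe_resize(cr$image, spec$output_size))
    },
    hist_only = {
      std <- histogram_standardize(image, spec$standardize, clip = TRUE)
      quantize_uint8(maybe_resize(std, spec$output_size))
    },
    stop(sprintf("ablation_variant() handles crop_only / hist_only, not '%s'",
                 spec$method), call. = FALSE)
  )
}

#' Bilinear resize
#'
#' Corner-aligned convention: output index `i` (0-based) samples source
#' coordinate `i * (n_in - 1) / (n_out - 1)` so the first and last output
#' rows/columns coincide with the first and last input ones; a single-pixel
#' output axis samples coordinate 0. Identity when the size is unchanged;
#' constant images stay constant at any size.
#'
#' @param image a [gray_image()].
#' @param height,width target dimensions, `>= 1`.
#' @return A [gray_image()] of the requested size (depth `standardized` when
#'   interpolation creates non-integer values from a uint8 input, otherwise
#'   the input depth).
#' @export
resize_bilinear <- function(image, height, width) {
  stopifnot(is_gray_image(image))
  if (height < 1 || width < 1) stop("resize target dims must be >= 1", call. = FALSE)
  m <- as_pixel_matrix(image)
  h <- nrow(m); w <- ncol(m)
  if (height == h && width == w) return(image)

  src_coord <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(0, n_out)
    else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ry <- src_coord(height, h); rx <- src_coord(width, w)
  y0 <- pmin(floor(ry), h - 1); x0 <- pmin(floor(rx), w - 1)
  fy <- ry - y0; fx <- rx - x0
  y0 <- y0 + 1; x0 <- x0 + 1                       # 1-based
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)

  top    <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
            m[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  bottom <- m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
            m[y1, x1, drop = FALSE] * outer(fy, fx)
  out <- top + bottom

  depth <- img_depth(image)
  if (depth == "uint8" && any(out != round(out))) depth <- "standardized"
  gray_image(out, depth = depth)
}
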