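#' Read a grayscale image from PNG or JPEG
#'
#' Decodes an 8-bit PNG or JPEG into the canonical in-memory [gray_image()]
#' (uint8 depth). Multi-channel inputs are collapsed to a single channel with
#' the ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B); an alpha
#' channel, if present, is ignored. Higher bit depths are quantized to 8 bit.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A uint8 [gray_image()].
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("unreadable image '%s': %s", path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (length(arr) == 0L) stop(sprintf("zero-sized image: %s", path), call. = FALSE)
  if (length(dim(arr)) == 3L) {
    d <- dim(arr)
    arr <- if (d[3] >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]  # gray(+alpha)
    }
    arr <- matrix(arr, d[1], d[2])  # guard against dimension dropping
  }
  gray_image(round(arr * 255), depth = "uint8")
}

#' Write a grayscale image as PNG
#'
#' Only uint8 images are written (quantize first with [quantize_uint8()]).
#' PNG round trips are bit exact: `read_gray(write_gray(x, p))` reproduces
#' `x`. JPEG output is deliberately unsupported (lossy round trip).
#'
#' @param image a uint8 [gray_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  assert_depth(image, "uint8", "write_gray()")
  if (tolower(tools::file_ext(path)) != "png") {
    stop("write_gray() writes PNG only; use a .png path", call. = FALSE)
  }
  png::writePNG(as_pixel_matrix(image) / 255, target = path)
  invisible(path)
}

#' Dataset manifests
#'
#' A manifest is a data frame with class `dataset_manifest` and columns
#' `path` (image file), `label` (0 = normal, 1 = abnormal), `patient_id`
#' (opaque grouping key used for patient-level splitting) and `domain`
#' (opaque acquisition-site key). `read_manifest()` / `write_manifest()`
#' round-trip the CSV dialect `path,label,patient_id,domain` preserving
#' record order.
#'
#' @param records data frame with the four manifest columns.
#' @return A `dataset_manifest`.
#' @export
dataset_manifest <- function(records) {
  req <- c("path", "label", "patient_id", "domain")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("manifest has no records", call. = FALSE)
  lab <- records$label
  bad <- which(!(lab %in% c(0, 1)) | is.na(lab))
  if (length(bad) > 0L) {
    stop(sprintf("non-binary label at manifest row %d (value '%s')", bad[1], lab[bad[1]]),
         call. = FALSE)
  }
  if (any(is.na(records$patient_id) | records$patient_id == "")) {
    stop("every manifest record needs a patient_id", call. = FALSE)
  }
  out <- data.frame(
    path = as.character(records$path),
    label = as.integer(lab),
    patient_id = as.character(records$patient_id),
    domain = as.character(records$domain),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' @rdname dataset_manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("unreadable manifest '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (nrow(df) == 0L) stop(sprintf("manifest '%s' has no records", path), call. = FALSE)
  if ("label" %in% names(df)) {
    lab <- suppressWarnings(as.numeric(df$label))
    bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary label at row %d of %s (value '%s')",
                   bad[1], path, df$label[bad[1]]), call. = FALSE)
    }
    df$label <- lab
  }
  dataset_manifest(df)
}

#' @rdname dataset_manifest
#' @param manifest a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
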