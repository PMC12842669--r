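#' Per-domain acquisition parameters for the phantom generator
#'
#' Emulates inter-site acquisition differences: after the anatomy is
#' composited, each pixel `p` (0–255) is mapped through a display/exposure
#' curve `clip(contrast_gain * 255 * (p/255)^gamma + brightness_offset +
#' noise)` with Gaussian read-out noise, then quantized to uint8. The
#' gamma-then-gain-then-offset order mimics exposure-curve versus
#' display-curve differences that histogram standardization should cancel
#' while leaving lesion structure intact.
#'
#' @param brightness_offset additive intensity offset (0–255 scale).
#' @param contrast_gain multiplicative gain, `> 0`.
#' @param gamma exponent of the intensity transfer curve, `> 0`.
#' @param noise_sd standard deviation of additive Gaussian noise, `>= 0`.
#' @return A `domain_params` list.
#' @export
domain_params <- function(brightness_offset = 0, contrast_gain = 1,
                          gamma = 1, noise_sd = 0) {
  stopifnot(contrast_gain > 0, gamma > 0, noise_sd >= 0)
  structure(list(brightness_offset = brightness_offset,
                 contrast_gain = contrast_gain,
                 gamma = gamma, noise_sd = noise_sd),
            class = "domain_params")
}

default_phantom_domains <- function(noise_sd = 3) {
  list(
    site_a = domain_params(0,   1.00, 1.00, noise_sd),
    site_b = domain_params(40,  0.90, 0.75, noise_sd),
    site_c = domain_params(-30, 1.15, 1.40, noise_sd)
  )
}

#' Phantom generator configuration
#'
#' Describes a stylized frontal chest radiograph: a dark background, two
#' bright lung-field ellipses, a central mediastinal column, a bright
#' neck/shoulder band across the top rows, a bright sub-diaphragmatic
#' (abdomen) band at the bottom, and dim lateral margins. Geometry is given
#' as fractions of the image size so any resolution works. The defaults are
#' chosen so that the default [crop_spec()] excises the shoulder band and
#' the lateral margins while retaining both lung bounding boxes (the
#' shoulder band fraction sits below the default `y_lo = 0.15` on a mass
#' basis).
#'
#' Abnormal images (label 1) receive 1–3 bright opacity disks placed inside
#' a lung ellipse.
#'
#' @param height,width image size in pixels.
#' @param intensities named list of base intensities (0–255) for
#'   `background`, `lateral`, `lung`, `mediastinum`, `shoulder`, `abdomen`.
#' @param lung_centers_x horizontal centers of the two lung ellipses
#'   (fractions of width).
#' @param lung_center_y,lung_semi_y,lung_semi_x lung ellipse geometry
#'   (fractions of the relevant dimension).
#' @param mediastinum_x `c(lo, hi)` column band of the mediastinum.
#' @param shoulder_frac top fraction of rows forming the shoulder band
#'   (must stay below the default vertical crop percentile of 0.15).
#' @param abdomen_frac bottom fraction of rows forming the abdomen band.
#' @param lateral_frac width fraction of each dim lateral margin.
#' @param lesion_count_range,lesion_radius_frac,lesion_delta lesion count
#'   range, radius range (fraction of `min(height, width)`), and additive
#'   intensity of the opacity disks.
#' @param domains named list of [domain_params()].
#' @param seed default seed for [generate_dataset()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(height = 64, width = 64,
                           intensities = list(background = 30, lateral = 8,
                                              lung = 170, mediastinum = 110,
                                              shoulder = 200, abdomen = 130),
                           lung_centers_x = c(0.32, 0.68),
                           lung_center_y = 0.55,
                           lung_semi_y = 0.28, lung_semi_x = 0.15,
                           mediastinum_x = c(0.44, 0.56),
                           shoulder_frac = 0.06,
                           abdomen_frac = 0.12,
                           lateral_frac = 0.08,
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_frac = c(0.04, 0.07),
                           lesion_delta = 55,
                           domains = default_phantom_domains(),
                           seed = 42L) {
  stopifnot(height >= 16, width >= 16, shoulder_frac < 0.15,
            length(domains) >= 1, !is.null(names(domains)))
  structure(list(height = height, width = width, intensities = intensities,
                 lung_centers_x = lung_centers_x, lung_center_y = lung_center_y,
                 lung_semi_y = lung_semi_y, lung_semi_x = lung_semi_x,
                 mediastinum_x = mediastinum_x, shoulder_frac = shoulder_frac,
                 abdomen_frac = abdomen_frac, lateral_frac = lateral_frac,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_frac = lesion_radius_frac,
                 lesion_delta = lesion_delta, domains = domains,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# deterministic anatomy, before lesions / domain transform; plain matrix 0-255
phantom_anatomy <- function(config) {
  h <- config$height; w <- config$width
  ints <- config$intensities
  m <- matrix(ints$background, h, w)

  lat <- max(1L, round(config$lateral_frac * w))
  m[, c(seq_len(lat), (w - lat + 1L):w)] <- ints$lateral

  med <- round(config$mediastinum_x * w)
  m[, max(1L, med[1]):min(w, med[2])] <- ints$mediastinum

  yy <- matrix(seq_len(h), h, w) / h         # fractional coords
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  for (cx in config$lung_centers_x) {
    inside <- ((yy - config$lung_center_y) / config$lung_semi_y)^2 +
              ((xx - cx) / config$lung_semi_x)^2 <= 1
    m[inside] <- ints$lung
  }

  sh <- max(1L, round(config$shoulder_frac * h))
  m[seq_len(sh), ] <- ints$shoulder
  ab <- max(1L, round(config$abdomen_frac * h))
  m[(h - ab + 1L):h, ] <- ints$abdomen
  m
}

# lesion mask for label-1 images; uses the current RNG stream
add_lesions <- function(m, config) {
  h <- nrow(m); w <- ncol(m)
  n_lesion <- sample(config$lesion_count_range[1]:config$lesion_count_range[2], 1L)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_lesion)) {
    cx_frac <- sample(config$lung_centers_x, 1L)
    # keep the disk center well inside the ellipse
    u <- stats::runif(1, -0.45, 0.45); v <- stats::runif(1, -0.45, 0.45)
    cy <- (config$lung_center_y + u * config$lung_semi_y) * h
    cx <- (cx_frac + v * config$lung_semi_x) * w
    r <- stats::runif(1, config$lesion_radius_frac[1], config$lesion_radius_frac[2]) *
      min(h, w)
    disk <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    m[disk] <- pmin(m[disk] + config$lesion_delta, 255)
  }
  m
}

apply_domain_transform <- function(m, dp) {
  out <- dp$contrast_gain * 255 * (m / 255)^dp$gamma + dp$brightness_offset
  if (dp$noise_sd > 0) {
    out <- out + stats::rnorm(length(out), sd = dp$noise_sd)
  }
  matrix(pmin(pmax(trunc(out + 0.5), 0), 255), nrow(m), ncol(m))
}

#' Generate one synthetic radiograph
#'
#' Composites the base anatomy of `config`, adds opacity lesions when
#' `label == 1`, applies the named domain's acquisition transform and
#' quantizes to uint8. Bit-identical output for identical arguments and
#' seed; the global RNG state is left untouched.
#'
#' @param config a [phantom_config()].
#' @param domain name of a domain in `config$domains`.
#' @param label 0 (normal) or 1 (abnormal).
#' @param seed integer seed for this image's randomness (lesion placement
#'   and noise).
#' @return A uint8 [gray_image()] with attributes `label` and `domain`.
#' @export
generate_phantom <- function(config, domain, label, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"), label %in% c(0, 1))
  if (!domain %in% names(config$domains)) {
    stop(sprintf("unknown domain '%s' (configured: %s)", domain,
                 paste(names(config$domains), collapse = ", ")), call. = FALSE)
  }
  # independent sub-streams for lesions and acquisition noise, so the same
  # seed with label 0 vs 1 differs only where lesions sit
  sub <- withr::with_seed(as.integer(seed),
                          sample.int(.Machine$integer.max - 1L, 2))
  m <- phantom_anatomy(config)
  if (label == 1) m <- withr::with_seed(sub[1], add_lesions(m, config))
  m <- withr::with_seed(sub[2],
                        apply_domain_transform(m, config$domains[[domain]]))
  img <- gray_image(m, depth = "uint8")
  attr(img, "label") <- as.integer(label)
  attr(img, "domain") <- domain
  img
}

#' Generate a multi-domain phantom dataset on disk
#'
#' Writes `n_per_domain` PNG phantoms per configured domain plus a
#' `manifest.csv` in the [dataset_manifest()] dialect. Class proportions per
#' domain follow `class_balance` to rounding (`n_pos = round(balance * n)`).
#' Synthetic patients contribute 1–3 images each so that patient-level
#' splitting is genuinely exercised; a patient's images share a domain. All
#' randomness flows from `seed`.
#'
#' @param config a [phantom_config()].
#' @param n_per_domain images per domain, `>= 2`.
#' @param class_balance fraction of abnormal (label 1) images per domain.
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return The [dataset_manifest()], invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config, n_per_domain, class_balance = 0.5,
                             seed = config$seed, dir = tempfile("phantom")) {
  stopifnot(inherits(config, "phantom_config"), n_per_domain >= 2)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output dir '%s'", dir), call. = FALSE)

  records <- withr::with_seed(as.integer(seed), {
    recs <- list()
    patient_counter <- 0L
    for (dom in names(config$domains)) {
      n_pos <- round(class_balance * n_per_domain)
      labels <- sample(c(rep(1L, n_pos), rep(0L, n_per_domain - n_pos)))
      # patients of size 1-3 within this domain
      pids <- character(0)
      while (length(pids) < n_per_domain) {
        patient_counter <- patient_counter + 1L
        sz <- sample(1:3, 1L)
        pids <- c(pids, rep(sprintf("p%04d", patient_counter), sz))
      }
      pids <- pids[seq_len(n_per_domain)]
      img_seeds <- sample.int(.Machine$integer.max - 1L, n_per_domain)
      for (i in seq_len(n_per_domain)) {
        path <- file.path(dir, sprintf("%s_%04d.png", dom, i))
        img <- generate_phantom(config, dom, labels[i], seed = img_seeds[i])
        write_gray(img, path)
        recs[[length(recs) + 1L]] <- data.frame(
          path = path, label = labels[i], patient_id = pids[i], domain = dom,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  })
  manifest <- dataset_manifest(records)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
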