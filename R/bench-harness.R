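#' Experiment configuration
#'
#' Defaults are the shared hyperparameters of the benchmark protocol: Adam
#' with learning rate 1e-4, batch size 100, at most 20 epochs, weight decay
#' 1e-5, an 80%/20% patient-level stratified train/validation split, three
#' fixed seeds (42, 123, 456) averaged in all reported tables, cross-entropy
#' loss, and 256 x 256 model input. The optimizer fields parameterize
#' gradient-trained classifiers plugged in via [classifier_contract()]; the
#' bundled closed-form fallbacks ignore them. Datasets smaller than one
#' batch use `min(batch_size, n_train)`.
#'
#' @param learning_rate,batch_size,max_epochs,weight_decay optimizer
#'   settings for gradient-based classifiers.
#' @param train_fraction training share of the patient-level split.
#' @param seeds integer vector of run seeds; reported results are means
#'   over these.
#' @param loss loss tag (`"cross_entropy"`).
#' @param input_size `c(height, width)` fed to the classifier after
#'   normalization.
#' @param augment apply geometric augmentation to training images? (Training
#'   only; validation is never augmented.)
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(learning_rate = 1e-4, batch_size = 100L,
                              max_epochs = 20L, weight_decay = 1e-5,
                              train_fraction = 0.8,
                              seeds = c(42L, 123L, 456L),
                              loss = "cross_entropy",
                              input_size = c(256L, 256L),
                              augment = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1, length(seeds) >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, weight_decay = weight_decay,
                 train_fraction = train_fraction, seeds = as.integer(seeds),
                 loss = loss, input_size = input_size, augment = augment),
            class = "experiment_config")
}

#' Patient-level stratified train/validation split
#'
#' Groups records by `patient_id` (a patient's images are never divided
#' across partitions; a patient with images in both classes is stratified by
#' their majority label, ties to abnormal), stratifies patients by label,
#' and assigns `round(train_fraction * n)` patients of each class to
#' training. Deterministic given `seed`.
#'
#' @param manifest a [dataset_manifest()].
#' @param train_fraction training share, in (0, 1).
#' @param seed integer seed.
#' @return List with `train` and `validation` manifests.
#' @export
stratified_group_split <- function(manifest, train_fraction = 0.8, seed = 42L) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            train_fraction > 0, train_fraction < 1)
  # patient-level label = majority vote, ties to positive
  pat_lab <- tapply(manifest$label, manifest$patient_id,
                    function(l) as.integer(mean(l) >= 0.5))
  pat_n <- table(manifest$patient_id)

  for (cls in c(0L, 1L)) {
    idx <- manifest$label == cls
    if (!any(idx)) next
    share <- max(table(manifest$patient_id[idx])) / sum(idx)
    if (share > max(train_fraction, 1 - train_fraction)) {
      stop(sprintf(
        "infeasible split: one patient holds %.0f%% of class-%d images",
        100 * share, cls), call. = FALSE)
    }
  }

  train_patients <- withr::with_seed(as.integer(seed), {
    unlist(lapply(c(0L, 1L), function(cls) {
      pats <- names(pat_lab)[pat_lab == cls]
      if (length(pats) == 0L) return(character(0))
      pats <- sample(pats)
      n_train <- round(train_fraction * length(pats))
      n_train <- min(max(n_train, 1L), length(pats) - 1L)  # both sides non-empty
      pats[seq_len(n_train)]
    }))
  })
  in_train <- manifest$patient_id %in% train_patients
  list(train = dataset_manifest(manifest[in_train, , drop = FALSE]),
       validation = dataset_manifest(manifest[!in_train, , drop = FALSE]))
}

#' Geometric training augmentation
#'
#' One combined affine pass per image: horizontal flip with probability 0.5,
#' rotation uniform in \[-7, +7\] degrees, isotropic scaling uniform in
#' \[0.9, 1.1\], and per-axis translation uniform in +/-5% of the image
#' dimensions (applied in that order: flip, rotate, scale, translate, about
#' the image center, single bilinear resampling). No intensity-changing
#' operation is ever applied; regions mapped from outside the frame are
#' filled with the image's minimum intensity, and the output size equals the
#' input size.
#'
#' @param image a [gray_image()] (any depth).
#' @param seed integer seed for the four draws; ignored when `draws` given.
#' @param draws optional list `(flip, angle_deg, scale, shift)` overriding
#'   the random draws (e.g. `list(flip = FALSE, angle_deg = 0, scale = 1,
#'   shift = c(0, 0))` forces the identity).
#' @return A [gray_image()] of the same size (depth `standardized` when
#'   interpolation leaves non-integer values on a uint8 input).
#' @export
augment_geometric <- function(image, seed = NULL, draws = NULL) {
  stopifnot(is_gray_image(image))
  if (is.null(draws)) {
    draws <- withr::with_seed(as.integer(seed), list(
      flip = stats::runif(1) < 0.5,
      angle_deg = stats::runif(1, -7, 7),
      scale = stats::runif(1, 0.9, 1.1),
      shift = stats::runif(2, -0.05, 0.05)
    ))
  }
  m <- as_pixel_matrix(image)
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  theta <- draws$angle_deg * pi / 180
  tx <- draws$shift[2] * w; ty <- draws$shift[1] * h

  # inverse map: output pixel -> source coordinate
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  Y <- matrix(seq_len(h), h, w) - cy
  u <- (X - tx) / draws$scale
  v <- (Y - ty) / draws$scale
  us <- cos(theta) * u + sin(theta) * v
  vs <- -sin(theta) * u + cos(theta) * v
  if (isTRUE(draws$flip)) us <- -us
  xs <- us + cx; ys <- vs + cy

  fill <- min(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  sample_at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out <- matrix(fill, h, w)
    out[ok] <- m[cbind(yy[ok], xx[ok])]
    out
  }
  out <- sample_at(y0, x0) * (1 - fy) * (1 - fx) +
         sample_at(y0, x0 + 1) * (1 - fy) * fx +
         sample_at(y0 + 1, x0) * fy * (1 - fx) +
         sample_at(y0 + 1, x0 + 1) * fy * fx

  depth <- img_depth(image)
  if (depth == "uint8" && any(out != round(out))) depth <- "standardized"
  if (depth == "unit") out <- pmin(pmax(out, 0), 1)
  gray_image(out, depth = depth)
}

# Normalize one uint8 image for model input: returns a plain numeric matrix
# of size config$input_size. `stats` (dataset-level) is required for the
# zscore method and must be fitted on training images only.
normalize_for_model <- function(image, spec, input_size, stats = NULL) {
  resize_plain <- function(img) {
    as_pixel_matrix(resize_bilinear(img, input_size[1], input_size[2]))
  }
  switch(spec$method,
    scaling = resize_plain(minmax_scale(image)),
    zscore = {
      if (spec$per_image_zscore) {
        m <- as_pixel_matrix(image)
        mom <- image_moments(m)
        if (mom$sigma == 0) stop("degenerate image: zero variance", call. = FALSE)
        resize_plain(gray_image((m - mom$mu) / mom$sigma, depth = "standardized"))
      } else {
        if (is.null(stats)) stop("zscore needs fitted dataset_stats", call. = FALSE)
        resize_plain(zscore_apply(image, stats))
      }
    },
    adaptive = {
      sp <- spec; sp$output_size <- input_size
      as_pixel_matrix(adaptive_normalize(image, sp)$image) / 255
    },
    crop_only = ,
    hist_only = {
      sp <- spec; sp$output_size <- input_size
      as_pixel_matrix(ablation_variant(image, sp)) / 255
    },
    stop(sprintf("unknown normalization method '%s'", spec$method), call. = FALSE)
  )
}

cross_entropy_loss <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a classifier under one normalization method and evaluate it
#'
#' Loads the images of both partitions, fits any normalization artifacts on
#' the training partition only (dataset-level Z-score statistics never see
#' validation pixels), applies the normalization method identically to both
#' partitions, optionally augments the training images (geometric only),
#' fits the classifier inside a seeded RNG scope, and evaluates accuracy,
#' F1, sensitivity, specificity and mean validation cross-entropy. A
#' non-finite loss is flagged (`status = "diverged"`) rather than silently
#' propagated.
#'
#' @param train,validation [dataset_manifest()]s (no shared patients).
#' @param classifier a [classifier_contract()].
#' @param method_spec a [normalization_spec()].
#' @param config an [experiment_config()].
#' @param seed integer run seed.
#' @return A one-row data frame: `accuracy`, `f1`, `loss`, `sensitivity`,
#'   `specificity`, `status`, plus attribute `fit_stats` (the dataset stats
#'   used, for audit).
#' @export
train_and_evaluate <- function(train, validation, classifier, method_spec,
                               config = experiment_config(), seed = 42L) {
  stopifnot(inherits(classifier, "radnorm_classifier"),
            inherits(method_spec, "normalization_spec"))
  overlap <- intersect(train$patient_id, validation$patient_id)
  if (length(overlap) > 0L) {
    stop(sprintf("patient leakage between partitions: %s",
                 paste(utils::head(overlap, 3), collapse = ", ")), call. = FALSE)
  }
  train_imgs <- lapply(train$path, read_gray)
  val_imgs <- lapply(validation$path, read_gray)

  stats <- NULL
  if (method_spec$method == "zscore" && !method_spec$per_image_zscore) {
    stats <- zscore_fit(train_imgs)              # training partition only
  }
  Xtr <- lapply(train_imgs, normalize_for_model, spec = method_spec,
                input_size = config$input_size, stats = stats)
  Xva <- lapply(val_imgs, normalize_for_model, spec = method_spec,
                input_size = config$input_size, stats = stats)
  if (isTRUE(config$augment)) {
    aug_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max - 1L, length(Xtr)))
    Xtr <- mapply(function(m, s) {
      as_pixel_matrix(augment_geometric(gray_image(m, depth = "standardized"),
                                        seed = s))
    }, Xtr, aug_seeds, SIMPLIFY = FALSE)
  }

  state <- withr::with_seed(as.integer(seed),
                            classifier$fit(Xtr, train$label, config))
  proba <- classifier$predict_proba(state, Xva)
  loss <- cross_entropy_loss(validation$label, proba)
  mets <- metrics(confusion(validation$label, as.integer(proba >= 0.5)))

  out <- data.frame(accuracy = mets$accuracy, f1 = mets$f1, loss = loss,
                    sensitivity = mets$sensitivity,
                    specificity = mets$specificity,
                    status = if (is.finite(loss)) "ok" else "diverged",
                    stringsAsFactors = FALSE)
  attr(out, "fit_stats") <- stats
  out
}

resolve_method_specs <- function(methods) {
  if (is.character(methods)) {
    specs <- lapply(methods, normalization_spec)
    names(specs) <- methods
  } else {
    specs <- methods
    stopifnot(all(vapply(specs, inherits, logical(1), "normalization_spec")))
    if (is.null(names(specs))) {
      names(specs) <- vapply(specs, `[[`, character(1), "method")
    }
  }
  specs
}

#' Run the full factorial benchmark matrix
#'
#' Executes every dataset x normalization method x model combination over
#' all configured seeds (e.g. 4 datasets x 3 methods x 3 models = 36
#' configurations, 108 runs at 3 seeds), each run on a fresh patient-level
#' stratified split. Failed runs are recorded with a failure tag instead of
#' aborting the matrix. Returns the long results table plus seed-averaged
#' pivot tables (one per metric) shaped dataset-by-model rows x method
#' columns.
#'
#' @param datasets named list of [dataset_manifest()]s.
#' @param methods character vector of method tags or named list of
#'   [normalization_spec()]s (must be distinct).
#' @param models named list of [classifier_contract()]s (must be distinct).
#' @param config an [experiment_config()].
#' @param out optional directory: writes `results.csv` and
#'   `pivot_<metric>.csv` files.
#' @return List with `results` (long data frame: dataset, method, model,
#'   seed, metrics, status), `pivots` (named list of wide data frames),
#'   `n_configurations`, and `coverage` (fraction of runs with status
#'   `"ok"`).
#' @export
run_matrix <- function(datasets, methods, models, config = experiment_config(),
                       out = NULL) {
  specs <- resolve_method_specs(methods)
  if (anyDuplicated(names(specs))) stop("duplicate methods in matrix", call. = FALSE)
  if (is.null(names(datasets)) || anyDuplicated(names(datasets))) {
    stop("datasets must be uniquely named", call. = FALSE)
  }
  if (is.null(names(models)) || anyDuplicated(names(models))) {
    stop("models must be uniquely named", call. = FALSE)
  }

  rows <- list()
  for (ds in names(datasets)) {
    for (met in names(specs)) {
      for (mod in names(models)) {
        for (seed in config$seeds) {
          split <- stratified_group_split(datasets[[ds]],
                                          config$train_fraction, seed)
          run <- tryCatch(
            train_and_evaluate(split$train, split$validation, models[[mod]],
                               specs[[met]], config, seed),
            error = function(e) {
              data.frame(accuracy = NA_real_, f1 = NA_real_, loss = NA_real_,
                         sensitivity = NA_real_, specificity = NA_real_,
                         status = paste0("failed: ", conditionMessage(e)),
                         stringsAsFactors = FALSE)
            })
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(dataset = ds, method = met, model = mod, seed = seed,
                       stringsAsFactors = FALSE), run)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  n_conf <- length(datasets) * length(specs) * length(models)

  pivots <- lapply(c("accuracy", "f1", "loss"), function(metric) {
    agg <- stats::aggregate(results[[metric]],
                            by = list(dataset = results$dataset,
                                      model = results$model,
                                      method = results$method),
                            FUN = mean)
    stats::reshape(agg, idvar = c("dataset", "model"), timevar = "method",
                   direction = "wide", v.names = "x") |>
      (\(d) { names(d) <- sub("^x\\.", "", names(d)); rownames(d) <- NULL; d })()
  })
  names(pivots) <- c("accuracy", "f1", "loss")

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out, "results.csv"), row.names = FALSE)
    for (metric in names(pivots)) {
      utils::write.csv(pivots[[metric]],
                       file.path(out, sprintf("pivot_%s.csv", metric)),
                       row.names = FALSE)
    }
  }
  list(results = results, pivots = pivots, n_configurations = n_conf,
       coverage = mean(results$status == "ok"))
}

#' Ablation study of the adaptive pipeline components
#'
#' Four conditions on one dataset and model: (A) Z-score baseline — neither
#' adaptive component; (B) percentile cropping only; (C) histogram
#' standardization only; (D) the full adaptive pipeline. Reports the
#' seed-averaged F1 per condition with component indicator columns.
#'
#' @param dataset a [dataset_manifest()].
#' @param model a [classifier_contract()].
#' @param config an [experiment_config()].
#' @return Data frame with columns `condition` (A–D), `method`, `cropping`,
#'   `histogram`, `f1`.
#' @export
ablation_matrix <- function(dataset, model, config = experiment_config()) {
  conditions <- data.frame(
    condition = c("A", "B", "C", "D"),
    method = c("zscore", "crop_only", "hist_only", "adaptive"),
    cropping = c(FALSE, TRUE, FALSE, TRUE),
    histogram = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- run_matrix(list(dataset = dataset), conditions$method,
                    stats::setNames(list(model), model$name), config)
  f1 <- stats::aggregate(f1 ~ method, data = res$results, FUN = mean)
  conditions$f1 <- f1$f1[match(conditions$method, f1$method)]
  conditions
}

#' Cross-domain benchmark on phantom data
#'
#' The stress test for normalization under domain shift: generates a
#' multi-site phantom dataset, trains on all source domains and validates on
#' one held-out domain (so the validation intensity distribution is shifted
#' relative to training), for every requested normalization method and seed.
#' A fresh dataset is generated per seed so both the phantom sampling and
#' the classifier see independent replicates.
#'
#' @param methods character vector or named list of [normalization_spec()]s.
#' @param classifier a [classifier_contract()].
#' @param phantom a [phantom_config()].
#' @param n_per_domain images generated per domain per seed.
#' @param holdout_domain validation domain name (default: last configured).
#' @param config an [experiment_config()].
#' @param seeds integer seeds (defaults to `config$seeds`).
#' @return Long results data frame (method, seed, metrics, status).
#' @export
domain_shift_benchmark <- function(methods, classifier,
                                   phantom = phantom_config(),
                                   n_per_domain = 200L,
                                   holdout_domain = NULL,
                                   config = experiment_config(input_size = c(64L, 64L)),
                                   seeds = config$seeds) {
  specs <- resolve_method_specs(methods)
  if (is.null(holdout_domain)) {
    holdout_domain <- names(phantom$domains)[length(phantom$domains)]
  }
  stopifnot(holdout_domain %in% names(phantom$domains))

  rows <- list()
  for (seed in seeds) {
    manifest <- generate_dataset(phantom, n_per_domain, seed = seed)
    val_idx <- manifest$domain == holdout_domain
    train <- dataset_manifest(manifest[!val_idx, , drop = FALSE])
    val <- dataset_manifest(manifest[val_idx, , drop = FALSE])
    for (met in names(specs)) {
      run <- train_and_evaluate(train, val, classifier, specs[[met]],
                                config, seed)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(method = met, seed = seed, holdout = holdout_domain,
                   stringsAsFactors = FALSE), run)
    }
    unlink(dirname(manifest$path[1]), recursive = TRUE)
  }
  do.call(rbind, rows)
}
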