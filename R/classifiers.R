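#' Classifier contract
#'
#' A classifier is a list with fields
#' * `name` — label used in results tables;
#' * `fit(images, labels, config)` — returns an opaque trained state;
#'   `images` is a list of equally sized numeric matrices (already
#'   normalized), `labels` a 0/1 vector, `config` an [experiment_config()].
#'   Called inside a seeded RNG scope, so any internal randomness is
#'   reproducible;
#' * `predict_proba(state, images)` — class-1 probabilities in \[0, 1\].
#'
#' A deep CNN (the reference architecture is a three-stage
#' convolution/ReLU/max-pool network with two fully connected layers and a
#' softmax head, ~1.2 M parameters) plugs in behind the same contract; no
#' deep-learning runtime ships with this package, so the bundled
#' implementations are fast deterministic fallbacks.
#'
#' @param name classifier label.
#' @param fit,predict_proba functions as described above.
#' @return A `radnorm_classifier` list.
#' @export
classifier_contract <- function(name, fit, predict_proba) {
  stopifnot(is.character(name), is.function(fit), is.function(predict_proba))
  structure(list(name = name, fit = fit, predict_proba = predict_proba),
            class = "radnorm_classifier")
}

#' Majority-class dummy classifier
#'
#' Predicts the training majority class for every sample (ties break to the
#' negative class, so a balanced split yields no positive predictions and an
#' undefined F1). Useful for bookkeeping tests and as a performance floor.
#'
#' @return A [classifier_contract()].
#' @export
classifier_dummy <- function() {
  classifier_contract(
    name = "dummy",
    fit = function(images, labels, config) {
      list(majority = as.integer(mean(labels) > 0.5))
    },
    predict_proba = function(state, images) {
      rep(as.numeric(state$majority), length(images))
    }
  )
}

#' Ridge-regression fallback classifier
#'
#' The desk-scale stand-in for the reference CNN: each image is bilinearly
#' downsampled to `feature_size` x `feature_size`, flattened, and a ridge
#' (L2-regularized least squares) model is fit on the 0/1 labels in closed
#' form. Predicted scores are clipped to \[0, 1\] and read as class-1
#' probabilities. Fully deterministic, trains in milliseconds, and —
#' because it has no normalization of its own — faithfully transmits
#' whatever intensity shifts preprocessing leaves in the data.
#'
#' @param feature_size side length of the downsampled feature grid.
#' @param lambda ridge penalty.
#' @return A [classifier_contract()].
#' @export
classifier_ridge <- function(feature_size = 16L, lambda = 1) {
  featurize <- function(images) {
    t(vapply(images, function(m) {
      img <- gray_image(m, depth = "standardized")
      as.numeric(as_pixel_matrix(resize_bilinear(img, feature_size, feature_size)))
    }, numeric(feature_size * feature_size)))
  }
  classifier_contract(
    name = "ridge",
    fit = function(images, labels, config) {
      X <- cbind(1, featurize(images))
      A <- crossprod(X)
      diag(A)[-1] <- diag(A)[-1] + lambda        # do not penalize the intercept
      beta <- solve(A, crossprod(X, labels))
      list(beta = beta)
    },
    predict_proba = function(state, images) {
      X <- cbind(1, featurize(images))
      pmin(pmax(as.numeric(X %*% state$beta), 0), 1)
    }
  )
}

#' Contrast-threshold classifier
#'
#' Scores each image by the gap between a high intensity quantile and the
#' median (lesion disks are bright local outliers), then learns the
#' accuracy-maximizing threshold on the training scores. On noise-free
#' single-domain phantoms this separates the classes perfectly, which makes
#' it the "perfect oracle" end of the classifier spectrum for harness tests.
#'
#' @param q upper quantile used for the contrast score.
#' @return A [classifier_contract()].
#' @export
classifier_contrast <- function(q = 0.995) {
  score <- function(images) {
    vapply(images, function(m) {
      stats::quantile(m, q, names = FALSE) - stats::median(m)
    }, numeric(1))
  }
  classifier_contract(
    name = "contrast",
    fit = function(images, labels, config) {
      s <- score(images)
      cand <- sort(unique(s))
      thr <- if (length(cand) == 1L) cand else {
        mids <- (cand[-1] + cand[-length(cand)]) / 2
        acc <- vapply(mids, function(t) mean((s > t) == labels), numeric(1))
        mids[which.max(acc)]
      }
      list(threshold = thr)
    },
    predict_proba = function(state, images) {
      as.numeric(score(images) > state$threshold)
    }
  )
}
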