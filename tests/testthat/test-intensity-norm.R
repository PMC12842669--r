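test_that("minmax_scale divides by the fixed 255 range", {
  img <- gray_image(matrix(c(0, 51, 128, 255), 2, 2), depth = "uint8")
  out <- minmax_scale(img)
  expect_equal(as.numeric(unclass(out)), c(0, 51, 128, 255) / 255)
  expect_identical(img_depth(out), "unit")
  # constant image: no degenerate division, unlike per-image min-max
  const <- minmax_scale(gray_image(matrix(128, 3, 3), depth = "uint8"))
  expect_equal(unique(as.numeric(unclass(const))), 128 / 255)
  expect_error(minmax_scale(const), "uint8")
})

test_that("zscore_fit pools pixels over all images with population sd", {
  one <- gray_image(matrix(0, 1, 1), depth = "uint8")
  two <- gray_image(matrix(2, 1, 1), depth = "uint8")
  st <- zscore_fit(list(one, two))
  expect_equal(st$mu_global, 1)
  expect_equal(st$sigma_global, 1)
  expect_equal(st$n_images, 2L)

  # pooled-pixel oracle over the 4 pixels of [[0,0]] and [[2,4]]
  imgs <- list(gray_image(matrix(c(0, 0), 1), depth = "uint8"),
               gray_image(matrix(c(2, 4), 1), depth = "uint8"))
  st <- zscore_fit(imgs)
  px <- c(0, 0, 2, 4)
  expect_equal(st$mu_global, mean(px))
  expect_equal(st$sigma_global, sqrt(mean((px - mean(px))^2)))

  degenerate <- zscore_fit(list(gray_image(matrix(7, 2, 2), depth = "uint8")))
  expect_equal(degenerate$sigma_global, 0)
  expect_error(zscore_apply(one, degenerate), "degenerate")
})

test_that("zscore_apply centers and scales by the dataset statistics", {
  st <- structure(list(mu_global = 100, sigma_global = 50, n_images = 1L),
                  class = "dataset_stats")
  img <- gray_image(matrix(c(100, 200, 0, 150), 2, 2), depth = "uint8")
  out <- zscore_apply(img, st)
  expect_equal(as.numeric(unclass(out)), c(0, 2, -2, 1))
  expect_identical(img_depth(out), "standardized")
  # identity stats leave the image unchanged; monotone map preserves ranks
  ident <- structure(list(mu_global = 0, sigma_global = 1, n_images = 1L),
                     class = "dataset_stats")
  expect_equal(unclass(zscore_apply(img, ident))[, ], unclass(img)[, ])
  expect_equal(rank(as.numeric(unclass(out))), rank(as.numeric(unclass(img))))
})

test_that("histogram_standardize maps [0, 100] to the derived pre-clip values", {
  img <- gray_image(matrix(c(0, 100), 1), depth = "uint8")
  out <- histogram_standardize(img, clip = FALSE)
  # mu_orig = 50, sigma_orig = 50: frozen from direct evaluation of the map
  expect_equal(as.numeric(unclass(out)), c(64.719, 178.857))
})

test_that("histogram_standardize recovers the target moments exactly pre-clip", {
  withr::local_seed(21)
  params <- standardization_params()
  for (i in 1:40) {
    img <- rand_uint8_image(sample(2:30, 1), sample(2:30, 1))
    if (sd(unclass(img)) == 0) next
    out <- unclass(histogram_standardize(img, params, clip = FALSE))
    sigma <- sqrt(mean((out - mean(out))^2))
    expect_lt(abs(mean(out) - params$mu_target) / params$mu_target, 1e-9)
    expect_lt(abs(sigma - params$sigma_target) / params$sigma_target, 1e-9)
  }
})

test_that("histogram_standardize is idempotent and affine-invariant pre-clip", {
  withr::local_seed(22)
  params <- standardization_params()
  for (i in 1:15) {
    img <- rand_uint8_image(12, 10)
    once <- histogram_standardize(img, params, clip = FALSE)
    twice <- histogram_standardize(once, params, clip = FALSE)
    expect_equal(unclass(twice)[, ], unclass(once)[, ], tolerance = 1e-12)
    # positive affine intensity changes cancel
    a <- runif(1, 0.2, 1.4); b <- runif(1, -30, 30)
    shifted <- gray_image(a * unclass(img)[, ] + b, depth = "standardized")
    expect_equal(unclass(histogram_standardize(shifted, params, clip = FALSE))[, ],
                 unclass(once)[, ], tolerance = 1e-9)
  }
})

test_that("a constant image maps uniformly to the target mean", {
  const <- gray_image(matrix(7, 4, 4), depth = "uint8")
  out <- histogram_standardize(const)
  expect_equal(unique(as.numeric(unclass(out))), standardization_params()$mu_target)
})

test_that("adaptive_normalize composes crop, standardization and quantization", {
  img <- gray_image(matrix(50, 100, 100), depth = "uint8")
  res <- adaptive_normalize(img)
  expect_equal(dim(res$image), c(80L, 90L))
  expect_equal(unique(as.numeric(unclass(res$image))), 122)  # round(121.788)
  expect_equal(unname(res$crop$window), c(5L, 94L, 15L, 94L))

  # full-extent crop makes adaptive coincide with hist_only
  withr::local_seed(30)
  noisy <- gray_image(matrix(sample(1:255, 400, replace = TRUE), 20, 20),
                      depth = "uint8")
  full <- normalization_spec("adaptive", crop = crop_spec(0, 1, 0, 1))
  expect_identical(unclass(adaptive_normalize(noisy, full)$image)[, ],
                   unclass(ablation_variant(noisy, normalization_spec("hist_only")))[, ])
})

test_that("ablation variants isolate the two pipeline components", {
  img <- gray_image(matrix(50, 100, 100), depth = "uint8")
  cropped <- ablation_variant(img, normalization_spec("crop_only"))
  expect_equal(dim(cropped), c(80L, 90L))
  expect_equal(unique(as.numeric(unclass(cropped))), 50)  # pure selection

  const <- ablation_variant(gray_image(matrix(9, 5, 5), depth = "uint8"),
                            normalization_spec("hist_only"))
  expect_equal(unique(as.numeric(unclass(const))), 122)
  expect_error(ablation_variant(img, normalization_spec("adaptive")), "crop_only")
})

test_that("resize_bilinear follows the corner-aligned convention", {
  img <- rand_uint8_image(8, 6)
  expect_identical(resize_bilinear(img, 8, 6), img)          # identity

  const <- gray_image(matrix(3, 2, 2), depth = "uint8")
  big <- resize_bilinear(const, 9, 13)
  expect_equal(unique(as.numeric(unclass(big))), 3)          # constant preserved

  # 2x1 column [0, 255] -> 4x1: source coords 0, 1/3, 2/3, 1
  col <- gray_image(matrix(c(0, 255), 2, 1), depth = "uint8")
  out <- resize_bilinear(col, 4, 1)
  expect_equal(as.numeric(unclass(out)), c(0, 85, 170, 255))
  expect_error(resize_bilinear(img, 0, 5), ">= 1")
})

test_that("adaptive normalization collapses inter-domain brightness dispersion", {
  cfg <- phantom_config()
  man <- generate_dataset(cfg, n_per_domain = 30L, seed = 7L,
                          dir = withr::local_tempdir())
  imgs <- lapply(man$path, read_gray)
  mean_minmax <- vapply(imgs, function(i) mean(unclass(minmax_scale(i))), numeric(1))
  mean_adapt <- vapply(imgs, function(i)
    mean(unclass(adaptive_normalize(i)$image)) / 255, numeric(1))
  between_var <- function(x) var(tapply(x, man$domain, mean))
  expect_lt(between_var(mean_adapt), 0.01 * between_var(mean_minmax))
})
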