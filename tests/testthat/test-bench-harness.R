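make_manifest <- function(labels, patients, domains = "d1", paths = NULL) {
  dataset_manifest(data.frame(
    path = paths %||% sprintf("img%02d.png", seq_along(labels)),
    label = labels, patient_id = patients, domain = domains))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stratified_group_split respects patients and class balance", {
  man <- make_manifest(rep(c(0, 1), each = 5), sprintf("p%d", 1:10))
  sp <- stratified_group_split(man, 0.8, seed = 1L)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$validation), 2L)
  expect_equal(as.numeric(table(sp$train$label)), c(4, 4))
  expect_equal(as.numeric(table(sp$validation$label)), c(1, 1))
  expect_length(intersect(sp$train$patient_id, sp$validation$patient_id), 0L)

  # determinism
  sp2 <- stratified_group_split(man, 0.8, seed = 1L)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))

  # a patient with images in both classes is never divided
  mixed <- make_manifest(c(0, 1, 1, 0, 1, 0, 1, 0, 1, 0),
                         c("pa", "pa", sprintf("p%d", 2:9)))
  for (s in 1:5) {
    spm <- stratified_group_split(mixed, 0.8, seed = s)
    expect_length(intersect(spm$train$patient_id, spm$validation$patient_id), 0L)
    pa_side <- c("pa" %in% spm$train$patient_id, "pa" %in% spm$validation$patient_id)
    expect_equal(sum(pa_side), 1L)
  }
})

test_that("an overweight patient makes the split infeasible", {
  man <- make_manifest(c(rep(1, 9), 0, 0),
                       c(rep("whale", 9), "p1", "p2"))
  expect_error(stratified_group_split(man, 0.8, 1L), "infeasible")
})

test_that("augment_geometric applies purely geometric, size-preserving maps", {
  img <- rand_uint8_image(20, 24)
  identity_draws <- list(flip = FALSE, angle_deg = 0, scale = 1, shift = c(0, 0))
  expect_equal(unclass(augment_geometric(img, draws = identity_draws))[, ],
               unclass(img)[, ])

  const <- gray_image(matrix(99, 16, 16), depth = "uint8")
  out <- augment_geometric(const, seed = 5L)
  # constant in, constant out (up to interpolation round-off)
  expect_true(all(abs(unclass(out) - 99) < 1e-9))
  expect_equal(dim(out), dim(const))

  flip_draws <- list(flip = TRUE, angle_deg = 0, scale = 1, shift = c(0, 0))
  flipped_twice <- augment_geometric(augment_geometric(img, draws = flip_draws),
                                     draws = flip_draws)
  expect_equal(unclass(flipped_twice)[, ], unclass(img)[, ])  # involution

  expect_identical(unclass(augment_geometric(img, seed = 7L))[, ],
                   unclass(augment_geometric(img, seed = 7L))[, ])
})

test_that("train_and_evaluate honors the classifier contract and fit isolation", {
  man <- tiny_manifest(n = 16L, seed = 2L)
  sp <- stratified_group_split(man, 0.75, seed = 2L)
  cfg <- experiment_config(input_size = c(32L, 32L))

  run <- train_and_evaluate(sp$train, sp$validation, classifier_dummy(),
                            normalization_spec("scaling"), cfg, seed = 42L)
  expect_identical(run$status, "ok")
  # dummy predicts one class everywhere: accuracy is the majority share
  maj <- max(table(sp$validation$label)) / nrow(sp$validation)
  expect_true(run$accuracy %in% c(maj, 1 - maj))

  # noise-free phantoms + contrast classifier = perfect separation
  clean <- generate_dataset(
    phantom_config(domains = list(site = domain_params(noise_sd = 0))),
    n_per_domain = 16L, seed = 3L, dir = withr::local_tempdir())
  spc <- stratified_group_split(clean, 0.75, seed = 3L)
  oracle <- train_and_evaluate(spc$train, spc$validation, classifier_contrast(),
                               normalization_spec("scaling"), cfg, seed = 42L)
  expect_equal(oracle$accuracy, 1)
  expect_equal(oracle$f1, 1)

  # z-score statistics are fitted on training pixels only
  zrun <- train_and_evaluate(sp$train, sp$validation, classifier_dummy(),
                             normalization_spec("zscore"), cfg, seed = 42L)
  fit_stats <- attr(zrun, "fit_stats")
  ref <- zscore_fit(lapply(sp$train$path, read_gray))
  expect_equal(fit_stats$mu_global, ref$mu_global)
  expect_equal(fit_stats$n_images, nrow(sp$train))

  # patient leakage is rejected outright
  expect_error(train_and_evaluate(sp$train, sp$train, classifier_dummy(),
                                  normalization_spec("scaling"), cfg, 42L),
               "leakage")
})

test_that("run_matrix enumerates the factorial design deterministically", {
  man <- tiny_manifest(n = 12L, seed = 4L)
  cfg <- experiment_config(input_size = c(32L, 32L), seeds = 42L)
  res <- run_matrix(list(ds = man), c("scaling", "zscore", "adaptive"),
                    list(dummy = classifier_dummy()), cfg)
  expect_equal(res$n_configurations, 3L)
  expect_equal(nrow(res$results), 3L)
  expect_named(res$pivots, c("accuracy", "f1", "loss"))
  expect_equal(res$coverage, 1)

  res2 <- run_matrix(list(ds = man), c("scaling", "zscore", "adaptive"),
                     list(dummy = classifier_dummy()), cfg)
  expect_identical(res$results, res2$results)   # bit-identical re-run

  expect_error(run_matrix(list(ds = man), c("scaling", "scaling"),
                          list(dummy = classifier_dummy()), cfg),
               "duplicate")
})

test_that("ablation_matrix reports the four component conditions", {
  man <- tiny_manifest(n = 12L, seed = 5L)
  cfg <- experiment_config(input_size = c(32L, 32L), seeds = 42L)
  tab <- ablation_matrix(man, classifier_ridge(feature_size = 8L), cfg)
  expect_equal(tab$condition, c("A", "B", "C", "D"))
  expect_equal(tab$method, c("zscore", "crop_only", "hist_only", "adaptive"))
  expect_equal(tab$cropping, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(tab$histogram, c(FALSE, FALSE, TRUE, TRUE))
  # condition D is exactly a run of the adaptive method
  ref <- run_matrix(list(dataset = man), "adaptive",
                    list(ridge = classifier_ridge(feature_size = 8L)), cfg)
  expect_equal(tab$f1[4], mean(ref$results$f1))
})
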