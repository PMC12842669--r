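test_that("wilcoxon handles the canonical exact cases", {
  # 8 same-sign differences of distinct magnitude: two-sided p = 2/256
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  y <- x - c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$p_value, 2 / 256)
  expect_equal(res$statistic, 0)           # W- = 0
  expect_equal(res$n_effective, 8L)
  expect_identical(res$exact_flag, "exact")

  tie <- wilcoxon_signed_rank(c(1, 0), c(0, 1))   # d = (+1, -1), tied |d|
  expect_equal(tie$p_value, 1)

  same <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$n_effective, 0L)
})

test_that("exact p-values match full sign enumeration for n <= 12", {
  withr::local_seed(55)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    # integer scores force frequent zeros and ties, the hard cases
    x <- sample(0:6, n, replace = TRUE)
    y <- sample(0:6, n, replace = TRUE)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(x, y, alternative = alt)$p_value
      expect_equal(got, enum_signed_rank_p(x - y, alt),
                   info = sprintf("n=%d alt=%s", n, alt))
    }
    two <- wilcoxon_signed_rank(x, y)$p_value
    one <- min(wilcoxon_signed_rank(x, y, "greater")$p_value,
               wilcoxon_signed_rank(x, y, "less")$p_value)
    expect_gte(two, one)
    expect_true(two >= 0 && two <= 1)
  }
})

test_that("the normal-approximation path engages above the exactness bound", {
  withr::local_seed(56)
  x <- rnorm(40); y <- rnorm(40)
  res <- wilcoxon_signed_rank(x, y)
  expect_identical(res$exact_flag, "normal_approx")
  # agrees with the tie-corrected large-sample reference
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("friedman reproduces the closed form and the rank-based oracle", {
  ordered3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  res <- friedman(ordered3)
  expect_equal(res$statistic, 6)
  expect_equal(res$rank_sums, c(3, 6, 9), ignore_attr = TRUE)

  flat <- friedman(matrix(5, 4, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  withr::local_seed(77)
  for (i in 1:10) {
    m <- matrix(runif(36), 12, 3)            # continuous, so tie-free
    res <- friedman(m)
    ref <- stats::friedman.test(m)           # independent base-R oracle
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
    # invariant under a strictly monotone transform of the scores
    expect_equal(friedman(exp(2 * m))$statistic, res$statistic)
  }
})

test_that("nemenyi_cd evaluates the embedded q table", {
  expect_equal(nemenyi_cd(3, 12), 2.343 * sqrt(3 * 4 / (6 * 12)))
  expect_equal(nemenyi_cd(2, 10, alpha = 0.1), 1.645 * sqrt(2 * 3 / 60))
  # monotone decreasing in n
  cds <- vapply(c(5, 10, 50, 500), function(n) nemenyi_cd(4, n), numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_error(nemenyi_cd(11, 10), "table bounds")
  expect_error(nemenyi_cd(3, 10, alpha = 0.2), "table bounds")
})

test_that("compare_methods runs the three-stage procedure", {
  withr::local_seed(88)
  # one treatment dominating every block wins all pairwise comparisons
  base <- matrix(runif(24, 0.5, 0.7), 12, 2)
  mat <- cbind(base, best = apply(base, 1, max) + runif(12, 0.01, 0.05))
  colnames(mat) <- c("scaling", "zscore", "adaptive")
  res <- compare_methods(mat)
  expect_lt(res$friedman$p_value, 0.05)
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(which.max(res$nemenyi$mean_ranks), c(adaptive = 3L))
  adaptive_rows <- grep("adaptive", res$pairwise$comparison)
  expect_true(all(res$pairwise$p_value[adaptive_rows] < 0.05))

  # constant matrix: omnibus degenerate, post hoc skipped
  flat <- compare_methods(matrix(1, 5, 3))
  expect_equal(flat$friedman$p_value, 1)
  expect_null(flat$pairwise)
})

test_that("compare_methods builds the matrix from long results and flags gaps", {
  long <- expand.grid(dataset = c("d1", "d2"), model = c("m1", "m2"),
                      method = c("a", "b"), seed = 1:2,
                      stringsAsFactors = FALSE)
  long$f1 <- seq_len(nrow(long)) / nrow(long)
  res <- compare_methods(long, posthoc = "always")
  expect_equal(dim(res$scores), c(4L, 2L))
  # seed replicates are averaged into each cell
  cell <- with(long, mean(f1[dataset == "d1" & model == "m1" & method == "a"]))
  expect_equal(res$scores["d1 / m1", "a"], cell)

  gap <- !(long$dataset == "d1" & long$model == "m1" & long$method == "a")
  expect_error(compare_methods(long[gap, ], posthoc = "always"), "missing cells")
})
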