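#' Exact Wilcoxon signed-rank test on paired scores
#'
#' Differences `d = x - y`; zero differences are discarded (classical
#' handling, not Pratt's), `n_effective` is the count of non-zero
#' differences. Absolute differences are ranked with midranks for ties and
#' the reported statistic is `W = min(W+, W-)`.
#'
#' The null distribution of `W+` is computed exactly — by a
#' dynamic-programming convolution over the (doubled) midranks that is
#' arithmetically identical to full enumeration of all `2^n` sign
#' assignments, including under ties — whenever `n_effective <= exact_limit`
#' (default 25). Above the limit a normal approximation with tie correction
#' (no continuity correction) is used; `exact_flag` records which path ran.
#' Two-sided p-values are `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"` (x tends to exceed y) or
#'   `"less"`.
#' @param exact_limit largest `n_effective` for which the exact distribution
#'   is enumerated.
#' @return A `radnorm_test` list: `statistic` (W), `p_value`, `method`,
#'   `n_effective`, `exact_flag`, `w_plus`, `w_minus`, `alternative`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  if (length(x) < 1L) stop("need at least one pair", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, method = "wilcoxon_signed_rank",
                          n_effective = 0L, exact_flag = "degenerate",
                          w_plus = 0, w_minus = 0, alternative = alternative,
                          degenerate = TRUE), class = "radnorm_test"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus

  if (n <= exact_limit) {
    probs <- signed_rank_null(r)                 # P(2*W+ = k), k = 0..sum(2r)
    k_obs <- round(2 * w_plus)
    p_le <- sum(probs[seq_len(k_obs + 1L)])      # P(W+ <= w_plus)
    p_ge <- sum(probs[(k_obs + 1L):length(probs)])
    exact_flag <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- tabulate(match(r, unique(r)))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p_le <- stats::pnorm(z)
    p_ge <- stats::pnorm(z, lower.tail = FALSE)
    exact_flag <- "normal_approx"
  }
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
  structure(list(statistic = min(w_plus, w_minus), p_value = p,
                 method = "wilcoxon_signed_rank", n_effective = n,
                 exact_flag = exact_flag, w_plus = w_plus, w_minus = w_minus,
                 alternative = alternative, degenerate = FALSE),
            class = "radnorm_test")
}

# Exact null pmf of the signed-rank sum over ranks r (midranks allowed).
# Works on doubled ranks so all masses sit on integers; returns the vector
# P(2*W+ = 0), ..., P(2*W+ = sum(2r)). Equivalent to enumerating all 2^n
# sign assignments.
signed_rank_null <- function(r) {
  r2 <- round(2 * r)
  f <- 1                                   # polynomial coefficients over 2*W+
  for (a in r2) {
    g <- c(f, numeric(a))
    g[(a + 1L):(length(f) + a)] <- g[(a + 1L):(length(f) + a)] + f
    f <- g
  }
  f / 2^length(r2)
}

#' Friedman rank test over a block-by-treatment score matrix
#'
#' Scores are midranked within each block (row); the tie-corrected statistic
#'
#'   `chi2_F = (k - 1) * sum_j (R_j - n(k+1)/2)^2 /
#'             (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#'
#' reduces to the classical `12/(nk(k+1)) * sum R_j^2 - 3n(k+1)` when no
#' ties occur. The p-value uses the chi-squared distribution with `k - 1`
#' degrees of freedom, an asymptotic reference that is anti-conservative for
#' very small `n`; exact small-sample tables are not implemented. A matrix
#' whose rows are all constant yields statistic 0 and p 1.
#'
#' @param scores numeric matrix, blocks (e.g. dataset-by-model
#'   configurations) in rows, treatments (normalization methods) in columns;
#'   `>= 2` of each, no missing cells.
#' @return A `radnorm_test` list (`statistic`, `p_value`, `n_effective` =
#'   number of blocks, plus `rank_sums` and `mean_ranks`).
#' @export
friedman <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix has missing cells", call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments", call. = FALSE)
  ranks <- t(apply(scores, 1, rank))
  Rj <- colSums(ranks)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- num / den
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p, method = "friedman",
                 n_effective = n, exact_flag = "chisq_approx",
                 rank_sums = Rj, mean_ranks = Rj / n, df = k - 1,
                 degenerate = den <= 0),
            class = "radnorm_test")
}

# Critical values q_alpha of the studentized range statistic divided by
# sqrt(2), for the Nemenyi test (Demsar 2006, Table 5), k = 2..10.
.nemenyi_q <- list(
  "0.05" = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164),
  "0.1"  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920)
)

#' Nemenyi critical difference
#'
#' After a significant Friedman test, two treatments differ at level `alpha`
#' when their mean ranks differ by at least `CD = q_alpha(k) *
#' sqrt(k(k+1)/(6n))`. The `q_alpha` values come from the conventional
#' embedded table (studentized range / sqrt(2)), `k` from 2 to 10, `alpha`
#' 0.05 or 0.10.
#'
#' @param k number of treatments (2–10).
#' @param n number of blocks.
#' @param alpha 0.05 or 0.10.
#' @return The critical difference (a positive real, decreasing in `n`).
#' @export
nemenyi_cd <- function(k, n, alpha = 0.05) {
  key <- as.character(alpha)
  if (!key %in% names(.nemenyi_q)) {
    stop("alpha must be 0.05 or 0.1 (embedded table bounds)", call. = FALSE)
  }
  if (k < 2 || k > 10) {
    stop("k must be between 2 and 10 (embedded table bounds)", call. = FALSE)
  }
  stopifnot(n >= 1)
  q <- .nemenyi_q[[key]][k - 1]
  q * sqrt(k * (k + 1) / (6 * n))
}

# build a blocks x treatments seed-averaged score matrix from a long results
# table with columns dataset, model, method, <metric> (and optionally seed)
score_matrix <- function(results, metric = "f1") {
  req <- c("dataset", "model", "method", metric)
  missing_cols <- setdiff(req, names(results))
  if (length(missing_cols) > 0L) {
    stop(sprintf("results table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  block <- interaction(results$dataset, results$model, sep = " / ", drop = TRUE)
  agg <- stats::aggregate(results[[metric]],
                          by = list(block = block, method = results$method),
                          FUN = mean)
  blocks <- sort(unique(as.character(agg$block)))
  methods <- unique(as.character(results$method))
  mat <- matrix(NA_real_, length(blocks), length(methods),
                dimnames = list(blocks, methods))
  mat[cbind(match(as.character(agg$block), blocks),
            match(as.character(agg$method), methods))] <- agg$x
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("incomplete score matrix; missing cells: %s",
                 paste(sprintf("(%s, %s)", rownames(mat)[miss[, 1]],
                               colnames(mat)[miss[, 2]]), collapse = "; ")),
         call. = FALSE)
  }
  mat
}

#' Three-stage comparison of normalization methods
#'
#' Runs the omnibus [friedman()] test on a seed-averaged block-by-treatment
#' score matrix; when its p-value falls below `alpha`, follows with the
#' [nemenyi_cd()] mean-rank comparison and all pairwise exact
#' [wilcoxon_signed_rank()] tests. Pairwise p-values are reported raw (no
#' multiplicity correction) with significance verdicts at the 0.05 and 0.01
#' thresholds; set `holm = TRUE` to additionally report Holm-adjusted
#' p-values.
#'
#' @param results either a numeric blocks-by-treatments matrix (e.g. 12
#'   dataset-by-model configurations by 3 methods) or a long results table
#'   with columns `dataset`, `model`, `method`, and the metric (seed
#'   replicates are averaged).
#' @param metric metric column to compare when `results` is a table.
#' @param alpha omnibus significance level gating the post hoc stage.
#' @param holm also report Holm-adjusted pairwise p-values?
#' @param posthoc `"auto"` (default) runs the post hoc stage only when the
#'   omnibus p-value falls below `alpha`; `"always"` reports the Nemenyi and
#'   pairwise Wilcoxon results unconditionally (useful when the omnibus
#'   verdict is already known from finer-grained scores than the matrix at
#'   hand, e.g. unrounded per-run values).
#' @return A `comparison_result` list: `scores` (the matrix), `friedman`,
#'   and — when the omnibus test is significant — `nemenyi` (critical
#'   difference, mean ranks, pairwise verdict matrix) and `pairwise` (a
#'   data frame with columns `comparison`, `statistic`, `p_value`,
#'   `n_effective`, `verdict_0.05`, `verdict_0.01`).
#' @export
compare_methods <- function(results, metric = "f1", alpha = 0.05, holm = FALSE,
                            posthoc = c("auto", "always")) {
  posthoc <- match.arg(posthoc)
  mat <- if (is.matrix(results)) {
    if (anyNA(results)) stop("incomplete score matrix (NA cells)", call. = FALSE)
    results
  } else {
    score_matrix(results, metric)
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("method_", seq_len(ncol(mat)))
  fr <- friedman(mat)
  out <- list(scores = mat, friedman = fr, alpha = alpha,
              nemenyi = NULL, pairwise = NULL)

  if (posthoc == "always" || (!fr$degenerate && fr$p_value < alpha)) {
    k <- ncol(mat); n <- nrow(mat)
    cd <- nemenyi_cd(k, n, alpha = alpha)
    mr <- fr$mean_ranks
    names(mr) <- colnames(mat)
    sig <- abs(outer(mr, mr, "-")) >= cd
    diag(sig) <- FALSE
    out$nemenyi <- list(critical_difference = cd, mean_ranks = mr,
                        significant = sig)

    pairs <- utils::combn(colnames(mat), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      wt <- wilcoxon_signed_rank(mat[, pr[1]], mat[, pr[2]])
      data.frame(comparison = sprintf("%s vs. %s", pr[1], pr[2]),
                 statistic = wt$statistic, p_value = wt$p_value,
                 n_effective = wt$n_effective,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$verdict_0.05 <- pw$p_value < 0.05
    pw$verdict_0.01 <- pw$p_value < 0.01
    if (holm) pw$p_holm <- stats::p.adjust(pw$p_value, method = "holm")
    out$pairwise <- pw
  }
  structure(out, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.4g (n = %d blocks)\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value,
              x$friedman$n_effective))
  if (is.null(x$pairwise)) {
    cat("Omnibus test not significant; post hoc comparisons skipped.\n")
  } else {
    cat(sprintf("Nemenyi critical difference (alpha = %g): %.4f\n",
                x$alpha, x$nemenyi$critical_difference))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
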