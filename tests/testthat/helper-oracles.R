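# Independent oracles and fixture builders used across the suite.

# Full 2^n enumeration of the signed-rank null: for each sign assignment over
# the midranks of |d|, accumulate W+; tail probabilities by counting.
enum_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force retention scan for the percentile window rule.
brute_window <- function(cdf, lo, hi) {
  keep <- which(cdf > lo & cdf <= hi)
  if (length(keep) == 0L) return(NULL)
  c(min(keep) - 1L, max(keep) - 1L)
}

rand_uint8_image <- function(h, w) {
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w), depth = "uint8")
}

# manifest of tiny on-disk phantoms for harness tests (one image per record)
tiny_manifest <- function(n = 12L, seed = 1L, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- phantom_config(domains = list(site_a = domain_params(noise_sd = 2)),
                        seed = seed)
  generate_dataset(cfg, n_per_domain = n, seed = seed, dir = dir)
}
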