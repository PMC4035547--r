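# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit enumeration, no shared code with R/).

# Pool-genotype distribution by enumerating all 2^4 ordered draws of the
# four parental allele copies.
enumerate_pool_probs <- function(p) {
  draws <- expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:1, a4 = 0:1)
  k <- rowSums(draws)
  w <- apply(draws, 1, function(d) prod(ifelse(d == 1, p, 1 - p)))
  vapply(0:4, function(kk) sum(w[k == kk]), numeric(1))
}

# Eq.-8-style noise variance by explicit weighting of g(1-g)/S over the
# five pool genotypes.
enumerate_noise_variance <- function(p, depth) {
  g <- c(0, 0.25, 0.5, 0.75, 1)
  pr <- enumerate_pool_probs(p)
  sum(g * (1 - g) * pr) / depth
}

# Reference slope fit through stats::lm, mirroring what a user would do
# by hand; used to cross-check the vectorized engine.
lm_slope_stats <- function(y, x) {
  keep <- !is.na(x)
  fit <- stats::lm(y[keep] ~ x[keep])
  cf <- stats::coef(summary(fit))
  list(b = cf[2, 1], se = cf[2, 2], t = cf[2, 3], p = cf[2, 4],
       df = fit$df.residual)
}

# Default design used in several power tests.
base_design <- function(...) {
  args <- modifyList(list(n_families = 2000, depth = 7, p = 0.3,
                          sigma_e = 4, b = 1), list(...))
  do.call(design_point, args)
}
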