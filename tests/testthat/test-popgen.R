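test_that("pool genotype distribution matches brute-force enumeration", {
  # frozen values from the 16-draw enumeration oracle
  expect_equal(pool_genotype_probs(0.5)$probs,
               c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  expect_equal(pool_genotype_probs(0.1)$probs,
               c(0.6561, 0.2916, 0.0486, 0.0036, 0.0001))
  expect_equal(pool_genotype_probs(0)$probs, c(1, 0, 0, 0, 0))
  expect_equal(pool_genotype_probs(1)$probs, c(0, 0, 0, 0, 1))
  for (p in c(0.07, 0.3, 0.62, 0.95)) {
    expect_equal(pool_genotype_probs(p)$probs, enumerate_pool_probs(p),
                 tolerance = 1e-12)
  }
  expect_error(pool_genotype_probs(1.2), "\\[0, 1\\]")
})

test_that("probabilities normalize for random allele frequencies", {
  set.seed(11)
  for (p in runif(1000)) {
    d <- pool_genotype_probs(p)
    expect_true(abs(sum(d$probs) - 1) < 1e-12)
    expect_true(all(d$probs >= 0 & d$probs <= 1))
  }
})

test_that("mating table aggregates to the pool genotype distribution", {
  tab <- mating_table(0.5)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$mating_freq[tab$mating == "aa x aa"], 0.0625)
  expect_equal(tab$pool_freq[tab$mating == "aa x aa"], 0)
  expect_equal(tab$pool_dose, 2 * tab$pool_freq)
  # fixation: only AA x AA remains
  expect_equal(mating_table(1)$mating_freq, c(0, 0, 0, 0, 0, 1))
  set.seed(12)
  for (p in c(0, 0.5, 1, runif(50))) {
    tab <- mating_table(p)
    expect_equal(sum(tab$mating_freq), 1, tolerance = 1e-12)
    agg <- tapply(tab$mating_freq, factor(tab$pool_freq,
                                          levels = c(0, .25, .5, .75, 1)),
                  sum, default = 0)
    expect_equal(as.vector(agg), pool_genotype_probs(p)$probs,
                 tolerance = 1e-12)
  }
})

test_that("genetic variances follow the additive one-locus formulas", {
  expect_equal(genetic_variance_individual(locus_model(0.5, b = 2)), 0.5)
  expect_equal(genetic_variance_individual(locus_model(0.3, b = 1)), 0.105)
  expect_equal(genetic_variance_individual(locus_model(0, b = 2)), 0)
  expect_equal(genetic_variance_individual(locus_model(1, b = 2)), 0)

  # pool value variance is half the individual one; frequency scale p(1-p)/4
  expect_equal(genetic_variance_pool(locus_model(0.5, b = 2)),
               c(value = 0.25, freq = 0.0625))
  expect_equal(genetic_variance_pool(locus_model(0.1, b = 2)),
               c(value = 0.09, freq = 0.0225))
  expect_equal(genetic_variance_pool(locus_model(0.4, b = 0))[["value"]], 0)
  set.seed(13)
  for (i in 1:20) {
    m <- locus_model(runif(1), b = rnorm(1))
    expect_equal(genetic_variance_pool(m)[["value"]],
                 genetic_variance_individual(m) / 2)
    # cross-check by direct expectation over the five-point support
    d <- pool_genotype_probs(m$p)
    gv <- sum(d$probs * (d$support * m$b)^2) -
      sum(d$probs * d$support * m$b)^2
    expect_equal(genetic_variance_pool(m)[["value"]], gv,
                 tolerance = 1e-12)
  }
})

test_that("binomial noise variance equals the enumeration oracle", {
  expect_equal(binomial_noise_variance(0.5, 3), 0.0625)
  expect_equal(binomial_noise_variance(0, 10), 0)
  expect_equal(binomial_noise_variance(0.3, 7), 0.0225)
  set.seed(14)
  for (i in 1:50) {
    p <- runif(1)
    s <- sample(1:60, 1)
    expect_equal(binomial_noise_variance(p, s),
                 enumerate_noise_variance(p, s), tolerance = 1e-12)
  }
  expect_error(binomial_noise_variance(0.5, 0.5), ">= 1")
})

test_that("attenuation factor is 1/(1 + 3/depth) and monotone", {
  expect_identical(attenuation_factor(3), 0.5)
  expect_equal(attenuation_factor(30), 1 / 1.1)
  expect_equal(attenuation_factor(1e12), 1, tolerance = 1e-9)
  d <- sort(runif(100, 0.1, 100))
  expect_true(all(diff(attenuation_factor(d)) > 0))
  expect_error(attenuation_factor(0), "positive")
})

test_that("harmonic mean depth excludes zero-depth families", {
  expect_equal(as.numeric(harmonic_mean_depth(c(5, 5, 5))), 5)
  expect_equal(as.numeric(harmonic_mean_depth(c(3, 3, 6))), 3.6)
  hd <- harmonic_mean_depth(c(0, 4, 4))
  expect_equal(as.numeric(hd), 4)
  expect_equal(attr(hd, "n_excluded"), 1L)
  expect_error(harmonic_mean_depth(c(0, 0)), "all depths are zero")
})

test_that("explained variance matches the closed form and is monotone", {
  expect_equal(explained_variance(locus_model(0.1, b = 1, sigma_e = 4)),
               0.0014, tolerance = 1e-4 / 0.0014)
  expect_equal(explained_variance(locus_model(0.5, b = 1, sigma_e = 4)),
               0.0625 / 16.0625)
  # increasing in |b|, decreasing in sigma_e
  ev_b <- sapply(c(0.5, 1, 2, 4),
                 function(b) explained_variance(locus_model(0.3, b = b)))
  expect_true(all(diff(ev_b) > 0))
  ev_s <- sapply(c(2, 4, 8),
                 function(s) explained_variance(locus_model(0.3, sigma_e = s)))
  expect_true(all(diff(ev_s) < 0))
  expect_error(explained_variance(locus_model(0.3, sigma_e = 0)),
               "positive")
})

test_that("Poisson zero-read probability matches exp(-lambda)", {
  expect_equal(prob_zero_reads(5), exp(-5))
  expect_equal(prob_zero_reads(c(5, 6, 7)), exp(-c(5, 6, 7)))
  expect_error(prob_zero_reads(0), "positive")
})

test_that("haplotype frequencies recover marginals and LD", {
  # perfect LD puts all mass on the coupling haplotypes
  expect_equal(unname(haplotype_frequencies(0.5, 0.5, 1)$x),
               c(0.5, 0, 0, 0.5))
  # linkage equilibrium gives products of marginals
  expect_equal(unname(haplotype_frequencies(0.3, 0.3, 0)$x),
               c(0.09, 0.21, 0.21, 0.49))
  tl <- haplotype_frequencies(0.3, 0.3, 0.7)
  expect_equal(tl$D, 0.147)
  expect_equal(unname(tl$x), c(0.237, 0.063, 0.063, 0.637))
  expect_error(haplotype_frequencies(0.05, 0.9, 0.9), "infeasible")
})

test_that("LD round-trips through haplotype frequencies", {
  set.seed(15)
  n_ok <- 0
  while (n_ok < 200) {
    p1 <- runif(1, 0.05, 0.95); q1 <- runif(1, 0.05, 0.95)
    r <- runif(1, -1, 1)
    tl <- tryCatch(haplotype_frequencies(p1, q1, r),
                   error = function(e) NULL)
    if (is.null(tl)) next  # infeasible r for these marginals
    n_ok <- n_ok + 1
    expect_true(abs(sum(tl$x) - 1) < 1e-12)
    expect_true(all(tl$x >= 0))
    expect_equal(tl$x[["x11"]] + tl$x[["x12"]], p1, tolerance = 1e-12)
    expect_equal(tl$x[["x11"]] + tl$x[["x21"]], q1, tolerance = 1e-12)
    expect_equal(ld_correlation(tl), r, tolerance = 1e-9)
  }
})
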