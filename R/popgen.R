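# Closed-form population-genetic quantities for F2 full-sib family pools.
#
# An F2 family from a pair cross of two diploid parents carries up to four
# copies of each allele, so its "pool genotype" behaves like a tetraploid
# dosage: the pool allele frequency takes values in {0, 1/4, 1/2, 3/4, 1}.
# Everything below follows from random mating at Hardy-Weinberg
# proportions and an additive model.

POOL_FREQ_SUPPORT <- c(0, 0.25, 0.5, 0.75, 1)

#' Distribution of F2 pool allele frequencies
#'
#' Probabilities of the five possible F2-family pool allele frequencies
#' \{0, 1/4, 1/2, 3/4, 1\} under random mating of parents drawn from a
#' population with allele frequency `p`. The pool frequency is `k/4` where
#' `k` is the number of counted-allele copies among the four parental
#' copies, so `k ~ Binomial(4, p)`.
#'
#' @param p Population allele frequency in `[0, 1]`.
#' @return An object of class `"pool_genotype_dist"`: a list with
#'   `support` (the five pool frequencies) and `probs` (their
#'   probabilities, summing to 1).
#' @examples
#' pool_genotype_probs(0.5)$probs  # 0.0625 0.25 0.375 0.25 0.0625
#' @seealso [mating_table()] for the same distribution broken out by
#'   parental mating type.
#' @export
pool_genotype_probs <- function(p) {
  check_prob(p, "p")
  structure(
    list(support = POOL_FREQ_SUPPORT, probs = stats::dbinom(0:4, 4, p)),
    class = "pool_genotype_dist"
  )
}

#' @export
print.pool_genotype_dist <- function(x, ...) {
  cat("F2 pool allele-frequency distribution\n")
  print(stats::setNames(x$probs, format(x$support)))
  invisible(x)
}

#' Parental mating table for F2 pools
#'
#' All six unordered parental matings at a biallelic locus, the frequency
#' of each mating under random mating at allele frequency `p`, the average
#' pool allele dose (0 to 2 in halves) and the F2 pool allele frequency
#' (in quarters) each mating produces. Aggregating the mating frequencies
#' by pool frequency reproduces [pool_genotype_probs()].
#'
#' @inheritParams pool_genotype_probs
#' @return A data frame with columns `mating`, `mating_freq`, `pool_dose`,
#'   `pool_freq` (six rows; `mating_freq` sums to 1).
#' @examples
#' mating_table(0.5)
#' @export
mating_table <- function(p) {
  check_prob(p, "p")
  q <- 1 - p
  data.frame(
    mating      = c("aa x aa", "aa x Aa", "aa x AA",
                    "Aa x Aa", "Aa x AA", "AA x AA"),
    mating_freq = c(q^4, 4 * p * q^3, 2 * p^2 * q^2,
                    4 * p^2 * q^2, 4 * p^3 * q, p^4),
    pool_dose   = c(0, 0.5, 1, 1, 1.5, 2),
    pool_freq   = c(0, 0.25, 0.5, 0.5, 0.75, 1),
    stringsAsFactors = FALSE
  )
}

#' Genetic variance at a locus, individual scale
#'
#' Additive genetic variance `2 p (1 - p) a^2` among diploid individuals
#' at Hardy-Weinberg proportions, with allele-substitution effect
#' `a = b / 2`.
#'
#' @param model A [locus_model()].
#' @return Variance of the genotypic value among individuals
#'   (phenotype units squared).
#' @export
genetic_variance_individual <- function(model) {
  model <- as_locus_model(model)
  2 * model$p * (1 - model$p) * model$a^2
}

#' Genetic variance across F2-family pools
#'
#' The genotypic value of an F2 pool is the mean of its two parents'
#' genotypic values, so the between-family genetic variance is
#' `p (1 - p) a^2` — exactly half the individual-scale variance. On the
#' pool-frequency scale (dividing by `b^2 = 4 a^2`) it is `p (1 - p) / 4`,
#' the variance of the pool allele frequency itself.
#'
#' @param model A [locus_model()].
#' @return Named numeric vector: `value` (variance of the pool genotypic
#'   value, phenotype units squared) and `freq` (variance of the pool
#'   allele frequency, unitless).
#' @export
genetic_variance_pool <- function(model) {
  model <- as_locus_model(model)
  pq <- model$p * (1 - model$p)
  c(value = pq * model$a^2, freq = pq / 4)
}

#' Binomial sampling variance of the observed pool frequency
#'
#' A pool sequenced to total depth `S_T` yields an observed frequency
#' `S1 / S_T` whose binomial sampling variance, averaged over the five
#' possible pool genotypes at population allele frequency `p`, is
#' `3 p (1 - p) / (4 S_T)`.
#'
#' @inheritParams pool_genotype_probs
#' @param depth Total read count `S_T` per family (>= 1; may be the
#'   effective depth from [harmonic_mean_depth()], hence fractional).
#' @return Average sampling variance of the observed pool frequency.
#' @examples
#' binomial_noise_variance(0.5, 3)  # 0.0625
#' @export
binomial_noise_variance <- function(p, depth) {
  check_prob(p, "p")
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) ||
      depth < 1) {
    stop("'depth' must be a single number >= 1", call. = FALSE)
  }
  3 * p * (1 - p) / (4 * depth)
}

#' Attenuation of the regression slope under sequencing noise
#'
#' Measurement error on the pool frequency shrinks the regression of
#' phenotype on observed frequency toward zero by the reliability ratio
#' `var(g) / (var(g) + noise)`, which for F2 pools reduces to
#' `1 / (1 + 3 / S_T)` — independent of allele frequency. Dividing a raw
#' slope estimate by this factor removes the attenuation.
#'
#' @param depth Effective total reads per family (`> 0`; use
#'   [harmonic_mean_depth()] when depth varies across families).
#'   Vectorized.
#' @return Multiplicative bias factor in `(0, 1)`, increasing in depth
#'   and approaching 1 as depth grows.
#' @examples
#' attenuation_factor(3)   # 0.5: the raw slope is halved at depth 3
#' attenuation_factor(30)  # ~0.909
#' @export
attenuation_factor <- function(depth) {
  if (!is.numeric(depth) || any(is.na(depth)) || any(depth <= 0)) {
    stop("'depth' must be positive", call. = FALSE)
  }
  1 / (1 + 3 / depth)
}

#' Harmonic mean sequencing depth
#'
#' Effective depth for the attenuation correction when depth varies
#' across families: the harmonic mean of the per-family total read
#' counts. Families with zero reads carry no frequency estimate; they are
#' excluded and their number is reported.
#'
#' @param depths Numeric vector of per-family total read counts
#'   (non-negative; at least one must be positive).
#' @return The harmonic mean of the positive depths, with attribute
#'   `n_excluded` giving the number of zero-depth families dropped.
#' @examples
#' harmonic_mean_depth(c(3, 3, 6))  # 3.6
#' @export
harmonic_mean_depth <- function(depths) {
  if (!is.numeric(depths) || length(depths) == 0L || any(is.na(depths)) ||
      any(depths < 0)) {
    stop("'depths' must be a non-empty vector of non-negative counts",
         call. = FALSE)
  }
  pos <- depths[depths > 0]
  if (length(pos) == 0L) {
    stop("all depths are zero: no families with data", call. = FALSE)
  }
  structure(length(pos) / sum(1 / pos),
            n_excluded = length(depths) - length(pos))
}

#' Phenotypic variance explained by one locus across pools
#'
#' Fraction `V_g / (V_g + sigma_e^2)` of the between-family phenotypic
#' variance attributable to the locus, where
#' `V_g = b^2 p (1 - p) / 4` is the pool genetic variance expressed
#' through the frequency-scale effect `b`.
#'
#' @param model A [locus_model()] with `sigma_e > 0`.
#' @return Explained-variance fraction in `[0, 1)`.
#' @examples
#' explained_variance(locus_model(p = 0.5, b = 1, sigma_e = 4))  # ~0.0039
#' @export
explained_variance <- function(model) {
  model <- as_locus_model(model)
  if (model$sigma_e <= 0) {
    stop("'sigma_e' must be positive to define an explained-variance ratio",
         call. = FALSE)
  }
  vg <- model$b^2 * model$p * (1 - model$p) / 4
  vg / (vg + model$sigma_e^2)
}

#' Probability of a missing genotype under Poisson depth
#'
#' When the number of reads per family follows a Poisson distribution
#' with mean `lambda`, a family has no reads at all — and hence a missing
#' frequency estimate — with probability `exp(-lambda)`.
#'
#' @param lambda Mean sequencing depth (> 0). Vectorized.
#' @return Probability of zero reads.
#' @examples
#' prob_zero_reads(5)  # ~0.0067, i.e. 0.7% missing at mean depth 5
#' @export
prob_zero_reads <- function(lambda) {
  if (!is.numeric(lambda) || any(is.na(lambda)) || any(lambda <= 0)) {
    stop("'lambda' must be positive", call. = FALSE)
  }
  stats::dpois(0, lambda)
}

# two-locus LD model --------------------------------------------------------

#' Haplotype frequencies for two loci in linkage disequilibrium
#'
#' Builds a two-locus model from the allele frequencies `p1` (causal
#' locus, allele A1) and `q1` (marker locus, allele B1) and the LD
#' correlation `r`. The LD covariance is
#' `D = r * sqrt(p1 (1 - p1) q1 (1 - q1))` and the four haplotype
#' frequencies are `x11 = p1 q1 + D`, `x12 = p1 (1 - q1) - D`,
#' `x21 = (1 - p1) q1 - D`, `x22 = (1 - p1)(1 - q1) + D`. A requested `r`
#' that would make any haplotype frequency negative is infeasible for
#' those marginals and raises an error (it is never silently clipped,
#' which would simulate a different LD level than asked for).
#'
#' @param p1 Allele frequency at the causal locus, in `(0, 1)`.
#' @param q1 Allele frequency at the marker locus, in `(0, 1)`.
#' @param r LD correlation between the allele indicators, in `[-1, 1]`.
#' @return An object of class `"two_locus_model"`: list with `p1`, `q1`,
#'   `r`, `D` and `x` (named haplotype frequencies `x11`, `x12`, `x21`,
#'   `x22` summing to 1).
#' @examples
#' haplotype_frequencies(0.3, 0.3, 0.7)$x
#' @export
haplotype_frequencies <- function(p1, q1, r) {
  for (nm in c("p1", "q1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("'%s' must be strictly inside (0, 1)", nm), call. = FALSE)
    }
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1) {
    stop("'r' must be in [-1, 1]", call. = FALSE)
  }
  D <- r * sqrt(p1 * (1 - p1) * q1 * (1 - q1))
  x <- c(x11 = p1 * q1 + D,
         x12 = p1 * (1 - q1) - D,
         x21 = (1 - p1) * q1 - D,
         x22 = (1 - p1) * (1 - q1) + D)
  # tolerate tiny negative round-off, reject genuinely infeasible r
  bad <- x < -1e-12
  if (any(bad)) {
    stop(sprintf(
      "LD r = %g is infeasible for p1 = %g, q1 = %g: haplotype %s would have frequency %.4g",
      r, p1, q1, names(x)[bad][1L], x[bad][1L]), call. = FALSE)
  }
  x[x < 0] <- 0
  structure(list(p1 = p1, q1 = q1, r = r, D = D, x = x),
            class = "two_locus_model")
}

#' LD correlation implied by haplotype frequencies
#'
#' Recomputes `r = D / sqrt(p1 (1 - p1) q1 (1 - q1))` with
#' `D = x11 - p1 q1` from a set of haplotype frequencies; the round trip
#' through [haplotype_frequencies()] returns the input `r`.
#'
#' @param x Named haplotype frequencies (`x11`, `x12`, `x21`, `x22`) or a
#'   `"two_locus_model"`.
#' @return The LD correlation `r`.
#' @export
ld_correlation <- function(x) {
  if (inherits(x, "two_locus_model")) x <- x$x
  stopifnot(is.numeric(x), length(x) == 4L)
  x <- x / sum(x)
  p1 <- x[["x11"]] + x[["x12"]]
  q1 <- x[["x11"]] + x[["x21"]]
  D <- x[["x11"]] - p1 * q1
  D / sqrt(p1 * (1 - p1) * q1 * (1 - q1))
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat("Two-locus LD model\n")
  cat(sprintf("  p1 (causal) = %g, q1 (marker) = %g\n", x$p1, x$q1))
  cat(sprintf("  r = %g  (D = %g)\n", x$r, x$D))
  cat("  haplotype frequencies:\n")
  print(x$x)
  invisible(x)
}
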