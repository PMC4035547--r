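# Synthetic F2-family pool data: true pool frequencies, phenotypes,
# sequencing read counts under constant or Poisson depth, optional
# per-read error and genotype calling, and two-locus pools in LD.

#' Depth model for pooled sequencing
#'
#' Describes how the total read count per family is generated: a fixed
#' depth for every family (`"constant"`) or a Poisson draw around a mean
#' depth (`"poisson"`), in which case some families may receive zero
#' reads and become missing.
#'
#' @param kind `"constant"` or `"poisson"`.
#' @param value Fixed depth (constant) or mean depth lambda (poisson);
#'   must be positive.
#' @return An object of class `"depth_model"`.
#' @export
depth_model <- function(kind = c("constant", "poisson"), value) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value <= 0) {
    stop("'value' must be a single positive number", call. = FALSE)
  }
  if (kind == "constant" && value != round(value)) {
    stop("constant depth must be a whole number of reads", call. = FALSE)
  }
  structure(list(kind = kind, value = value), class = "depth_model")
}

#' Sequencing error model
#'
#' @param per_read_error Probability that a read reports the wrong allele
#'   (symmetric flip), in `[0, 0.5)`. Default 0.
#' @param call_genotypes If `TRUE`, observed frequencies are forced to
#'   the nearest quarter (tetraploid genotype calling) before analysis.
#' @return An object of class `"error_model"`.
#' @export
error_model <- function(per_read_error = 0, call_genotypes = FALSE) {
  if (!is.numeric(per_read_error) || length(per_read_error) != 1L ||
      is.na(per_read_error) || per_read_error < 0 || per_read_error >= 0.5) {
    stop("'per_read_error' must be in [0, 0.5)", call. = FALSE)
  }
  stopifnot(is.logical(call_genotypes), length(call_genotypes) == 1L)
  structure(list(per_read_error = per_read_error,
                 call_genotypes = call_genotypes),
            class = "error_model")
}

#' Simulate true F2 pool allele frequencies
#'
#' Draws `n` family pool frequencies i.i.d. from the five-point
#' distribution [pool_genotype_probs()] at population allele frequency
#' `p` (equivalently, `Binomial(4, p) / 4`).
#'
#' @param n Number of families (>= 1).
#' @inheritParams pool_genotype_probs
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `n` with values in
#'   \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
simulate_pools <- function(n, p, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  check_prob(p, "p")
  set_seed_if(derive_seed(seed, "pools"))
  stats::rbinom(n, 4, p) / 4
}

#' Simulate family phenotypes from pool frequencies
#'
#' `P_i = mu + b * g_i + e_i` with `e_i ~ Normal(0, sigma_e^2)`: the
#' family phenotype is linear in the true pool allele frequency with
#' slope `b` (twice the allele-substitution effect).
#'
#' @param g_true Vector of true pool allele frequencies.
#' @param model A [locus_model()].
#' @inheritParams simulate_pools
#' @return Numeric vector of phenotypes, same length as `g_true`.
#' @export
simulate_phenotypes <- function(g_true, model, seed = NULL) {
  model <- as_locus_model(model)
  stopifnot(is.numeric(g_true))
  set_seed_if(derive_seed(seed, "phenotypes"))
  model$mu + model$b * g_true +
    stats::rnorm(length(g_true), 0, model$sigma_e)
}

#' Simulate pooled sequencing read counts
#'
#' For each family, the total depth `S_T` is drawn from the depth model
#' and the count of reads carrying the counted allele is
#' `S1 ~ Binomial(S_T, g')` where `g' = g (1 - eps) + (1 - g) eps` folds
#' a symmetric per-read error rate `eps` into the success probability
#' (distributionally identical to flipping individual reads). The
#' observed pool frequency is `S1 / S_T`, or missing (`NA`) when a
#' Poisson draw gives zero reads. With `call_genotypes = TRUE` the
#' observed frequency is additionally forced to the nearest quarter by
#' [call_genotype()].
#'
#' @param g_true Vector of true pool allele frequencies.
#' @param depth A [depth_model()] (a single number is shorthand for a
#'   constant depth).
#' @param error An [error_model()]; defaults to error-free sequencing.
#' @inheritParams simulate_pools
#' @return A data frame with columns `family_id`, `s1`, `s2`, `depth`,
#'   `g_obs` (`NA` when `depth == 0`).
#' @export
simulate_read_counts <- function(g_true, depth, error = error_model(),
                                 seed = NULL) {
  stopifnot(is.numeric(g_true), all(g_true >= 0 & g_true <= 1))
  if (is.numeric(depth)) depth <- depth_model("constant", depth)
  stopifnot(inherits(depth, "depth_model"), inherits(error, "error_model"))
  n <- length(g_true)
  set_seed_if(derive_seed(seed, "reads"))
  st <- switch(depth$kind,
               constant = rep.int(as.integer(depth$value), n),
               poisson  = stats::rpois(n, depth$value))
  eps <- error$per_read_error
  g_seq <- g_true * (1 - eps) + (1 - g_true) * eps
  s1 <- stats::rbinom(n, st, g_seq)
  g_obs <- ifelse(st > 0, s1 / st, NA_real_)
  if (error$call_genotypes) g_obs <- call_genotype(g_obs)
  data.frame(family_id = seq_len(n), s1 = s1, s2 = st - s1,
             depth = st, g_obs = g_obs)
}

#' Call a tetraploid pool genotype from an observed frequency
#'
#' Rounds an observed pool frequency to the nearest quarter — the
#' frequency a hard tetraploid genotype call would force it to. Exact
#' midpoints (0.125, 0.375, 0.625, 0.875) round toward the higher
#' quarter.
#'
#' @param g_obs Observed frequencies in `[0, 1]`; `NA` passes through.
#' @return Frequencies on the grid \{0, 0.25, 0.5, 0.75, 1\}.
#' @examples
#' call_genotype(c(0.6, 0.375, 1))  # 0.5 0.5 1
#' @export
call_genotype <- function(g_obs) {
  ok <- is.na(g_obs) | (g_obs >= 0 & g_obs <= 1)
  if (!is.numeric(g_obs) || !all(ok)) {
    stop("'g_obs' must be frequencies in [0, 1]", call. = FALSE)
  }
  floor(4 * g_obs + 0.5) / 4
}

#' Simulate two-locus F2 pools under LD
#'
#' Each family pool is formed from four parental haplotypes drawn i.i.d.
#' from the haplotype distribution of a [haplotype_frequencies()] model;
#' the pool allele frequency at each locus is the count of allele-1
#' haplotypes divided by 4. The correlation of the two pool frequencies
#' across families equals the haplotype-level LD correlation `r`.
#'
#' @param n Number of families.
#' @param model A `"two_locus_model"` from [haplotype_frequencies()].
#' @inheritParams simulate_pools
#' @return A data frame with columns `g_A` (causal locus) and `g_B`
#'   (marker locus), pool frequencies in quarters.
#' @export
simulate_two_locus_pools <- function(n, model, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            inherits(model, "two_locus_model"))
  set_seed_if(derive_seed(seed, "twolocus"))
  counts <- stats::rmultinom(n, 4, model$x)  # 4 x n haplotype counts
  data.frame(g_A = (counts[1L, ] + counts[2L, ]) / 4,
             g_B = (counts[1L, ] + counts[3L, ]) / 4)
}

#' Simulate a complete family-pool dataset
#'
#' Convenience wrapper chaining [simulate_pools()] (or
#' [simulate_two_locus_pools()] when `ld_r` is given),
#' [simulate_phenotypes()] and [simulate_read_counts()]. In two-locus
#' mode the phenotype is generated from the causal locus A while
#' sequencing is performed on the marker locus B (and, as columns
#' `s1_B`/`s2_B`, the marker counts are stored alongside the causal-locus
#' counts when both are sequenced).
#'
#' @param n Number of families.
#' @param model A [locus_model()]; its `p` is used for both loci in
#'   two-locus mode.
#' @param depth A [depth_model()] or a single constant depth, applied to
#'   the sequenced (marker) locus.
#' @param error An [error_model()].
#' @param ld_r Optional LD correlation between causal and marker locus;
#'   `NULL` (default) for the one-locus model.
#' @param seed Optional master seed; substreams for pools, phenotypes and
#'   reads are derived from it.
#' @return A data frame with columns `family_id`, `s1`, `s2`, `depth`,
#'   `phenotype`, plus hidden-truth columns `g_true` (sequenced locus)
#'   and, in two-locus mode, `g_causal`.
#' @export
simulate_pool_dataset <- function(n, model, depth, error = error_model(),
                                  ld_r = NULL, seed = NULL) {
  model <- as_locus_model(model)
  if (is.null(ld_r)) {
    g_causal <- g_seq <- simulate_pools(n, model$p, seed = seed)
  } else {
    tlm <- haplotype_frequencies(model$p, model$p, ld_r)
    pools <- simulate_two_locus_pools(n, tlm, seed = seed)
    g_causal <- pools$g_A
    g_seq <- pools$g_B
  }
  phen <- simulate_phenotypes(g_causal, model, seed = seed)
  reads <- simulate_read_counts(g_seq, depth, error, seed = seed)
  out <- data.frame(family_id = reads$family_id, s1 = reads$s1,
                    s2 = reads$s2, depth = reads$depth,
                    phenotype = phen, g_true = g_seq)
  if (!is.null(ld_r)) out$g_causal <- g_causal
  out
}
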