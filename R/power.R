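# Replicated Monte-Carlo power studies over family-pool association
# designs (sample size x depth x allele frequency x environmental SD x
# LD), including fixed-sequencing-budget grids and error stacking.
#
# The replicate loop is vectorized: all families of a block of
# replicates are drawn at once and the simple-regression slope test is
# computed column-wise in closed form (algebraically identical to
# stats::lm + the slope t-test, which the test suite cross-checks).

#' Define a design point for a power study
#'
#' @param n_families Number of F2 families (one phenotype each).
#' @param depth Sequencing depth of the analysed (marker) locus: fixed
#'   reads per family, or the Poisson mean when `depth_kind = "poisson"`.
#' @param p Population allele frequency (both loci in two-locus mode).
#' @param sigma_e Environmental standard deviation.
#' @param b True effect per unit pool frequency (`2a`); `b = 0` gives a
#'   null design for type-I-error checks.
#' @param mu Phenotype intercept.
#' @param ld_r Optional LD correlation between the causal locus and the
#'   sequenced marker locus; `NULL` means the causal locus itself is
#'   sequenced (one-locus mode).
#' @param depth_kind `"constant"` or `"poisson"`.
#' @param per_read_error Symmetric per-read sequencing error rate.
#' @param call_genotypes Force observed frequencies to quarters before
#'   the regression.
#' @param alpha Significance level of the slope t-test.
#' @return An object of class `"design_point"`; its `effort` element is
#'   `n_families * depth` (expected total reads, the budget proxy).
#' @export
design_point <- function(n_families, depth, p, sigma_e = 4, b = 1, mu = 0,
                         ld_r = NULL, depth_kind = c("constant", "poisson"),
                         per_read_error = 0, call_genotypes = FALSE,
                         alpha = 0.05) {
  depth_kind <- match.arg(depth_kind)
  dm <- depth_model(depth_kind, depth)
  em <- error_model(per_read_error, call_genotypes)
  lm_ <- locus_model(p = p, b = b, mu = mu, sigma_e = sigma_e)
  if (!is.null(ld_r)) {
    # validates feasibility up front
    haplotype_frequencies(p, p, ld_r)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(
    list(n_families = as.integer(n_families), depth = depth, p = p,
         sigma_e = sigma_e, b = b, mu = mu, ld_r = ld_r,
         depth_kind = depth_kind, per_read_error = per_read_error,
         call_genotypes = call_genotypes, alpha = alpha,
         effort = n_families * depth,
         depth_model = dm, error_model = em, locus_model = lm_),
    class = "design_point"
  )
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf(
    "Design: n = %d, depth = %g (%s), p = %g, sigma_e = %g, b = %g%s\n",
    x$n_families, x$depth, x$depth_kind, x$p, x$sigma_e, x$b,
    if (is.null(x$ld_r)) "" else sprintf(", marker LD r = %g", x$ld_r)))
  if (x$per_read_error > 0)
    cat(sprintf("  per-read error %g\n", x$per_read_error))
  if (x$call_genotypes) cat("  genotype calling on\n")
  cat(sprintf("  effort = %g read-families, alpha = %g\n",
              x$effort, x$alpha))
  invisible(x)
}

# vectorized replicate engine ----------------------------------------------

# Simulate `m` replicates of a design in one block and return per-replicate
# slope statistics. Matrices are n_families x m; families with zero depth
# are masked out column-wise.
simulate_block <- function(design, m) {
  n <- design$n_families
  nm <- n * m
  if (is.null(design$ld_r)) {
    g_causal <- g_seq <- matrix(stats::rbinom(nm, 4, design$p) / 4, n, m)
  } else {
    tlm <- haplotype_frequencies(design$p, design$p, design$ld_r)
    counts <- stats::rmultinom(nm, 4, tlm$x)
    g_causal <- matrix((counts[1L, ] + counts[2L, ]) / 4, n, m)
    g_seq <- matrix((counts[1L, ] + counts[3L, ]) / 4, n, m)
  }
  y <- design$mu + design$b * g_causal +
    matrix(stats::rnorm(nm, 0, design$sigma_e), n, m)
  st <- switch(design$depth_kind,
               constant = matrix(as.integer(design$depth), n, m),
               poisson  = matrix(stats::rpois(nm, design$depth), n, m))
  eps <- design$per_read_error
  g_p <- g_seq * (1 - eps) + (1 - g_seq) * eps
  s1 <- matrix(stats::rbinom(nm, st, g_p), n, m)
  x <- s1 / st                       # NaN where depth 0
  if (design$call_genotypes) x <- floor(4 * x + 0.5) / 4
  w <- st > 0
  x[!w] <- 0
  y0 <- y
  y0[!w] <- 0

  n_used <- colSums(w)
  sx <- colSums(x);      sy <- colSums(y0)
  sxx <- colSums(x * x); sxy <- colSums(x * y0); syy <- colSums(y0 * y0)
  sxx_c <- sxx - sx^2 / n_used
  sxy_c <- sxy - sx * sy / n_used
  syy_c <- syy - sy^2 / n_used

  ok <- n_used >= 3L & sxx_c > 0
  slope <- ifelse(ok, sxy_c / sxx_c, NA_real_)
  df <- n_used - 2L
  rss <- pmax(syy_c - slope * sxy_c, 0)
  se <- sqrt(rss / df / sxx_c)
  t_stat <- slope / se
  p_value <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)

  inv_depth <- colSums(ifelse(w, 1 / st, 0))
  eff_depth <- n_used / inv_depth
  b_corr <- slope / attenuation_factor(eff_depth)

  data.frame(b_hat = slope, se = se, t_stat = t_stat, p_value = p_value,
             n_used = n_used, effective_depth = eff_depth,
             b_corrected = b_corr)
}

#' Run replicated simulations of one design
#'
#' Simulates `n_reps` independent datasets under a [design_point()] and
#' returns the fitted slope statistics of every replicate — the raw
#' material for both effect-recovery studies (mean of `b_hat` and
#' `b_corrected`) and power estimates (fraction of `p_value < alpha`).
#'
#' @param design A [design_point()].
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Optional master seed; replicates are reproducible given
#'   the same seed.
#' @param block_size Replicates simulated per vectorized block (memory
#'   knob; the default keeps blocks around a million families).
#' @return A data frame with one row per replicate: `b_hat`, `se`,
#'   `t_stat`, `p_value`, `n_used`, `effective_depth`, `b_corrected`.
#' @export
run_replicates <- function(design, n_reps, seed = NULL,
                           block_size = NULL) {
  stopifnot(inherits(design, "design_point"),
            is.numeric(n_reps), n_reps >= 1)
  if (is.null(block_size)) {
    block_size <- max(1L, as.integer(1e6 / design$n_families))
  }
  n_reps <- as.integer(n_reps)
  starts <- seq.int(1L, n_reps, by = block_size)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    m <- min(block_size, n_reps - starts[i] + 1L)
    set_seed_if(derive_seed(seed, "power-block", i))
    out[[i]] <- simulate_block(design, m)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate power of the slope test for a design
#'
#' Runs `n_reps` Monte-Carlo replicates of simulate-then-fit for a
#' design and reports the fraction of replicates whose slope t-test is
#' significant at the design's `alpha`, with its binomial Monte-Carlo
#' standard error.
#'
#' @inheritParams run_replicates
#' @return An object of class `"power_result"`: list with `design`,
#'   `n_reps`, `n_significant`, `power`, `mc_se`, `seed`.
#' @export
run_power <- function(design, n_reps = 1000, seed = NULL,
                      block_size = NULL) {
  reps <- run_replicates(design, n_reps, seed, block_size)
  n_sig <- sum(reps$p_value < design$alpha, na.rm = TRUE)
  pw <- n_sig / n_reps
  structure(
    list(design = design, n_reps = as.integer(n_reps),
         n_significant = n_sig, power = pw,
         mc_se = sqrt(pw * (1 - pw) / n_reps), seed = seed),
    class = "power_result"
  )
}

#' Power at a marker locus linked to an unobserved causal locus
#'
#' Two-locus power study: phenotypes are generated from the causal
#' locus, the regression is run on the sequenced frequency of a marker
#' locus in LD `r` with it. This is [run_power()] restricted to designs
#' that carry an `ld_r`; with `r = 1` the two loci are identical and
#' one-locus power is recovered.
#'
#' @inheritParams run_replicates
#' @return A `"power_result"`.
#' @export
run_two_locus_power <- function(design, n_reps = 1000, seed = NULL,
                                block_size = NULL) {
  stopifnot(inherits(design, "design_point"))
  if (is.null(design$ld_r)) {
    stop("design has no 'ld_r': use run_power() for the one-locus model",
         call. = FALSE)
  }
  run_power(design, n_reps, seed, block_size)
}

#' @export
print.power_result <- function(x, ...) {
  print(x$design)
  cat(sprintf("  power = %.3f (%d / %d significant, MC se %.4f)\n",
              x$power, x$n_significant, x$n_reps, x$mc_se))
  invisible(x)
}

#' @export
as.data.frame.power_result <- function(x, ...) {
  d <- x$design
  data.frame(n_families = d$n_families, depth = d$depth,
             depth_kind = d$depth_kind, p = d$p, sigma_e = d$sigma_e,
             b = d$b, ld_r = if (is.null(d$ld_r)) NA_real_ else d$ld_r,
             per_read_error = d$per_read_error,
             call_genotypes = d$call_genotypes, alpha = d$alpha,
             effort = d$effort, n_reps = x$n_reps,
             n_significant = x$n_significant, power = x$power,
             mc_se = x$mc_se)
}

power_table <- function(results) {
  out <- do.call(rbind, lapply(results, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Power across designs with (almost) equal sequencing effort
#'
#' Runs [run_power()] for a set of candidate designs whose total
#' sequencing effort (`n_families * mean depth`) lies within a relative
#' tolerance of a nominal budget — the trade-off between many shallowly
#' sequenced families and few deep ones at fixed cost. Designs outside
#' the tolerance are rejected up front.
#'
#' @param total_effort Nominal budget in read-families (e.g. 12000 for
#'   4000 families at depth 3).
#' @param designs List of [design_point()]s.
#' @param n_reps Replicates per design.
#' @param seed Optional master seed (each design gets its own
#'   substream).
#' @param tolerance Allowed relative deviation of a design's effort from
#'   `total_effort` (default 0.25).
#' @return A data frame, one row per design ordered by effort then
#'   `n_families`, with design descriptors and `power`/`mc_se`.
#' @export
fixed_budget_grid <- function(total_effort, designs, n_reps = 1000,
                              seed = NULL, tolerance = 0.25) {
  stopifnot(is.numeric(total_effort), total_effort > 0, is.list(designs))
  if (length(designs) == 0L) stop("empty design grid", call. = FALSE)
  efforts <- vapply(designs, function(d) d$effort, numeric(1))
  off <- abs(efforts - total_effort) / total_effort > tolerance
  if (any(off)) {
    stop(sprintf(
      "design(s) %s exceed the +/-%.0f%% effort tolerance around %g",
      paste(which(off), collapse = ", "), 100 * tolerance, total_effort),
      call. = FALSE)
  }
  # ties in effort resolved toward larger sample size first
  ord <- order(efforts, -vapply(designs, function(d) d$n_families,
                                numeric(1)))
  designs <- designs[ord]
  res <- lapply(seq_along(designs), function(i) {
    run_power(designs[[i]], n_reps, derive_seed(seed, "budget", i))
  })
  power_table(res)
}

#' Stacked-error power study
#'
#' For each design, estimates power under three nested noise layers:
#' (i) binomial read sampling only, (ii) plus a 10% symmetric per-read
#' sequencing error, (iii) plus hard genotype calling to quarters.
#' Depth follows the design's depth model (the reference study uses
#' Poisson depths here, so that zero-read families occur and are
#' dropped).
#'
#' @param designs List of [design_point()]s (their own
#'   `per_read_error`/`call_genotypes` settings are overridden by the
#'   layer definitions).
#' @param n_reps Replicates per design and layer.
#' @param seed Optional master seed.
#' @param per_read_error Error rate of layers (ii) and (iii).
#' @return A data frame with one row per (design, layer); column `layer`
#'   is `"binomial"`, `"+seq_error"` or `"+calling"`.
#' @export
error_stacking_study <- function(designs, n_reps = 1000, seed = NULL,
                                 per_read_error = 0.10) {
  stopifnot(is.list(designs), length(designs) >= 1L)
  layers <- list(
    binomial     = c(eps = 0, call = FALSE),
    `+seq_error` = c(eps = per_read_error, call = FALSE),
    `+calling`   = c(eps = per_read_error, call = TRUE)
  )
  rows <- list()
  for (i in seq_along(designs)) {
    d0 <- designs[[i]]
    for (ln in names(layers)) {
      d <- design_point(
        n_families = d0$n_families, depth = d0$depth, p = d0$p,
        sigma_e = d0$sigma_e, b = d0$b, mu = d0$mu, ld_r = d0$ld_r,
        depth_kind = d0$depth_kind,
        per_read_error = unname(layers[[ln]]["eps"]),
        call_genotypes = as.logical(layers[[ln]]["call"]),
        alpha = d0$alpha)
      res <- run_power(d, n_reps, derive_seed(seed, "stack", i))
      row <- as.data.frame(res)
      row$layer <- ln
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("layer", setdiff(names(out), "layer"))]
}

#' Shipped design grids
#'
#' Ready-made design grids for the package's standard studies:
#' \describe{
#'   \item{`"fig2"`}{Effect-recovery grid: n = 4000, depths 3/7/15/30,
#'     p = 0.1/0.3/0.5, sigma_e = 4, b = 1 (12 designs).}
#'   \item{`"fig3"`}{Full one-locus power grid: n = 500/1000/2000/4000
#'     crossed with the same depths and frequencies (48 designs).}
#'   \item{`"fig4"`}{Fixed-budget subset: (4000, 3), (2000, 7),
#'     (1000, 15), (500, 30) at p = 0.1/0.3/0.5 (efforts
#'     12000-15000 read-families).}
#'   \item{`"fig5"`}{The fixed-budget pairs with Poisson depths, for
#'     [error_stacking_study()] (p = 0.3).}
#'   \item{`"table2"`}{Two-locus grid at n = 2000:
#'     (r, depth) = (0.95, 7), (0.7, 15), (0.3, 30) crossed with
#'     sigma_e = 2/4 and p = 0.1/0.3/0.5, plus the causal-locus
#'     reference designs (no LD, depth `causal_depth`) — 24 designs.}
#' }
#'
#' @param name Preset name.
#' @param causal_depth Sequencing depth of the causal-locus reference
#'   designs in `"table2"` (default 7).
#' @return A list of [design_point()]s.
#' @export
power_preset <- function(name = c("fig2", "fig3", "fig4", "fig5",
                                  "table2"),
                         causal_depth = 7) {
  name <- match.arg(name)
  mk <- function(grid, ...) {
    lapply(seq_len(nrow(grid)), function(i) {
      do.call(design_point, c(as.list(grid[i, , drop = FALSE]), list(...)))
    })
  }
  budget_pairs <- data.frame(n_families = c(4000, 2000, 1000, 500),
                             depth = c(3, 7, 15, 30))
  switch(name,
    fig2 = mk(expand.grid(n_families = 4000, depth = c(3, 7, 15, 30),
                          p = c(0.1, 0.3, 0.5))),
    fig3 = mk(expand.grid(n_families = c(500, 1000, 2000, 4000),
                          depth = c(3, 7, 15, 30), p = c(0.1, 0.3, 0.5))),
    fig4 = mk(merge(budget_pairs,
                    expand.grid(p = c(0.1, 0.3, 0.5)))),
    fig5 = mk(cbind(budget_pairs, p = 0.3), depth_kind = "poisson"),
    table2 = {
      marker <- expand.grid(sigma_e = c(2, 4), p = c(0.1, 0.3, 0.5),
                            pair = 1:3)
      rd <- data.frame(pair = 1:3, ld_r = c(0.95, 0.7, 0.3),
                       depth = c(7, 15, 30))
      marker <- merge(marker, rd)
      marker_designs <- lapply(seq_len(nrow(marker)), function(i) {
        design_point(n_families = 2000, depth = marker$depth[i],
                     p = marker$p[i], sigma_e = marker$sigma_e[i],
                     ld_r = marker$ld_r[i])
      })
      causal <- expand.grid(sigma_e = c(2, 4), p = c(0.1, 0.3, 0.5))
      causal_designs <- lapply(seq_len(nrow(causal)), function(i) {
        design_point(n_families = 2000, depth = causal_depth,
                     p = causal$p[i], sigma_e = causal$sigma_e[i])
      })
      c(marker_designs, causal_designs)
    })
}
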