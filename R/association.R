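# Allele-effect estimation for family pools: OLS regression of family
# phenotype on observed pool allele frequency, slope t-test, and the
# attenuation correction for binomial sequencing noise.

#' Regress family phenotypes on observed pool allele frequencies
#'
#' Ordinary least-squares fit of `phenotype = mu + b * g_obs + e`. The
#' slope `b_hat` estimates the effect per unit pool frequency — twice the
#' allele-substitution effect — attenuated by sequencing noise when
#' `g_obs` comes from finite-depth read counts (see
#' [correct_attenuation()]). Families with missing frequency (zero
#' depth) are dropped. Inference is the standard slope t-test with
#' `n_used - 2` degrees of freedom.
#'
#' @param phenotype Numeric vector of family phenotypes.
#' @param g_obs Numeric vector of observed pool allele frequencies
#'   (`NA` for families without reads), same length.
#' @return An object of class `"pool_assoc"`: list with `b_hat`,
#'   `intercept`, `se`, `t_stat`, `p_value`, `df`, `n_used`, and
#'   `NA`-initialized correction fields (`effective_depth`,
#'   `bias_factor`, `b_corrected`, `se_corrected`, `a_hat`).
#' @examples
#' g <- c(0, 0.25, 0.5, 0.75, 1)
#' fit_pool_regression(2 + 3 * g, g)$b_hat  # 3
#' @export
fit_pool_regression <- function(phenotype, g_obs) {
  stopifnot(is.numeric(phenotype), is.numeric(g_obs),
            length(phenotype) == length(g_obs))
  keep <- !is.na(g_obs) & !is.na(phenotype)
  y <- phenotype[keep]
  x <- g_obs[keep]
  if (length(x) < 3L) {
    stop("need at least 3 families with sequencing data to fit",
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("observed pool frequencies are constant: slope is not identifiable",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(summary(fit))
  structure(
    list(b_hat = cf["x", "Estimate"],
         intercept = cf["(Intercept)", "Estimate"],
         se = cf["x", "Std. Error"],
         t_stat = cf["x", "t value"],
         p_value = cf["x", "Pr(>|t|)"],
         df = fit$df.residual,
         n_used = length(x),
         effective_depth = NA_real_, bias_factor = NA_real_,
         b_corrected = NA_real_, se_corrected = NA_real_,
         a_hat = NA_real_),
    class = "pool_assoc"
  )
}

#' Correct a fitted slope for sequencing-noise attenuation
#'
#' Divides the raw slope by the attenuation factor `1 / (1 + 3 / S_T)`
#' evaluated at the harmonic-mean depth of the families used, recovering
#' an unbiased estimate of the effect per unit pool frequency; the
#' allele-substitution effect is half of that. The standard error is
#' scaled by the same factor (first-order treatment); the p-value is the
#' one from the uncorrected fit, which the rescaling leaves unchanged.
#'
#' @param fit A `"pool_assoc"` object from [fit_pool_regression()].
#' @param depths Per-family total read counts (zero-depth families are
#'   excluded from the harmonic mean, matching their exclusion from the
#'   fit).
#' @return The `"pool_assoc"` object with `effective_depth`,
#'   `bias_factor`, `b_corrected`, `se_corrected` and `a_hat` filled in.
#' @examples
#' g <- c(0, 0.25, 0.5, 0.75, 1)
#' fit <- fit_pool_regression(2 + 3 * g, g)
#' correct_attenuation(fit, depths = rep(3, 5))$b_corrected  # 6: slope / 0.5
#' @export
correct_attenuation <- function(fit, depths) {
  stopifnot(inherits(fit, "pool_assoc"))
  hd <- harmonic_mean_depth(depths)
  fit$effective_depth <- as.numeric(hd)
  fit$bias_factor <- attenuation_factor(fit$effective_depth)
  fit$b_corrected <- fit$b_hat / fit$bias_factor
  fit$se_corrected <- fit$se / fit$bias_factor
  fit$a_hat <- fit$b_corrected / 2
  fit
}

#' Estimate the allele effect from a family-pool dataset
#'
#' End-to-end estimator: computes observed pool frequencies
#' `g_obs = s1 / (s1 + s2)` per family, fits the phenotype-on-frequency
#' regression and applies the attenuation correction at the
#' harmonic-mean depth. Accepts a data frame (columns `s1`, `s2`,
#' `phenotype`, as produced by [simulate_pool_dataset()]) or the path of
#' a TSV dataset readable by [read_pool_dataset()].
#'
#' @param dataset Data frame or file path.
#' @return A `"pool_assoc"` object with raw and corrected effects.
#' @export
estimate_effect <- function(dataset) {
  if (is.character(dataset)) dataset <- read_pool_dataset(dataset)
  stopifnot(is.data.frame(dataset),
            all(c("s1", "s2", "phenotype") %in% names(dataset)))
  st <- dataset$s1 + dataset$s2
  g_obs <- as.numeric(ifelse(st > 0, dataset$s1 / st, NA_real_))
  fit <- fit_pool_regression(dataset$phenotype, g_obs)
  correct_attenuation(fit, depths = st)
}

#' @export
print.pool_assoc <- function(x, ...) {
  cat("Family-pool association fit\n")
  cat(sprintf("  families used      : %d (df = %d)\n", x$n_used, x$df))
  cat(sprintf("  raw slope b_hat    : %.4f  (se %.4f)\n", x$b_hat, x$se))
  cat(sprintf("  t = %.3f, p = %.3g\n", x$t_stat, x$p_value))
  if (!is.na(x$bias_factor)) {
    cat(sprintf("  effective depth    : %.3f (harmonic mean)\n",
                x$effective_depth))
    cat(sprintf("  attenuation factor : %.4f\n", x$bias_factor))
    cat(sprintf("  corrected effect b : %.4f  (se %.4f)\n",
                x$b_corrected, x$se_corrected))
    cat(sprintf("  allele effect a    : %.4f (= b/2)\n", x$a_hat))
  }
  invisible(x)
}

#' @export
as.data.frame.pool_assoc <- function(x, ...) {
  data.frame(b_hat = x$b_hat, se = x$se, t_stat = x$t_stat,
             p_value = x$p_value, df = x$df, n_used = x$n_used,
             effective_depth = x$effective_depth,
             bias_factor = x$bias_factor, b_corrected = x$b_corrected,
             se_corrected = x$se_corrected, a_hat = x$a_hat)
}
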