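#' Single-locus model for F2-family pools
#'
#' Bundles the parameters of the additive one-locus model underlying
#' family-pool association mapping: the population frequency `p` of the
#' counted allele in the parents, the regression effect `b` per unit pool
#' allele frequency (the quantity the phenotype-on-frequency regression
#' estimates), the phenotype intercept `mu`, and the environmental
#' standard deviation `sigma_e`. The allele-substitution effect per allele
#' copy is `a = b / 2` and is always derived from `b`, never stored
#' independently, so the two parameterizations cannot drift apart.
#'
#' @param p Population allele frequency in `[0, 1]`.
#' @param b Effect per unit pool allele frequency (phenotype units). The
#'   regression of family phenotype on pool frequency estimates `b`, which
#'   equals twice the allele-substitution effect.
#' @param mu Phenotype intercept (phenotype units). Default 0.
#' @param sigma_e Environmental standard deviation (phenotype units),
#'   must be non-negative.
#' @return An object of class `"locus_model"`: a list with elements
#'   `p`, `b`, `a` (`= b/2`), `mu`, `sigma_e`.
#' @examples
#' m <- locus_model(p = 0.3, b = 1, sigma_e = 4)
#' m$a  # 0.5
#' @export
locus_model <- function(p, b = 1, mu = 0, sigma_e = 4) {
  check_prob(p, "p")
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma_e) || length(sigma_e) != 1L || !is.finite(sigma_e) ||
      sigma_e < 0) {
    stop("'sigma_e' must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(p = p, b = b, a = b / 2, mu = mu, sigma_e = sigma_e),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat("One-locus F2 pool model\n")
  cat(sprintf("  allele frequency p : %g\n", x$p))
  cat(sprintf("  effect b (= 2a)    : %g  (a = %g)\n", x$b, x$a))
  cat(sprintf("  intercept mu       : %g\n", x$mu))
  cat(sprintf("  environmental SD   : %g\n", x$sigma_e))
  invisible(x)
}

# shared validators ---------------------------------------------------------

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}

as_locus_model <- function(x) {
  if (inherits(x, "locus_model")) return(x)
  stop("expected a 'locus_model' object; see locus_model()", call. = FALSE)
}
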