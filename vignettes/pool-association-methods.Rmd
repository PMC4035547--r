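---
title: "Association mapping with F2-family pool allele frequencies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping with F2-family pool allele frequencies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolassoc)
```

## The problem

In outcrossing forage crops such as perennial ryegrass, yield and
persistency are measured on plots sown with F2 full-sib families, not on
individual plants. The individuals inside a family are genetically
heterogeneous, so there is no single "genotype" to associate with the
plot phenotype. `poolassoc` implements an association framework built on
two observations:

1. An F2 family from a pair cross carries up to four copies of each
   allele (two per parent), so its aggregate locus content behaves like
   a **tetraploid genotype**: the within-family allele frequency takes
   one of the five values $g \in \{0, \tfrac14, \tfrac12, \tfrac34, 1\}$.
2. Genotyping-by-sequencing (GBS) of a pooled DNA sample of the family
   estimates exactly this frequency as a read-count ratio
   $\hat g = S_1 / S_T$ — there is no need to call genotypes at all.

Under additivity, the family phenotype is linear in the pool frequency,

$$P = \mu + b\,g + e, \qquad e \sim N(0, \sigma_e^2),$$

and the regression coefficient $b$ equals **twice the
allele-substitution effect** $a$, because one unit of pool frequency
corresponds to two allele copies per individual. The package estimates
$b$ by ordinary least squares (`fit_pool_regression()`, a front end to
`stats::lm`), reports the slope t-test, and maps back to $a = b/2$.

## Pool genotype distribution

With parental allele frequency $p$ and random mating, the number of
counted-allele copies among the four parental copies is
$\mathrm{Binomial}(4, p)$, giving the five-point distribution computed
by `pool_genotype_probs()`. The same distribution arises by enumerating
the six parental mating types (`mating_table()`); the identity of the
two routes is tested numerically across random $p$. The associated
variances are

* individuals: $\mathrm{Var}(G) = 2p(1-p)a^2$
  (`genetic_variance_individual()`),
* family pools: $\mathrm{Var}(G_{\mathrm{pool}}) = p(1-p)a^2$, half the
  individual-scale variance; on the frequency scale $p(1-p)/4$
  (`genetic_variance_pool()`).

## Measurement error and the attenuation correction

Sequencing to finite total depth $S_T$ adds binomial sampling noise to
the frequency estimate. Averaged over the five pool genotypes the noise
variance is

$$\sigma^2_{\mathrm{bin}} = \sum_k g(k)\,(1-g(k))\,\Pr(k)\,/\,S_T
  = \frac{3p(1-p)}{4S_T},$$

(`binomial_noise_variance()`), and classical errors-in-variables theory
then shrinks the expected regression slope by the reliability ratio

$$\frac{\mathrm{Var}(g)}{\mathrm{Var}(g) + \sigma^2_{\mathrm{bin}}}
  = \frac{1}{1 + 3/S_T},$$

which — remarkably — does not depend on $p$ (`attenuation_factor()`). At
depth 3 the estimate is halved; at depth 30 about 9% of the effect is
still lost. `correct_attenuation()` divides the raw slope (and, as a
first-order treatment, its standard error) by this factor; when depth
varies across families the **harmonic mean** of the per-family depths is
used (`harmonic_mean_depth()`), with zero-depth families excluded as
missing. The p-value is taken from the uncorrected fit: rescaling slope
and standard error by the same constant leaves the t statistic
unchanged, and no separate inferential theory is attached to the
corrected estimate.

Two interpretation notes. The harmonic-mean rule is implemented as the
plain (equally weighted) harmonic mean over families with nonzero
depth — the natural reading when every family contributes one
observation. And an infeasible correction cannot arise: the factor is
strictly inside $(0,1)$ for finite depth.

## The simulator

`simulate_pool_dataset()` chains three generators, each reproducible
from a single master seed via deterministic substreams (so the pools,
phenotype and read layers can also be re-drawn independently):

* `simulate_pools()` draws true pool frequencies from the five-point
  distribution;
* `simulate_phenotypes()` adds the linear effect and Gaussian
  environmental noise;
* `simulate_read_counts()` draws the total depth per family — constant,
  or Poisson with mean $\lambda$ (`depth_model()`), in which case a
  family is missing with probability $e^{-\lambda}$
  (`prob_zero_reads()`; about 0.7% at mean depth 5) — and then the
  allele counts $S_1 \sim \mathrm{Binomial}(S_T, g')$.

A symmetric per-read error rate $\varepsilon$ is folded into the
binomial success probability as
$g' = g(1-\varepsilon) + (1-g)\varepsilon$, which is distributionally
identical to flipping reads individually but far cheaper. Hard genotype
calling is modelled by `call_genotype()`, which forces the observed
frequency to the nearest quarter; exact midpoints round to the higher
quarter (the calling rule is not prescribed anywhere, so a deterministic
convention was chosen and documented).

For a marker linked to an unobserved causal locus, two loci with allele
frequencies $p_1, q_1$ and LD correlation $r$ are modelled through the
haplotype frequencies $x_{11} = p_1 q_1 + D$ etc., with
$D = r\sqrt{p_1(1-p_1)q_1(1-q_1)}$ (`haplotype_frequencies()`). A
requested $r$ that would drive a haplotype frequency negative is
rejected loudly rather than clipped, so a study never silently runs at a
different LD level than asked for. Each family pool is four i.i.d.
haplotype draws (`simulate_two_locus_pools()`); the pool-frequency
correlation across families then equals $r$ exactly.

What the generator deliberately does not emulate: read-level artefacts
(base quality, mapping error beyond the symmetric flip), relatedness
between parents, inbreeding, dominance, selection or drift in the F1
multiplication, and LD decay along a chromosome (a single marker-causal
pair is simulated). Passing tests therefore validate the statistical
machinery under the stated genetic model, not the full messiness of real
GBS data.

## The power engine

`run_power()` estimates power as the fraction of Monte-Carlo replicates
whose slope t-test is significant at $\alpha$ (default 0.05, two-sided),
with binomial Monte-Carlo standard error
$\sqrt{\hat\pi(1-\hat\pi)/n_{\mathrm{reps}}}$. The replicate loop is
vectorized: a block of replicates is drawn as one matrix and the
simple-regression statistics are computed column-wise in closed form.
This path is algebraically identical to `lm` — the test suite checks
slope, standard error, t and p per replicate against `stats::lm` on the
same draws — and makes a 12-design × 1000-replicate study a matter of
seconds. Replicates with a degenerate design matrix (constant observed
frequency, or fewer than three sequenced families) return `NA` and count
as non-significant.

Standard studies are shipped as presets (`power_preset()`):

* `"fig2"` — effect recovery: n = 4000, depths 3/7/15/30,
  p = 0.1/0.3/0.5; the mean raw slope tracks $1/(1+3/S_T)$ and the mean
  corrected slope recovers $b$;
* `"fig3"`/`"fig4"` — the one-locus power grid and its fixed-budget
  subset (4000×3, 2000×7, 1000×15, 500×30 read-families;
  `fixed_budget_grid()` enforces a ±25% effort band and breaks effort
  ties toward the larger sample size);
* `"fig5"` — the fixed-budget pairs with Poisson depths for
  `error_stacking_study()`, which stacks binomial sampling, 10% per-read
  error, and genotype calling. The source study does not state the
  allele frequency for this experiment; the preset fixes p = 0.3, the
  middle scenario, and none of that experiment's printed powers are used
  as checks;
* `"table2"` — the two-locus grid at n = 2000: (r, depth) =
  (0.95, 7), (0.7, 15), (0.3, 30) — LD levels chosen as successive
  halvings of SNP density, each paid for by doubling depth — crossed
  with $\sigma_e \in \{2, 4\}$ and p ∈ {0.1, 0.3, 0.5}, plus
  causal-locus reference designs. The depth at which the causal locus
  itself is sequenced is not stated in the source; it is a parameter
  (`causal_depth`, default 7).

Both loci of a two-locus design share one allele frequency; this matches
the single frequency quoted per scenario and keeps $r = 0.95$ feasible
at every frequency used.

### Numerical and design choices

* **Seeding.** One master seed; every operation and replicate block
  derives an independent substream from (seed, tag, index) by a
  multiplicative hash below $2^{31}$. Identical seeds give bit-identical
  datasets and byte-identical CLI output tables.
* **Test sizes.** Distributional checks run at $n = 10^5$ draws with
  3-standard-error bands; replicated studies in the acceptance suite use
  the studies' own 1000 replicates at their stated sample sizes (the
  full effect-recovery grid is 12 designs × 1000 replicates × 4000
  families), which keeps the whole suite within a few minutes on one
  core.
* **Type-I calibration.** Null designs ($b = 0$) hold the 5% size
  within Monte-Carlo error across one-locus, Poisson-depth and
  two-locus families, and null p-values are uniform
  (Kolmogorov–Smirnov).
* **Serialization.** TSV output carries 6 significant digits,
  tab-separated, locale-independent; JSON results keep full precision.

## Known limitations

The corrected standard error is a first-order (delta-method) rescaling;
it ignores uncertainty in the estimated effective depth. Single-locus
inference only: no multi-SNP joint models, kinship correction or
multiple-testing control — one SNP, one regression, as appropriate for
the design stage this package targets. Replicated two-locus runs at the
lowest allele frequency (p = 0.1) with high LD reproduce the closed-form
attenuation theory exactly but sit a few points above the corresponding
published simulation powers, consistent with the source's own remark
that its simulations deviate slightly from theory at low allele
frequency and small effective signal.
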