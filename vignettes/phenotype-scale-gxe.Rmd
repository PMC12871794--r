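---
title: "Phenotype scale and PGS×E interactions: methods and design notes"
author: "scaleGxE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype scale and PGS×E interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and what it assumes

`scaleGxE` tests whether a polygenic score × environment (PGS×E)
interaction in a positive quantitative trait is a property of the trait or
a property of the scale the trait happens to be recorded on. The working
model is ordinary least squares on a transformed phenotype:

$$y^*_\lambda = \mu + \mathrm{PGS}\,\beta + E\,\alpha +
(\mathrm{PGS}\cdot E)\,\gamma + C\eta + (C\cdot E)\,\sigma + \varepsilon,$$

where $y^*_\lambda$ is the Box-Cox transform $(y^\lambda - 1)/\lambda$
(with $\log y$ at $\lambda = 0$) and $C$ is a covariate matrix. The
covariate-by-environment block $(C\cdot E)\sigma$ is not optional
decoration: omitting it lets confounder effects that differ by environment
masquerade as PGS×E. The interaction is judged by a two-sided Wald t-test
on $\hat\gamma$ with residual degrees of freedom (a joint F-test over the
interaction contrasts when $E$ is a multi-level factor). Classical
standard errors are the default because the procedure profiles a plain
linear model; heteroskedasticity-robust (HC1) errors are available via
`robust = TRUE` in `fitInteraction()`.

Profiling this p-value over a λ grid (default: 25 evenly spaced points on
$[-1, 2]$, which contains both $\lambda = 0$ and $\lambda = 1$ exactly)
plus the rank inverse normal transformation (RINT) yields a
`LambdaProfile`. The classification rule is deliberately blunt:

* `not_significant` — p at $\lambda = 1$ is at or above the threshold;
* `scale_independent` — p below the threshold at **every** grid λ;
* `scale_dependent` — significant untransformed but rescued by some λ.

RINT is reported alongside but excluded from the classification: it is not
a member of the power family, and a rank map cannot be inverted back to a
measurement scale. The significance threshold defaults to a Bonferroni
correction of 0.05 over the number of transformations tested in one
profile — $0.05/26$ with the default grid plus RINT. This denominator is a
genuine design choice (one could instead correct over scores, or over
scores × transformations); it is configurable through `alpha` /
`threshold` in `profileLambda()`, and every rejection-rate experiment in
the package states the threshold it used in its output.

Scale-dependence is defined *relative to the family considered*: a
classification of `scale_dependent` means a power transform removes the
signal; `scale_independent` means no power transform does, not that no
transformation whatsoever could. Richer families (shifted power,
Yeo-Johnson) are out of scope.

## The generative simulation

`simulateCohort()` draws from the latent model

$$Y' = G\beta + E\alpha + (G*E)\gamma + \varepsilon,\qquad
Y = f(Y' + s),$$

with $G$ an $n \times m$ matrix of independent standard-normal scores,
$\varepsilon \sim N(0,1)$, and $f$ one of identity, exponential or
inverse-logit. Defaults are $n = 100{,}000$, $m = 25$, $h^2 = 0.3$,
environment variance $0.2$. Design decisions a reader should know about:

* **Variance bookkeeping.** The noise has unit variance and supplies the
  residual fraction, so the total latent variance is
  $1/(1 - h^2 - v_E)$; $\beta$ (constant across columns) and $\alpha$ are
  scaled to give the genetic and environmental components their stated
  fractions. With $\gamma \neq 0$ the interaction variance sits on top of
  these fractions rather than being squeezed out of them.
* **The environment is binary by default** (Bernoulli(0.5), coded 0/1),
  i.e. Sex-like; a Gaussian option exists (`envType = "gaussian"`). This
  choice matters more than it looks — see the RINT section below.
* **γ is a scalar applied to every score column.** The alternative (a
  per-column vector, or one affected column) is representable by editing
  `trueBeta`/`trueGamma` downstream but is not the default reading.
* **Positivity.** Box-Cox needs $y > 0$. The exponential and
  inverse-logit maps are already positive, so no shift is applied there.
  On the identity scale the automatic rule places the minimum latent value
  six latent standard deviations above zero; the shift is configurable,
  and `boxCox()` itself never shifts silently — it errors, naming the
  smallest offending value, because a hidden shift would change the scale
  being tested.
* **Per-score testing.** Every score column is tested in its own model
  ($y^* \sim g_j * E$); rejection rates pool columns and replicates. An
  internal closed-form scan (`scanInteractions()`) makes this cheap and is
  held equal to `fitInteraction()` by the test suite.

`simulateGenotypeCohort()` generates unlinked SNP panels
(dosages Binomial(2, f), positions 1-based on a single chromosome with
uniform spacing) with known, optionally group-specific, effects, and an
optional multiplicative (`exp`) observation map. What the generator does
**not** emulate: linkage disequilibrium structure, minor-allele and
Hardy–Weinberg QC, relatedness, population stratification, missing
genotypes. Tests passing on these panels therefore say nothing about
LD-aware clumping behaviour on real chromosomes beyond the greedy
definition itself, and nothing about confounding from structure.

## Why RINT stays calibrated here (and when it would not)

The package's null experiments (γ = 0) apply RINT to the observed
phenotype and test PGS×E. Because RINT only sees ranks, its result is
identical across the three observation scales — a property the suite
checks with matched latent seeds. Something stronger holds under the
default conditions: the latent trait is Gaussian given $(G, E)$, and with
a *balanced binary* (or any symmetric) environment the marginal
distribution is symmetric, so the composed quantile map
$h = \Phi^{-1} \circ F$ is odd about its centre. The two environment
groups are mirror images through that centre, their conditional-mean
slopes in the score are equal, and the population interaction coefficient
after RINT is exactly zero. The RINT interaction test is therefore
calibrated (in our runs, if anything slightly conservative at the
Bonferroni threshold) — this is what `scripts/acceptance.R` measures at
full scale. With a *skewed* environment (an unbalanced exposure, a skewed
ordinal scale) the symmetry breaks and the same test can inflate
dramatically; users applying RINT to interaction tests should treat the
symmetry of $E$ as a load-bearing assumption, not a detail.

## The GWAS / PRS layer

`runGwas()` is per-SNP OLS with covariates, implemented by
Frisch–Waugh residualisation with exact degrees of freedom (held equal to
`lm()` by the tests). Zero-variance SNPs yield missing statistics and a
warning, not an error. `clumpSnps()` is the standard greedy procedure:
smallest p first (ties: position, then id), absorb unassigned neighbours
with $r^2 \ge 0.1$ within 250 kb; missing LD entries count as $r^2 = 0$
(conservative toward more leads) and are reported. `sharedHits()` clumps
the per-SNP minimum of two studies' p-values and labels each significant
lead `shared`/`a_only`/`b_only` by comparing each study's own p-value to
the same genome-wide threshold ($5\times10^{-8}$ on both sides; a relaxed
within-study threshold would be a defensible alternative reading).

`buildPrs()` is clump-then-threshold with weights equal to GWAS betas,
tuned over a p-value grid from $5\times10^{-8}$ to 0.5 by R² on the
tuning cohort *on the training scale*, first maximum on ties.
`evaluatePrs()` implements the scale-aware evaluation model: a log-trained
score evaluated on the default scale enters the regression exponentiated,
$y = \exp(\mathrm{PGS}_{\log})\beta + C\eta + \varepsilon$; R² is the
squared Pearson (or Spearman) correlation between the phenotype on the
evaluation scale and the fitted values, with per-group values obtained by
refitting within each group (not by slicing pooled residuals — pooled
slicing would inherit the dominant group's slope). Spearman R² without
covariates is exactly invariant to increasing transforms of $y$; with
covariates the fitted values are no longer monotone in the score and the
invariance is only approximate.

`naiveGeneticCorrelation()` is the Pearson correlation of two GWAS's
effect estimates over independent SNPs. It is a desk-scale stand-in for a
proper genetic correlation: it ignores LD (acceptable for the unlinked
panels generated here), does not de-attenuate sampling error, and needs at
least 10 SNPs by fiat. The CV experiment (`runCvExperiment()`) uses it on
group-stratified GWAS of a multiplicative two-group trait: the latent
(log-scale) variance is set from the target coefficient of variation via
the lognormal identity $CV^2 = e^{\sigma^2} - 1$, and within each
replicate the same panel, effects and noise are reused across all CV
levels so that the CV → distortion curve is isolated from Monte-Carlo
noise rather than buried in it.

## Numerical and degenerate-input choices

* $|\lambda| < 10^{-12}$ is treated as $\lambda = 0$ in `boxCox()` to
  avoid catastrophic cancellation near the log limit; continuity there is
  tested to $10^{-6}$.
* RINT uses the Blom offset, $\Phi^{-1}((r - 3/8)/(n + 1/4))$, mean ranks
  on ties — the common GWAS convention; other offsets change nothing that
  matters at biobank $n$.
* Outlier filtering uses linear-interpolation (type 7) quantiles with
  strict exclusion. This is *not* idempotent: each application trims up to
  the tail fraction of the remaining sample again, because the quantiles
  are recomputed on the filtered set. The suite documents this rather than
  pretending otherwise; filter once.
* Zero-variance phenotype, score or environment, and rank-deficient
  designs (after contrast expansion) are errors that name the offending
  columns; profiling errors are annotated with the offending λ.
* Ties in clumping are broken by position then id; threshold selection
  takes the first maximum. Determinism over input row order is tested.
* GWAS p-values are clamped at the smallest positive double so that
  noiseless fits stay inside $(0, 1]$.

## Problem sizes

The test suite runs the study-level experiments at $n = 20{,}000$ with
25 scores (calibration: 200 replicates; inflation/correction: 100;
power: 50 with γ recalibrated by $\sqrt{100{,}000/20{,}000}$ to preserve
the reference noncentrality; recovery: 50 single-score replicates), sizes
chosen so the whole suite completes in a few minutes while keeping the
binomial error of rejection-rate checks meaningfully small.
`scripts/acceptance.R` runs the RINT null experiment at the full
$n = 100{,}000$ with 100 replicates per observation scale.

## Known limitations

Single-score linear interaction tests only — no variance-QTL or
mixed-model G×E, no binary-trait link-function profiling. The power family
is one-parameter Box-Cox; traits needing a shift or a non-power rescue are
declared scale-independent by this procedure even when a richer family
would remove the signal, so the scale-dependent fraction it reports is a
lower bound. The genotype simulator's lack of LD makes clumping exact but
easy; real-panel behaviour depends on the LD source supplied. And the
naive effect-size correlation is only as good as the independence and
precision of the SNPs fed to it.
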