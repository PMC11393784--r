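---
title: "Two-sample Mendelian randomization with two-step mediation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with two-step mediation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepmr)
```

## The inference problem

Observational associations between a modifiable exposure (say, age at
menarche) and a disease outcome (say, nonalcoholic fatty liver disease)
are confounded. Two-sample Mendelian randomization (MR) sidesteps
confounding by using genetic variants as instruments: a variant that
robustly associates with the exposure, is assigned at conception, and
affects the outcome only through the exposure provides a natural
experiment. "Two-sample" means the exposure and outcome associations come
from different GWAS, so only summary statistics — per-variant effect
sizes, standard errors, allele frequencies — are needed.

For variant $j$ with exposure association $\hat\gamma_j$ (SE
$\sigma_{Xj}$) and outcome association $\hat\Gamma_j$ (SE $\sigma_{Yj}$),
the Wald ratio $r_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal
effect $\theta$. All estimators in this package are functionals of the set
$\{r_j\}$ with first-order SEs $s_j = \sigma_{Yj}/|\hat\gamma_j|$ and
inverse-variance weights $w_j = 1/s_j^2$.

This package additionally quantifies *mediation*: given an exposure $X$, a
candidate mediator $M$ and an outcome $Y$, two-step MR estimates the total
effect $\beta_0$ ($X \to Y$), the exposure–mediator effect $\beta_1$
($X \to M$) and the mediator–outcome effect $\beta_2$ ($M \to Y$), each by
an independent univariable MR. The indirect effect is the product
$\beta_1\beta_2$ and the mediated proportion is
$\beta_1\beta_2 / \beta_0$.

## Instrument selection and harmonization

Instruments are selected by three filters applied in order:

* **p-value threshold** — default $5\times10^{-8}$ (genome-wide
  significance); a relaxed preset of $5\times10^{-7}$ is provided for
  exposures with few hits and $5\times10^{-6}$ for reverse-direction
  analyses, where the instrumented trait's GWAS is typically less
  powered.
* **LD clumping** — greedy: keep the smallest-p remaining variant,
  discard every variant within 10,000 kb on the same chromosome with
  $r^2 > 0.001$ against it, repeat. The package takes LD as an explicit
  input (`ld_matrix()` or `ld_independent()`) instead of querying a
  reference panel, which keeps the algorithm testable and the tool
  offline; `simulate_ld_blocks()` produces block-diagonal LD for
  exercising the algorithm.
* **Instrument strength** — the per-variant F-statistic is computed as
  $\hat\gamma_j^2/\sigma_{Xj}^2$ and variants with $F < 10$ are dropped
  (F equal to 10 is kept).

Harmonization re-expresses every outcome association on the exposure's
effect-allele frame. Same-pair alignments are kept or sign-flipped;
complementary-strand reports (A/G vs T/C) are re-complemented first. For
palindromic variants (A/T, G/C) the allele labels cannot identify the
strand, so orientation is resolved by comparing effect-allele frequencies;
when either frequency lies inside the band (0.42, 0.58) — or is missing —
the frequency signal is considered uninformative and the variant is
dropped as ambiguous. The band is a convention: inside it, sampling noise
and population differences can flip which allele looks like the minor one.
Every action (`unchanged`, `flipped`, `dropped_palindromic`,
`dropped_incompatible`) is recorded per variant.

## The estimator suite

Five estimators are applied to each harmonized instrument set, each with a
different robustness profile:

* **IVW** (primary): $\hat\theta = \sum w_j r_j / \sum w_j$. Fixed-effects
  SE $(\sum w_j)^{-1/2}$; the multiplicative random-effects model scales
  the SE by $\sqrt{\max(Q/(L-1), 1)}$ and is selected automatically when
  Cochran's $Q$ has $p < 0.05$ (the switching rule used in applied work,
  and this package's `effects_model = "auto"` default). Unbiased only if
  every instrument is valid.
* **MR-Egger**: weighted regression of outcome on exposure effects with a
  free intercept, instruments oriented so exposure effects are positive.
  The slope is robust to directional pleiotropy under the InSIDE
  assumption; the intercept estimates mean directional pleiotropy and
  furnishes a pleiotropy test. Inference uses $t_{L-2}$.
* **Weighted median**: the 50th percentile of the weight-standardized
  ratio distribution (cumulative weights $p_j = (S_j - w_j/2)/S_L$,
  linear interpolation at $p = 0.5$). Consistent while valid instruments
  hold $\ge 50\%$ of the weight. SE by parametric bootstrap
  ($r_j^* \sim N(r_j, s_j)$, seeded).
* **Simple and weighted mode**: the argmax of a normal-kernel density of
  the ratios, evaluated on a 512-point grid spanning the ratio range
  $\pm 3$ bandwidths. The default bandwidth is
  $0.9 \cdot \mathrm{MAD}(r) \cdot L^{-1/5}$ (falling back to the SD when
  the MAD degenerates), scaled by a user-visible `bandwidth_factor`.
  Consistent when the largest group of instruments sharing a ratio is
  valid. SE by seeded bootstrap.

Binary outcomes analysed on the log-odds scale are reported as odds
ratios per SD of the exposure via `beta_to_or()`, with rounding to three
decimals left to the reporting layer.

### Standard errors for the IVW estimate

The first-order ratio SE ignores the exposure-side uncertainty. That is
standard and harmless when the exposure GWAS dwarfs the outcome GWAS, but
at comparable sample sizes the neglected term —
$r_j^2\sigma_{Xj}^2/\hat\gamma_j^4$ in the ratio variance — is roughly
$\theta^2$ of the total, and the IVW interval visibly undercovers (about
93% empirical coverage at nominal 95% in this package's calibration
simulations). `mr_ivw()` therefore exposes `ratio_se = "second"`, which
keeps the first-order weights for the *point estimate* (re-weighting by
outcome-dependent second-order variances would bias the estimate toward
zero) but pools the second-order variances into the reported SE:
$\mathrm{Var}(\hat\theta) = \sum w_j^2 v_{2j} / (\sum w_j)^2$. The
pipeline functions default to this second-order SE; `mr_ivw()` called
directly defaults to the textbook first-order formula.

## Diagnostics

* **Cochran's Q** over the ratios with $\chi^2_{L-1}$ reference;
  heterogeneity beyond sampling noise suggests pleiotropy.
* **Egger intercept test** as above.
* **Leave-one-out**: the primary IVW estimate recomputed excluding each
  variant; a row is flagged if the exclusion flips the sign of the
  estimate or moves it outside the all-variant confidence interval.
* **MR-PRESSO**: the observed residual sum of squares
  $\sum_j w_j (r_j - \hat\theta^{(-j)})^2$ (leave-one-out predictions) is
  compared with a null distribution built by redrawing all summary
  statistics from their reported sampling distributions around the
  no-pleiotropy fit. The global p is the exceedance fraction; per-variant
  exceedance p-values declare outliers at `outlier_alpha / L`
  (Bonferroni); the distortion test compares the estimates before and
  after outlier removal against removals of random non-outlier subsets of
  the same size. Defaults (`n_sim = 1000`, `outlier_alpha = 0.05`) follow
  the original method's conventions. All draws happen inside
  `withr::with_seed()` in a fixed order (exposure matrix, outcome matrix,
  then permutations), so a seed fully determines the result.

## Two-step mediation

$\beta_0$, $\beta_1$ and $\beta_2$ are estimated by three univariable IVW
pipelines. A candidate mediator is screened out when its own effect on the
outcome is not significant at 0.05 — a trait with no credible outcome
effect cannot transmit one. The indirect effect is $\beta_1\beta_2$ with
first-order delta-method SE
$\sqrt{\beta_1^2 s_2^2 + \beta_2^2 s_1^2}$ (the cross term $s_1^2 s_2^2$
is available behind `second_order = TRUE`; the cross-covariance is zero
for non-overlapping samples). The mediated proportion is
$100\cdot\beta_1\beta_2/\beta_0$ percent, with a confidence interval
obtained by dividing the indirect-effect CI bounds by $\beta_0$ and
ordering them — the convention under which the proportion interval remains
arithmetically consistent with the indirect-effect interval it is printed
next to. A delta-method-on-the-ratio alternative (propagating $s_0$) is
available via `method = "delta"`.

Because $\beta_2$ comes from *univariable* MR of the mediator on the
outcome, mediator instruments that also track the exposure fold part of
the direct path into $\beta_2$. The results therefore carry the standard
caveat that $\beta_2$ is unadjusted for the exposure; multivariable MR is
out of scope.

### Reporting convention

`report_mediation()` rounds the indirect effect and its CI bounds to three
decimals *first* and derives the displayed proportion (two decimals) from
the rounded values, while always carrying the full-precision numbers in
parallel columns. Published mediation tables are typically assembled this
way — the displayed proportion equals displayed-indirect over displayed-
total — and the package reproduces the shipped reference table
(`reference_mediation_table()`) digit for digit under exactly this
convention; from full-precision values the last printed digit can differ.

## The synthetic-data generator

`simulate_chain()` draws GWAS summary statistics under a known causal
chain so that every pipeline stage can be tested against generative
truth. Three disjoint locus sets mirror the architecture that makes
two-step mediation identifiable in practice:

* $L = 100$ exposure loci, per-allele effects
  $\gamma_j \sim N(0, 0.06^2)$ — instrument strength comparable to a
  well-powered continuous-trait GWAS at $n = 10^5$ (median F in the low
  hundreds before selection);
* 100 mediator-specific loci with effects $\sim N(0, 0.15^2)$ — the
  mediator's own hits, which dominate its instrument set the way BMI's do;
* 100 outcome-specific loci with effects $\sim N(0, 0.1^2)$ — the
  disease's own susceptibility loci, which are what a reverse-direction
  analysis instruments.

Causal effects default to $\kappa = 0.4$ (exposure to mediator),
$\theta_M = 0.5$ (mediator to outcome) and $\theta_{dir} = 0.1$ (direct),
so the total effect is $0.3$ and the true mediated proportion is $2/3$.
Observation noise has SE $1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ (the
standardized-trait approximation), samples are non-overlapping, allele
frequencies are drawn in $(0.05, 0.5)$ and 20% of variants get
palindromic allele pairs to exercise the harmonization path. Horizontal
pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ can be applied
to a configurable fraction of exposure loci (balanced when
$\mu_\alpha = 0$).

What the generator deliberately does *not* emulate: realistic LD from
haplotypes (LD is block-diagonal by construction), winner's-curse-free
replication samples, case–control ascertainment, a liability-threshold
model for the binary outcome (log-odds are treated as linear in the
instrument effects), or sample overlap. Passing tests therefore show that
the estimators and their calibration behave as designed under a clean
two-sample model — not that any particular epidemiological claim about
real traits is correct.

Two residual imperfections are worth knowing about, both visible in the
calibration suite: selecting instruments in the same exposure GWAS that
supplies $\hat\gamma_j$ induces a small winner's-curse attenuation
(absolute IVW bias on the order of $2\times10^{-3}$ at the default
settings), and exposure loci strong enough to pass the mediator's
selection threshold leak a few tenths of a percentage point of upward
bias into the estimated mediated proportion. Both are properties of the
standard analysis itself, not of the implementation.

## Numerical choices and degenerate inputs

* 95% intervals use the normal quantile (1.959964) except MR-Egger, which
  uses $t_{L-2}$.
* All stochastic operations (bootstraps, MR-PRESSO, the generator) take an
  explicit integer seed and run inside `withr::with_seed()`; nothing
  consumes or perturbs the caller's RNG state, and a fixed seed
  reproduces every output byte for byte.
* Empirical p-values are plain exceedance fractions and may be exactly 0
  at finite `n_sim`; the Bonferroni outlier cut at small `n_sim`
  effectively requires an observed residual beyond every simulated one.
* Degenerate inputs: pairs with $\hat\gamma_j = 0$ are dropped from ratio
  computations with a warning; all-equal ratios give $Q = 0$ and a mode
  estimate at the common value (the kernel bandwidth falls back from MAD
  to SD, and to the median when both degenerate); estimators require 1
  (IVW), 2 (Q), 3 (Egger, median, mode, leave-one-out) or 4 (MR-PRESSO)
  variants and raise informative errors below that.
* Duplicate rsids keep the smallest-p row; tied p-values keep the first
  occurrence, making loading deterministic.
* `ld_clump()` with `r2_max = 1` and window 0 is the identity;
  `ld_independent()` declares the identity LD matrix implicitly.

## Problem sizes in the test and acceptance suites

The suites were sized to establish calibration, not to squeeze the last
decimal: 1000 replicates for IVW bias/coverage, 2000 (tests) / 1000
(acceptance script) null replicates for the IVW and Cochran-Q rejection
rates, 500 replicates for the MR-PRESSO type-I rate and 100 for its
planted-outlier detection (at `n_sim = 300`), and 200 (tests) / 100
(script) full two-step replicates for mediated-proportion recovery. At
these sizes the whole test suite runs in a couple of minutes on one CPU.

## Known limitations

* No multivariable MR: $\beta_2$ is unadjusted (flagged in reports).
* No Steiger directionality filtering; direction is probed only by the
  bidirectional design.
* No proxy-variant lookup: instruments absent from the outcome table are
  dropped (with a count) rather than replaced by LD proxies.
* Palindromic variants with near-0.5 frequencies are discarded, which is
  conservative and can cost instruments.
* The generator's binary-outcome approximation ignores the
  liability-scale attenuation of log-odds effects.
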