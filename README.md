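# twostepmr

Bidirectional two-sample Mendelian randomization (MR) with a five-estimator
suite, heterogeneity/pleiotropy diagnostics, and two-step mediation analysis
— for epidemiologists who work from GWAS summary statistics and want the
whole workflow (instrument selection, harmonization, estimation,
sensitivity analysis, mediation arithmetic) as tested, scriptable R
functions rather than a point-and-click pipeline.

## What it computes

Given per-variant summary associations for an exposure and an outcome, the
per-variant Wald ratio is `r_j = beta_out_j / beta_exp_j` with first-order
SE `se_out_j / |beta_exp_j|` and weight `w_j` equal to its inverse
variance. The package implements:

* **Instrument selection** — p-value thresholding (default `5e-8`; presets
  `5e-7` and `5e-6` for sparse exposures and reverse analyses), greedy LD
  clumping (`r² ≤ 0.001` within 10,000 kb, LD supplied as data), and the
  F-statistic filter `beta²/se² ≥ 10`.
* **Harmonization** — alignment of outcome associations onto the
  exposure's effect-allele frame, including strand complements and
  frequency-based resolution of palindromic (A/T, G/C) variants, with a
  per-variant action report.
* **Five estimators** — inverse-variance weighted
  (`Σ w_j r_j / Σ w_j`, fixed/multiplicative-random effects with the
  conventional switch to random when Cochran's Q has p < 0.05), MR-Egger
  (weighted regression with free intercept, t inference on L−2 df),
  weighted median (interpolated weight-standardized 50th percentile),
  and simple/weighted mode (kernel-density argmax), with seeded bootstrap
  SEs and odds-ratio-per-SD reporting.
* **Diagnostics** — Cochran's Q, Egger intercept test, leave-one-out with
  influence flags, and MR-PRESSO (simulation-based global RSS test,
  Bonferroni outlier test, distortion test).
* **Two-step mediation** — total effect `beta0`, exposure→mediator
  `beta1`, mediator→outcome `beta2`, indirect effect `beta1*beta2` with
  first-order delta-method SE `sqrt(beta1²se2² + beta2²se1²)`, and the
  mediated proportion `100·beta1·beta2/beta0` % with its CI obtained by
  dividing the indirect-effect CI bounds by `beta0`.
* **A synthetic-GWAS generator** — an exposure→mediator→outcome causal
  chain with known truth (configurable instrument strengths, pleiotropy,
  sample sizes, palindromic variants, block LD), used as ground truth by
  the entire test suite.

The methods vignette
(`vignettes/two-step-mendelian-randomization.Rmd`) documents the models,
parameter defaults, numerical choices and limitations.

## Worked example

The numbered scripts under `analysis/` run a full study on simulated
cohorts: `01` simulates the chain and block LD, `02` selects and
harmonizes instruments, `03` runs bidirectional MR, `04` the sensitivity
analyses, `05` the two-step mediation. Running them in order from the
repository root (`Rscript analysis/01_simulate_cohorts.R`, ...) writes
tables under `results/` and prints, with the shipped seeds:

```
simulated 300 variants per trait into results/sim
generative truth: theta_total = 0.300, mediated proportion = 66.7%
retained 31 instruments (median F = 228, min F = 42)
forward direction: supported (IVW p = 2.96e-158)
reverse direction: not supported (IVW p = 0.295)
           method n_snp  beta     se      pval   or
1             ivw    31 0.309 0.0115 2.96e-158 1.36
2           egger    31 0.299 0.0326  4.49e-10 1.35
3 weighted_median    31 0.304 0.0163  1.22e-77 1.35
4     simple_mode    31 0.304 0.0289  9.34e-26 1.35
5   weighted_mode    31 0.299 0.0261  2.27e-30 1.35
Q = 31.86 (df 30, p = 0.374); Egger intercept = 0.0009 (p = 0.745); PRESSO global p = 0.496
planted outlier rs80: detected = TRUE (distortion p = 0.000); beta 0.336 -> 0.312 after removal
simulated chain: beta0 = 0.309, beta1 = 0.405, beta2 = 0.502
indirect effect 0.203 (0.190,0.216); mediated proportion 65.62% (61.42,69.83) (truth 66.7%)
reference table: 9 rows recomputed; proportions match published values: TRUE
```

Reading: all five estimators agree on the forward causal effect (truth
0.3) while the reverse direction, instrumented by the outcome's own loci,
is correctly null; the planted pleiotropic outlier is recovered by
MR-PRESSO; and the estimated mediated proportion brackets the generative
two-thirds.

The same machinery reproduces published mediation arithmetic from a
coefficient table alone:

```r
library(twostepmr)
mediation_table(reference_mediation_table())[, c("exposure", "mediator",
  "indirect", "indirect_ci", "proportion_pct", "proportion_ci_pct")]
```

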