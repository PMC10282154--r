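---
title: "Methods: two-sample MR, pleiotropy diagnostics and network mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, pleiotropy diagnostics and network mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The causal model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables: a variant $j$ with effect $\gamma_j$ on an exposure $X$ and no
other path to the outcome $Y$ identifies the causal effect $\theta$ of $X$ on
$Y$ through the ratio of its associations,
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. The two association estimates
come from *different* GWAS samples, so their errors are independent. Validity
rests on the usual three assumptions: relevance ($\gamma_j \ne 0$, monitored
here through per-variant $F = (\hat\beta_X/\sigma_X)^2$ and the mean-$F < 10$
flag), independence from confounders, and exclusion restriction (no
horizontal pleiotropy — the assumption the whole diagnostic battery probes).

All binary-trait effects are on the log-odds scale; estimates against binary
outcomes exponentiate to odds ratios.

## Estimators

**IVW (multiplicative random effects).** The weighted mean of Wald ratios
with first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$. Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ measures heterogeneity;
$I^2 = \max(0, (Q-df)/Q) \times 100$ expresses it as a percentage. The
fixed-effect standard error $(\sum w_j)^{-1/2}$ is inflated by
$\sqrt{\max(1, Q/(J-1))}$: the interval widens when variant-specific
estimates disagree more than chance, and is never shrunk below the
fixed-effect width. We chose the multiplicative (rather than additive)
random-effects form because it leaves the point estimate unchanged and is
the form commonly paired with summary-data MR. First-order weights are used
throughout; the modified second-order weights would change results little at
the instrument strengths this package targets, and a single weighting
convention keeps the estimators mutually comparable.

**MR-Egger.** Weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
*with* an intercept, after orienting every variant so $\hat\beta_{Xj} \ge 0$
(orientation is arbitrary, and the intercept is only interpretable under a
common orientation). Under the InSIDE assumption the slope is the causal
effect and the intercept the average directional pleiotropy; an intercept
p-value below 0.05 is the trigger for outlier removal (below). Standard
errors use the same multiplicative inflation with $J-2$ degrees of freedom
and $t$ reference distributions.

**Weighted median.** Order the ratios, form cumulative midpoint weights
$p_j = (\sum_{k \le j} w'_k - w'_j/2)/\sum_k w'_k$ with first-order inverse
variances $w'_j$, and interpolate at $p = 0.5$. Consistent while valid
instruments carry at least half the weight. Its SE has no convenient closed
form, so it comes from a seeded parametric bootstrap (default 1000
replicates) that redraws $\hat\beta_X$ and $\hat\beta_Y$ from their
estimated sampling distributions.

**Mode-based.** The maximiser of the inverse-variance-weighted normal-kernel
density of the ratios, with bandwidth
$0.9\,\phi \min(\mathrm{sd}, 1.4826\,\mathrm{mad})\,J^{-1/5}$ ($\phi = 1$ by
default) evaluated on a dense 2000-point grid spanning the ratio range
extended by three bandwidths; ties resolve to the smallest grid value, and a
degenerate zero bandwidth (all ratios identical) returns the common value.
Consistent when the largest homogeneous cluster of instruments is valid.

**Multivariable MR.** Weighted regression of $\hat\beta_Y$ on the genetic
associations with two exposures jointly, no intercept — exactly the
two-regressor case the mediation design needs (the general $K$-exposure case
is out of scope). The design table is built from the union of both
instrument sets, re-pruned for mutual independence before fitting; a
rank-deficient design is a hard error rather than a silently unstable fit.

## Pleiotropy diagnostics and the removal protocol

*Leave-one-out* refits IVW $J$ times; the result is flagged when the full fit
is significant but some single-variant removal is not, i.e. the finding
hinges on one variant.

*MR-PRESSO* simulates the no-pleiotropy null: observed residuals are taken
about leave-one-out IVW predictions, and `n_sim` Monte-Carlo replicates of
the whole summary dataset give the null distribution of the residual sum of
squares (global test) and of each squared residual (outlier test, Bonferroni
corrected across the $J$ variants). Empirical p-values use the
$(1+k)/(n_{\mathrm{sim}}+1)$ convention, so they are never exactly zero —
which also means the smallest achievable Bonferroni-corrected p-value is
$J/(n_{\mathrm{sim}}+1)$: with the default `n_sim = 1000`, outlier detection
has adequate resolution up to roughly $J \approx 50$, and `n_sim` should be
raised for larger instrument sets. The distortion test compares the
raw-versus-corrected IVW difference against 1000 removals of random subsets
of the same size.

Outlier removal is deliberately *gated*: variants are removed and IVW and
leave-one-out rerun only when the Egger intercept test signals directional
pleiotropy (p < 0.05). Running removal unconditionally would reintroduce the
selection-on-noise the gate exists to prevent.

## Mediation

For an exposure–mediator–outcome triplet the three steps are: total effect
(TE) of exposure on outcome by IVW; effect $a$ of exposure on mediator by
IVW on the same instruments; and effect $b$ of the mediator on the outcome
*adjusted for the exposure*, the mediator coefficient of the multivariable
fit. Mediation is reported only when all three are nominally significant
(p < 0.05) — a gatekeeping choice that mirrors stepwise mediation practice;
the per-step p-values are always returned so a user can apply a different
rule.

The indirect effect is the product $\mathrm{NIE} = ab$ with first-order
Delta variance $a^2\sigma_b^2 + b^2\sigma_a^2$, and the proportion mediated
is $\mathrm{NIE}/\mathrm{TE}$ on the log-odds scale with ratio-Delta
variance $\sigma^2_{\mathrm{NIE}}/\mathrm{TE}^2 +
\mathrm{NIE}^2\sigma^2_{\mathrm{TE}}/\mathrm{TE}^4$, reported as a
percentage. Both variances assume independence between the component
estimates. That is exact for $a$ (different outcome GWAS) but ignores the
covariance between TE and $b$, which share the outcome sample; the
simulation suite shows the resulting interval is mildly conservative at the
default settings (empirical coverage of the true proportion ~95–98% at
nominal 95%). The log-odds scale is used for every product and ratio —
proportions computed on the OR-minus-one scale do not reproduce the bundled
worked examples, the log scale does (`mediation_worked_examples()`).

## Multiple testing and evidence grading

Exposures come in related subtypes (e.g. many bread or drinking variables);
the Bonferroni threshold $0.05/n$ is applied within each subtype. Grading
combines three criteria — (1) Bonferroni-level IVW significance, (2)
post-removal sign consistency with retained nominal significance, (3) sign
agreement of all sensitivity estimators with IVW — into
reliable / insufficient / weak / none, with a one-level demotion when the
leave-one-out flag is raised. The mapping of criteria to levels is an
explicit reconstruction (the rubric's source describes the levels
discursively), kept as a pure function (`grade_from_criteria()`) so the
table itself is testable and overridable. Two readings are configurable:
criterion 2 may additionally demand nominal significance of every
sensitivity method (off by default — the mode and Egger estimators have low
precision and would dominate the grade), and "direction" is sign agreement
rather than CI overlap.

## Harmonization choices

Variants are matched by identifier only; positions are carried for clumping.
Alleles are upper-cased; strand flips are resolved by complementing;
palindromic (A/T, C/G) variants are oriented by allele frequency when both
studies report a frequency outside $[0.42, 0.58]$ (window configurable via
`palindromic_eaf_window`) and otherwise dropped as ambiguous. Frequency
orientation versus outright dropping is genuinely undecidable from the
study designs this mirrors; the window parameter exposes both policies
(a window of 0.5 drops all palindromic variants).

## The simulator: what it emulates and what it does not

`simulate_two_sample()` draws minor-allele frequencies uniform on
(0.05, 0.5), per-variant exposure effects half-normal
$|N(0, \texttt{gamma\_sd}^2)|$ — variants oriented to their
exposure-increasing allele, the convention under which directional
pleiotropy has a direction — and observed betas around the truth with the
standard $1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ GWAS standard errors.
Pleiotropic direct effects $\alpha_j \sim N(\mu, \sigma^2)$ hit a random
subset of instruments ($\mu = 0$ balanced, $\mu \ne 0$ directional);
LD panels are block-diagonal AR(1) in $r$. Defaults emulate the consortium
scale of the studies this design mirrors: exposure GWAS $n = 450{,}000$
(biobank dietary trait), outcome $n = 260{,}000$ (disease cohort), mediator
$n = 1{,}330{,}000$ (large insomnia-type meta-analysis), 100 variants,
`gamma_sd = 0.03` (mean $F \approx 200$ at the exposure default — strong
instruments, as selected genome-wide-significant variants are).

The mediation triplet doubles the panel: $J$ exposure instruments plus $J$
mediator-specific instruments (half-normal effects $\delta_j$), because the
multivariable step is only identified when the mediator has genetic
associations not fully explained by the exposure. All three studies draw
independent noise (no sample overlap).

Deliberately *not* emulated: genotype-level data, realistic allele-frequency
spectra, winner's-curse from in-sample instrument selection, sample overlap
between exposure and outcome GWAS, population stratification, and
case-control imbalance beyond an effective-$n$. Passing the simulation suite
therefore demonstrates correctness of the estimators and protocol under the
stated model, not robustness to these additional real-data pathologies.

## Validation problem sizes

The test suite validates operating characteristics at: 500 replicates of
$J = 100$ instruments with a $n = 100{,}000$ outcome GWAS for IVW coverage
(93–97% required) and bias ($< 0.005$ log-odds); 1000 balanced-pleiotropy
replicates for the Egger intercept's type-I error (3–7%); 200 replicates
with 30% directional-pleiotropy instruments for the weighted-median
robustness comparison; 40 seeded runs for MR-PRESSO's recovery of a planted
10-SE outlier (with `n_sim = 1000`, see the resolution note above); and 100
mediation triplets ($a = 0.3$, $b = 0.5$, direct effect 0.1, true
proportion 60%) for Delta-interval coverage. These sizes give Monte-Carlo
standard errors comfortably below the acceptance bands while keeping the
default test run in tens of seconds.

## Known limitations

- First-order weights and SEs everywhere; no second-order or
  heteroscedasticity-robust options.
- The Delta interval for the proportion mediated ignores TE–$b$ covariance
  (shared outcome sample); a bootstrap alternative would capture it at
  substantial cost.
- No Steiger filtering or other directionality tests; bidirectional
  causation is probed only by swapping instrument roles, which requires the
  reverse trait to have its own instruments.
- MVMR is limited to two regressors, matching the mediation design.
- No correlated-instrument IVW: clumping is expected to have removed LD.
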