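---
title: "Methods: drug-target cis-MR from correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target cis-MR from correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The causal model

cis-MR treats variants inside a drug target's gene as instruments for
pharmacological perturbation of that target, weighted by a surrogate
biomarker. For variant $j$, let $\gamma_j$ (SE $\sigma_{\gamma j}$) be its
association with the biomarker and $\Gamma_j$ (SE $\sigma_{\Gamma j}$) its
association with an outcome, estimated in two separate samples. Under the
instrumental-variable assumptions (association with the biomarker, no
association with confounders, no effect on the outcome except through the
target) each variant identifies the causal effect through the Wald ratio
$\hat\theta_j = \Gamma_j / \gamma_j$ with first-order standard error
$\sigma_{\Gamma j} / |\gamma_j|$. The first-order form ignores the
uncertainty in $\gamma_j$ (the "NOME" approximation); it is accurate when
instruments are strong, which is why per-variant F statistics are part of
the standard diagnostics and why a weakest-instrument exclusion sensitivity
analysis is built into the pipeline.

Cis variants are correlated, so the per-variant ratios cannot be combined
with independent weights. `mr_ivw()` uses the generalised least squares
formulation on the association scale: with
$\Omega = D_{\sigma_\Gamma}\,\rho\,D_{\sigma_\Gamma}$, where $\rho$ is the
signed LD correlation matrix aligned to the harmonised effect alleles,

$$\hat\theta = (\gamma^\top \Omega^{-1} \gamma)^{-1}
               \gamma^\top \Omega^{-1} \Gamma, \qquad
  \mathrm{var}_0(\hat\theta) = (\gamma^\top \Omega^{-1} \gamma)^{-1}.$$

This is the standard summary-data form equivalent, to first order, to
meta-analysing the Wald ratios under their LD-induced correlation; the
package adopts GLS because it is exact under the generative model the
simulator implements and reduces algebraically to the textbook
inverse-variance weighted mean (weights $\gamma_j^2/\sigma_{\Gamma j}^2$)
when $\rho = I$ — an identity the test suite checks against a brute-force
oracle to $10^{-10}$.

Residual heterogeneity between variants (e.g. from mild pleiotropy) is
absorbed by a multiplicative random-effects model: the overdispersion
$\hat\phi = (\Gamma - \hat\theta\gamma)^\top \Omega^{-1}
(\Gamma - \hat\theta\gamma) / (J-1)$ multiplies the variance when
$\hat\phi > 1$. Multiplicative random effects can only inflate, never
shrink, the fixed-effect SE, so the reported SE is
$\mathrm{se}_0 \cdot \max(1, \sqrt{\hat\phi})$; the raw $\hat\phi$ is kept
unfloored in the result for diagnostics. With a single variant $\phi$ is
undefined and reported as `NA`. Confidence intervals and p values use the
normal reference distribution, matching the convention of summary-data MR
software; with the J ≤ 5 instruments typical of a cis analysis a
t-reference would be ill-defined anyway because the weights are estimated.

Binary outcomes from linear mixed-model GWAS are analysed on the linear
probability scale (the scale of the underlying association estimates) and
results read as additive changes in probability.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| eQTL p threshold | 5e-8, strict `<` | genome-wide significance for cis instrument candidacy |
| pruning r² | 0.35 | keeps mildly correlated variants for power while avoiding the numerical instability of near-collinear $\Omega$ |
| pruning window | 10 000 kb | pairwise distance beyond which correlated variants are not pruned |
| palindrome EAF window | 0.08 | A/T and C/G variants with exposure EAF in 0.5 ± window are strand-ambiguous and dropped |
| dose scale | 5.5 mm Hg, lowering | expresses estimates per dose-equivalent biomarker change (the approximate diastolic effect of 100 mg sildenafil); "lowering" negates the per-unit-higher estimate so inhibition effects read positively |
| coloc priors | p1 = p2 = 1e-4, p12 = 1e-5 | canonical single-variant colocalisation priors |
| coloc prior SD | 0.15 quantitative, 0.2 binary | Wakefield prior effect scale per trait |
| condition floor | 1e-8 × largest eigenvalue | relative cutoff for spectral pseudo-inversion of $\Omega$ |

The FDR family is defined by configuration: all outcomes analysed in one
`run_pipeline()` invocation are corrected together by Benjamini–Hochberg.

## Harmonisation rules

Two-sample MR requires the outcome association to be expressed per copy of
the exposure's effect allele. `harmonise()` intersects the variant lists,
flips the outcome beta and complements its frequency when alleles are
swapped, retries after strand complementation when they match neither way,
and resolves palindromic variants by frequency concordance — excluding them
as "ambiguous palindrome" when the exposure EAF lies within ±0.08 of 0.5.
The window is a design choice of this package (upstream publications are
typically silent on palindrome handling); it follows common two-sample MR
practice. Variant identity is keyed by rsid, since the data sources this
workflow consumes are rsid-keyed, and coordinates are 1-based GRCh37 with
closed intervals. Every input variant ends in either the harmonised set or
the exclusion log with a reason, and harmonisation is idempotent — both
properties are asserted in the tests.

## Instrument strength: two F statistics

Published instrument tables typically derive F from the variance explained,
$F = R^2 (n-2)/(1 - R^2)$ with $R^2 = 2f(1-f)\beta^2/\mathrm{SD}^2$; the
squared z statistic $(\beta/\mathrm{SE})^2$ is the other common definition.
The two differ under trait-SD rounding and covariate adjustment, so
`instrument_diagnostics()` reports both, labelling `f_r2` as the
table-compatible one. `instrument_summary()` reports both the arithmetic
and the geometric mean of the per-variant F values: with heterogeneous
instrument strength the two differ substantially, and summaries quoted in
the literature are sometimes closer to the geometric mean, so neither is
privileged.

Note that recomputing $R^2$ from a table's *rounded* $\beta$, EAF and trait
SD reproduces the printed per-variant $R^2$ only to roughly the precision
the rounding supports; the F statistics computed from the printed $R^2$
values themselves are exact.

## Colocalisation

`coloc_abf()` implements enumeration colocalisation under one causal
variant per trait. Per-variant evidence is the Wakefield approximate Bayes
factor $\log\mathrm{ABF} = \tfrac12\log(1-r) + r z^2/2$ with
$r = W/(V+W)$, and the five hypothesis evidences are assembled by
log-sum-exp over single-variant configurations — no raw-probability
products, so 100-variant regions with $z = 10$ signals remain numerically
exact and the posteriors sum to one within $10^{-9}$. The qualitative call
(`coloc_label()`) uses the conventional 0.8 threshold: pp4 supports a
shared causal variant, pp3 supports distinct variants (confounding by LD),
and otherwise the analysis is labelled likely underpowered. No
multi-causal (conditioning/masking or SuSiE-style) extension is provided.

## Two-step adjustment

`adjusted_mr()` subtracts, per variant and mediator, the transmitted
component $b_{GC,j}\,b_{CO}$ from $\Gamma_j$. The adjusted SE uses the
exact variance of a product of independent normals,
$\sqrt{\sigma_\Gamma^2 + b_{GC}^2\sigma_{CO}^2 + b_{CO}^2\sigma_{GC}^2 +
\sigma_{GC}^2\sigma_{CO}^2}$, rather than the first-order delta form: the
extra term costs nothing and the formula is then testable against a
Monte-Carlo oracle (the suite checks agreement within 1% over $10^6$
draws). Errors in the two steps are treated as independent; cross-step
covariances are out of scope. Mediator discovery is not performed live —
the mediator table is a file/argument input, so a body-mass-index
collider check is expressed as an ordinary mediator path rather than
special-cased. Because adjustment is additive in the point estimate and
additive in variance, independent mediator corrections commute; the SE
inflation does perturb the GLS weights, so the *combined* estimate after a
null-effect mediator adjustment is exactly invariant only when the
inflation is homogeneous across variants.

## The synthetic-data generator

`simulate_summary_stats()` emulates the two-sample structure the estimator
assumes: per-variant sampling SEs fixed at
$\mathrm{SD}/\sqrt{2 n f(1-f)}$, effect estimates drawn jointly from a
multivariate normal with covariance $D\,\rho\,D$ within traits and
$\mathrm{overlap}_\rho \cdot D_\gamma \rho D_\Gamma$ across traits when
participant overlap is configured, and p values from the normal z. The
default configuration reproduces the study setting this package is built
around: five instruments with $\gamma \approx 0.10$–$0.16$ and the
published allele frequencies, exposure SD 10.7 mm Hg at $n = 757\,601$,
outcome $n = 211\,840$ with SD 1.1 (a realistic SD for a children-count
phenotype — the generator needs an outcome SD although only the exposure SD
is published, and 1.1 places simulated outcome SEs at the magnitude implied
by the published confidence intervals), AR(1) LD with neighbour correlation
0.5 (below the 0.35 r² pruning ceiling), and no pleiotropy or overlap.
Under these defaults simulated exposure SEs land in the published
0.017–0.05 range — asserted in the tests.

What the generator does *not* emulate: individual-level genotypes, liability
-scale binary traits, winner's-curse selection of instruments, population
stratification, and LD estimated with error from a finite reference panel.
Passing recovery/coverage tests therefore show the estimator is correct
under its own assumptions at realistic scales, not that real-data biases
from those unmodelled features are absent.

Determinism: every draw is keyed by `seed` plus a replicate index folded in
as `seed + 7919 (replicate − 1)` (a prime stride keeps replicate streams
distinct for any seed); the generator restores the caller's RNG state.

## Numerical and procedural choices

- **$\Omega$ conditioning.** Eigenvalues below $10^{-8}$ of the largest are
  excluded from a spectral pseudo-inverse with a warning; a matrix with no
  usable eigenvalue is an error naming the smallest eigenvalue. At the
  r² < 0.35 pruning ceiling $\Omega$ is well-conditioned; the guard exists
  for user-supplied degenerate LD (e.g. duplicated variants, where the
  pseudo-inverse collapses to the single-variant estimate — tested).
- **Pruning tie-breaks.** P-value ties are ordered by distance to the
  midpoint of the candidates' position range, then by rsid, making the
  greedy selection a deterministic function of the ranking alone (the
  operation takes no region argument, so the candidates' own span stands in
  for the region midpoint).
- **Region bounds** are inclusive; the eQTL threshold is a strict `<`, so a
  p value exactly at 5e-8 is excluded.
- **Weakest-instrument ties** are broken by the larger exposure p value,
  then rsid.
- **Scaling** multiplies estimate, SE and CI by the dose factor (negated
  for "lowering") and refuses to scale twice; z scores and p values are
  invariant.
- **Degenerate inputs.** Empty eQTL filter results are legal and logged;
  an empty harmonisation intersection, a zero exposure beta in the Wald
  ratio, and out-of-domain probabilities are hard errors.

## Validation problem sizes

The acceptance-grade checks in `tests/testthat/test-acceptance.R` use 1000
replicates at the full published sample sizes for bias and coverage
(coverage is required to land in [0.92, 0.975]), 400 replicates for the
planted-pleiotropy bias-reduction check, $10^6$ draws for the
product-variance oracle, 100-variant regions for colocalisation scenarios,
and exhaustive permutations of up to six p values for the FDR check. These
sizes keep the whole suite under a couple of minutes on one CPU while
leaving Monte-Carlo error well below the tolerances being asserted.

## Known limitations

- First-order Wald SEs understate uncertainty for weak instruments; the
  weakest-exclusion sensitivity analysis mitigates but does not remove
  weak-instrument bias, which is also visible (well within Monte-Carlo
  tolerance) in the recovery simulations.
- Sample overlap between exposure and outcome GWAS biases two-sample MR
  when instruments are weak; the generator can emulate overlap, but the
  estimator applies no correction.
- LD matrices are consumed as given (no genotype handling, no liftover);
  reference-panel mismatch with the GWAS sample is not modelled.
- The colocalisation module assumes a single causal variant per trait and
  is not intended to reproduce posterior estimates that depend on full
  regional summary statistics unavailable here.
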