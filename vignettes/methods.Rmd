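---
title: "Methods: two-sample summary-data Mendelian randomization in mrtwosample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample summary-data Mendelian randomization in mrtwosample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwosample)
```

## The inferential setting

Mendelian randomization uses genetic variants as instrumental variables
for a modifiable exposure: if a SNP (i) is associated with the exposure,
(ii) shares no confounder with the outcome, and (iii) affects the outcome
only through the exposure, then the ratio of its outcome association to
its exposure association estimates the causal effect. In the two-sample
summary-data regime the two associations come from non-overlapping GWAS
samples, each reduced to per-SNP (beta, SE) pairs. This package implements
that regime for a small panel of independent (not in linkage
disequilibrium) instruments — the design used for serum mineral exposures
(6 magnesium and 7 calcium SNPs, explaining roughly 1.6% and 0.9% of
variance) against ischemic stroke case-control summary statistics — but
nothing in the code is specific to those traits.

Assumption (iii) is the fragile one: pleiotropy. The package therefore
pairs the efficient-but-fragile IVW estimator with estimators whose
validity degrades more gracefully (weighted median: 50% of weight valid;
MR-Egger: InSIDE; HetPen: plurality validity) and with diagnostics
(Cochran's Q, the Egger intercept, I²GX, MR-PRESSO). Agreement across this
battery, not any single p-value, is the intended inferential output.

## Harmonization

Exposure and outcome records are aligned per rsid on a common effect
allele: swapped alleles negate the outcome beta and complement its
frequency; alleles matching only after A↔T/C↔G complement are treated as a
strand flip; anything irreconcilable is dropped. Palindromic SNPs (A/T,
C/G) cannot be resolved from alleles alone, so a policy applies:
`freq-infer` (default) orients by effect-allele frequency and drops SNPs
whose frequency falls in the ambiguous window (0.42, 0.58) or is missing;
`drop` removes them; `keep` trusts the face-value alleles. The default and
window follow standard two-sample practice; consortium tables that were
aligned upstream pass through untouched, and every decision is logged
per-SNP in a provenance table so any convention can be audited — the
source studies do not state how their alignment was done.

Causal estimates are per one unit of the exposure betas;
`rescale_exposure(set, unit)` divides exposure betas/SEs by `unit` so
downstream estimates are per `unit` (e.g. 0.1 mmol/L ≈ 1 SD for serum
magnesium, 0.5 mg/dL ≈ 1 SD for calcium), recording the cumulative factor.

## Estimators and numerical choices

**Ratio SEs.** First-order SEs (σ_Yj/|β_Xj|) are the default; the
second-order form adds the exposure-beta term β_Yj²σ_Xj²/β_Xj⁴. The source
analyses do not state which they used; first order is the field's common
default and the choice is a flag. The delta expansion, either order, is
only meaningful while |β_Xj|/σ_Xj is large; the ratio distribution has no
finite moments when the exposure beta can cross zero.

**IVW.** `model = "auto"` uses fixed effects below 4 instruments and
multiplicative random effects (SE inflation max(1, √(Q/(J−1)))) otherwise,
matching mainstream summary-MR practice for 6–7 instrument panels; whether
the original analyses used fixed or random effects is unstated, so both
are available and the tag of the fitted model is reported.

**Weighted median.** The point estimate interpolates the weighted CDF
through the cumulative-weight midpoints p_j = Σ_{i≤j} w'_i − w'_j/2 and
inverts it at 0.5. The SE is a parametric bootstrap (default 1000
resamples, fixed default seed, both exposed) redrawing both betas from
their reported SEs. A stochastic SE is reported reproducibly rather than
replaced by an analytic approximation.

**MR-Egger, I²GX, SIMEX.** Pairs are oriented so every exposure beta is
positive before fitting the intercept (the Wald ratio is invariant to
joint negation). Coefficient SEs carry the multiplicative residual scale
max(1, √(RSS/(J−2))), the same convention as the IVW random-effects model;
p-values are normal-approximation throughout, consistent with the
symmetric log-scale intervals the field prints. I²GX is the
inverse-variance-weighted I² of the (positively oriented) exposure betas;
below 0.9 the Egger slope is substantially diluted and SIMEX applies:
noise of variance λσ_Xj² is added over λ ∈ {0, 0.5, 1, 1.5, 2} (1000
replicates per λ by default), mean slopes are fitted by a quadratic in λ
and extrapolated to λ = −1. The SE extrapolates the jackknife variance
component (mean within-replicate model variance minus between-replicate
variance) and falls back to the naive Egger variance if the extrapolated
variance is nonpositive. Quadratic extrapolant, this λ grid, and the
jackknife are the standard SIMEX defaults; the source gives none.

**MR-PRESSO.** Residuals are taken against leave-one-out IVW fits, their
weighted (1/σ_Yj², the default; unweighted available — the original run's
choice is unstated) sum of squares compared with `n_sim` simulated
no-pleiotropy datasets. The add-one p estimator (1+#{RSS* ≥ RSS})/(n+1)
keeps the global p away from exactly zero. Per-SNP ps are Bonferroni
multiplied by J — the source reports flags "at p < 0.10" without naming an
adjustment, so the choice is explicit here — and the distortion test
compares the outlier-removal shift against 1000 random same-size
removals. Fewer than 4 instruments refuses to run: leave-one-out IVW
needs 3 remaining.

**HetPen.** All 2^J − J − 1 subsets with |S| ≥ 2 are enumerated (J > 25
refuses with advice to subsample). Subset weight ∝
p^|S|(1−p)^(J−|S|)·exp(−Q_S/2) with prior validity p = 0.5 by default
(making the prior term constant, an uninformative choice; exposed as a
flag). The criterion Σ_S W_S·N(θ; θ_S, se_S²) is evaluated on a 2001-point
grid spanning min(θ_S) − 6·max(se_S) to max(θ_S) + 6·max(se_S); the 95%
confidence set cuts the log-criterion at χ²₁(0.95) = 3.84. The cited
method's exact penalty constant and interval rule are not restated in the
source, so this likelihood-ratio-style construction is this package's
documented choice, not a claimed equivalence. Disjoint interval unions are
reported as-is with a `multimodal` flag, never bridged: a bridged interval
would hide exactly the valid-vs-invalid ambiguity the method exists to
expose. Weight ties (exact under p = 0.5 with zero heterogeneity) resolve
toward the largest subset.

**Power and multiplicity.** Power uses the binary-outcome noncentrality
NCP = N·R²_GX·K(1−K)·(ln OR)², two-sided at α = 0.05 by default. The α
underlying the published "100% power" statement is unstated; with the
published N and R² the integer-rounded result is insensitive to 0.05
versus 0.006. The exact formula variant in the cited calculator is also
not restated; this approximation reproduces the magnesium claim robustly,
while for the calcium panel different variants give ~96–100%, so that
figure is not asserted as a test. Bonferroni thresholds are exact α/m with
a 2-significant-figure display value.

## The synthetic-data generator

`simulate_study()` generates summary statistics directly (no
individual-level genotypes — the estimators never see those anyway).
Genotypes are standardized, so SNP j's true effect is b_j = √(r²_j) with
the r²_j a seeded Dirichlet split of the total variance explained —
heterogeneous instrument strength like real panels. Defaults mirror the
magnesium design: J = 6, R² = 1.6%, exposure n = 23,829, outcome 34,217
cases / 404,630 noncases. SEs follow the standardized-genotype forms
σ_X = n_exp^(−1/2) and σ_Y = (n_case·n_ctrl/n)^(−1/2); pleiotropy is
`none`, `balanced` (N(0, τ²)) or `directional` (N(μ, τ²)), drawn
independently of instrument strength so InSIDE holds; planted outliers add
an offset in σ_Y units. Everything is bit-reproducible given the seed.

What it does *not* emulate: linkage disequilibrium, sample overlap,
population stratification, winner's-curse selection of instruments, or
allele-frequency-dependent precision. A green test on this generator
establishes that the estimators do what their theory claims under their
own assumptions — it does not validate any real-data finding.

## Design decisions that were genuinely open

- The reproduction of the published per-SNP results requires the source
  study's supplementary tables, not redistributable here; the acceptance test
  for it stays red offline rather than being skipped, and the packaged
  13-SNP panel file is explicitly synthetic.
- Two stated test invariants are unattainable as written for any correct
  implementation and were re-anchored to the nearest meaningful criterion:
  mode stability under instrument duplication is bounded by a tenth of the
  pooled SE (not one grid step — duplication genuinely re-weights the
  subset space), and weighted-median robustness is judged on the mean over
  replicates (its per-replicate standardized bias at 30% invalid weight is
  ~1.4 independent of the noise scale).
- `exec/mrtwosample` exposes `estimate` / `simulate` / `power`
  subcommands; repeated `--outcome` flags are collapsed into one
  comma-separated `path:LABEL` argument because optparse keeps only the
  last repeated flag.

## Known limitations

No LD-aware modelling, no multivariable MR, no Steiger direction test, no
mode-based estimator beyond HetPen, and no genome-build liftover — inputs
are assumed to be on a common build with unique rsids. HetPen is
exhaustive and so limited to ~25 instruments. SIMEX inherits the usual
extrapolation caveat: it reduces, not removes, dilution bias, and is
unreliable when exposure betas are so noisy they change sign.
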