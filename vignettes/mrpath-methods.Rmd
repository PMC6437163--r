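---
title: "Methods: summary-statistic MR, mediation and genetic-score IV analysis in mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic MR, mediation and genetic-score IV analysis in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The causal model and its assumptions

`mrpath` estimates the causal effect of a quantitative exposure (its unit
is one standard deviation) on a binary disease outcome (effects on the
log odds-ratio scale), using genetic variants as instruments. A valid
instrument satisfies three conditions: it is robustly associated with the
exposure (relevance, screened by the F statistic
`(β̂_X/σ_X)²`), it shares no common cause with the outcome
(independence), and it affects the outcome only through the exposure (no
horizontal pleiotropy). The estimator battery exists because the third
condition is untestable variant by variant; each method trades power for
robustness to a different pleiotropy regime, and agreement across them is
the practical argument for causality.

In the two-sample design the variant–exposure and variant–outcome
associations come from disjoint GWAS samples, so their sampling errors
are independent; the generators enforce this, and the estimators assume
it.

# Harmonisation

All effects are aligned to the exposure-increasing allele. Swapped
allele labels flip the outcome beta and complement the EAF; complement
(strand) codings of non-palindromic variants are resolved exactly.
Strand-ambiguous (A/T, C/G) variants cannot be resolved from the labels:
the default policy infers orientation from allele frequencies and drops
variants whose EAF falls in [0.42, 0.58] on either side (or is missing);
a strict `drop` policy is also provided. No published convention exists
for the motivating analysis, so neither policy claims to match it — the
ambiguity window is the conventional one used by harmonisation tools.
After allele alignment, every variant with a negative exposure effect is
re-oriented (all betas negated) so `β̂_X ≥ 0`; MR-Egger requires this
orientation and refuses input violating it.

LD pruning is greedy by ascending p-value: a variant is kept iff its r²
with every already-kept variant is ≤ 0.05 (the default threshold used
for the 828-variant height instrument set). Ties in p are broken by
larger `|β|/se`, then lexicographic id, making the output deterministic;
variant pairs absent from a pairwise LD list are treated as independent,
which is the correct prior for a pre-pruned instrument panel.

# Estimators

*Wald ratio.* `θ̂_j = β̂_Y/β̂_X`; first-order SE `σ_Y/|β̂_X|` (NOME:
exposure effects treated as known), second-order SE adds the
exposure-noise term `β̂_Y²σ_X²/β̂_X⁴`.

*IVW.* Inverse-variance pooling of the ratios; identical to fixed-effect
meta-analysis and to origin-constrained WLS (asserted to 1e-10 in the
tests, with `metafor::rma(method = "FE")` as an independent oracle).
Random effects use a multiplicative scale `max(1, √(Q/(J−1)))` — the
floor encodes that heterogeneity cannot make the pooled estimate more
precise; an additive DerSimonian–Laird variant is deliberately not
implemented. The "second-order" mode re-weights by the second-order Wald
SEs: the published description of an IVW "corrected for the standard
errors of each instrument" is ambiguous between this and a bivariate
correlation correction, and we implement the Taylor-weight reading and
flag it here.

*MR-Egger.* Weighted regression with free intercept; weights `1/σ_Y²`
(first order) or second-order ratio weights. Inference uses a
t-reference with J−2 df and a residual scale floored at 1 — the source
analyses do not state their reference distribution; with hundreds of
instruments the choice is immaterial, at small J the t is the safe one.
`I²_GX = max(0, (Q_GX − (J−1))/Q_GX)` quantifies regression dilution; in
the consortium-scale regime the simulated value is ≈ 0.99, matching the
regime where dilution is negligible.

*Weighted median.* Ratios ordered, cumulative-weight midpoints
interpolated at 0.5. The SE is the SD over a seeded parametric
bootstrap, implemented in compiled code.

*Mode-based estimate.* Weighted normal-kernel density of the ratios with
bandwidth `φ × 0.9 min(sd, mad) J^{-1/5}` (φ defaults to 1, the value
used in the motivating analysis); the mode is located on a 512-point
grid spanning mean ± 5 SD **plus the ratios themselves as candidates**,
then refined by golden-section search (tolerance 1e-8) within one
bandwidth of the best candidate. The candidate augmentation and the
bandwidth-scale refinement bracket are deliberate: ratio outliers from
near-zero exposure effects can inflate the grid span by orders of
magnitude, and a fixed-width bracket around a coarse grid point can miss
a narrow density spike entirely. If the ratio distribution is atomic
(repeated values, MAD = 0) the mode is the heaviest atom.

*Bootstrap centering (median and mode SEs).* The bootstrap redraws
`β̂*_X ~ N(β̂_X, σ_X)` and `β̂*_Y ~ N(θ̂ β̂_X, σ_Y)` — outcome effects
centered on the fitted ratio model, not on the observed outcome effects.
Observation-centered draws would convolve the sampling noise twice,
widening the ratio spread by √2 under homogeneity and inflating the SE
(probe runs showed null rejection collapsing to ~0.015 and CI coverage
near 1). The model-centered bootstrap restores nominal calibration; its
cost is that under strong heterogeneity it conditions on the homogeneous
fit and can understate uncertainty — Cochran's Q and the benchmark grid
are the tools for recognising that regime.

*Correlated instruments.* GLS with `Ω = σ_Y σ_Y' ∘ ρ`; a single ridge
retry (`+1e-8` on the diagonal) is allowed before failing with a
condition-number report. With identity LD this equals fixed-effect IVW
to machine precision.

# Heterogeneity diagnostics and sensitivity filters

Cochran's Q uses first-order weights against a reference estimate (IVW
by default; an Egger reference loses one further df); per-variant
contributions are non-negative and sum to Q. The per-instrument
exclusion levels L1/L2/L3 are the upper-tail χ²₁ quantiles at
5% / 1% / 0.19% — the lower-tail reading would exclude essentially
everything and contradicts excluding variants with *large* Q. The
0.19th level is taken literally as upper-tail mass 0.0019. Contributions
are computed once against the full-set IVW estimate, not iteratively
re-fit — iteration is unspecified in the source and a one-shot rule is
reproducible. The mediator filter excludes a variant when its p-value in
*any* supplied mediator table is strictly below 0.05; supplying all
tables at once yields the composite ("all traits") analysis.

The simplified residual-sum-of-squares pleiotropy test computes
`RSS = Σ w_j (β̂_Yj − θ̂_(−j) β̂_Xj)²` with leave-one-out IVW slopes and
builds its null by redrawing outcome effects from the fitted model,
re-estimating the leave-one-out slopes per draw (required for a uniform
null p, verified by a KS test across clean replicates). The distortion
test of the full published procedure is out of scope.

# Mediation

*Summary statistics.* Multivariable MR regresses outcome effects on
exposure and mediator effects jointly, no intercept (orientation makes
the origin meaningful — the source does not state this; it follows the
IVW convention), weights `1/σ_Y²`, SEs with the same multiplicative
overdispersion floor as univariable random effects. All-zero mediator
columns are dropped (they carry no conditioning information and would
only make the design singular); genuinely collinear columns raise an
error naming the offenders. Attenuation is reported on both the log-OR
and OR scales; the indirect effect is never returned, because the
product decomposition requires a linearity that fails for binary
outcomes.

*Individual level.* The three-stage estimator fits exposure and mediator
each on the **full** instrument set (both genetic scores) and regresses
the outcome on both fitted values. The one-score-per-trait reading of
the published description leaves the mediated path loading on the fitted
exposure — in a full-mediation simulation the direct-effect CI covered
zero only 57% of the time — whereas the two-stage-least-squares reading
(each first stage on all instruments), which the original description
equates itself to, restores nominal coverage. Stage-3 model-based SEs
are the default here: with strong scores the first-stage uncertainty is
second order, and the coverage studies confirm nominal behaviour; a
nonparametric bootstrap is available (`n_boot`). The two-stage IV
estimator defaults to the control-function variant (stage-1 residual
included in stage 2, absorbing shared confounding); the substitution
variant is kept for robustness comparisons, and its SEs default to a
seeded nonparametric bootstrap over samples (200 replicates) because the
plug-in SE ignores first-stage noise.

# Power

For a binary outcome the IVW z statistic has non-centrality parameter
`ncp = N φ(1−φ) R²_GX log(OR)²` under the summary-SE model
`se(log OR) = 1/√(2p(1−p) N φ(1−φ))`; power is the upper-tail
χ²₁(ncp) mass beyond the α critical value, exactly α at OR = 1. The
validation oracle simulates at a *fixed* instrument R² (equal effects,
point MAF): the formula computes power at a given R², and letting
realized R² vary ±25% across replicates shifts mean rejection by
convexity — a property of the oracle design, not of the formula.

# What the generators emulate — and what they do not

The two-sample generator draws true exposure effects half-normal (effects
are reported for the exposure-increasing allele, so re-orienting a
variant flips its pleiotropic effect too — this keeps "directional"
pleiotropy directional after harmonisation), MAFs uniform, and observed
effects with `se = 1/√(2p(1−p)N)`; binary-outcome effects are produced on
the log-OR scale directly rather than via per-variant logistic fits. The
`"height_cad_like"` preset (J = 828, exposure GWAS 700,000, effective
outcome GWAS 160,000, θ = −0.17, instrument R² ≈ 0.30) is a regime
label, not a claim about any dataset. The cohort generator builds
binomial dosages, a standardized exposure with configurable score
heritability and confounding, a mediator on the causal path, and a
Bernoulli outcome whose intercept is solved by bisection to the target
prevalence (tolerance 1e-4).

Not emulated: real LD maps (only block-exchangeable structure),
population stratification, selection and participation bias, sample
overlap between the two GWAS samples, genotype uncertainty beyond a
scalar INFO score, and non-linear or interacting exposure effects.
Passing tests therefore demonstrate correctness of the estimators under
their stated sampling models — not robustness to those real-data
phenomena.

# Study sizes

The test-suite and acceptance studies use: estimator identities on 100
random instances; null calibration with 2,000 replicates at J = 100
(bootstrap SEs from 200 draws); effect recovery with 500 replicates of
the consortium-scale preset; pleiotropy robustness with 500 replicates
(30% invalid instruments, mean direct effect 0.01); mediation coverage
with 500 replicates each for multivariable MR (J = 120) and the
three-stage estimator (cohorts of 4,000); the confounding contrast as
the mean of 16 cohorts of 50,000 (averaging removes the 11% single-run
sampling noise so the comparison measures the estimator's systematic
~4% non-collapsibility attenuation, which the 10% margin is meant to
absorb); and power validation with 2,000 replicates per grid point. The
acceptance script runs the same studies at 300–1,000 replicates. All
stochastic steps derive their streams from a single seed and restore the
caller's RNG state.

# Known limitations

Random-effects heterogeneity handling is multiplicative only; the
median/mode bootstrap conditions on the fitted homogeneous model; the
conditional instrument-strength diagnostic is reported but never gates
an analysis; the correlated-instrument estimator requires a full LD
matrix (no pairwise fallback); and the mediator filter treats mediator
GWAS p-values as exchangeable across traits with no multiplicity
adjustment, mirroring the sequential-exclusion design it reproduces.
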