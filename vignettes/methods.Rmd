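---
title: "Methods: partial-credit Rasch validation of the BBS in MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-credit Rasch validation of the BBS in MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
model and its assumptions, the estimation and diagnostic conventions we
adopted where several were defensible, what the synthetic-data generator
does and does not emulate, and the known limitations. It states no
empirical result that the test suite does not itself compute.

## The measurement model

The Berg Balance Scale is 14 ordinal items scored 0–4 (total 0–56). We model
responses with the partial credit model (PCM): for person ability θ (logits),
item location δ_i and centred thresholds τ_i1…τ_i4 (Στ_ik = 0),

P(X_i = x | θ) ∝ exp( Σ_{k ≤ x} (θ − δ_i − τ_ik) ).

The PCM places no constraints across items' threshold structures, which
matters for the BBS because its response anchors differ between tasks.
Assumptions under test: unidimensionality, monotonicity, local independence,
and invariance across person groups (no DIF) and across the ability range
(the item-trait interaction).

## Estimation

**Items: conditional maximum likelihood.** The raw total is sufficient for
θ, so the likelihood conditional on it is free of person parameters. With
cumulative category parameters β_ik = kδ_i + Σ_{j≤k} τ_ij and
ε_ik = exp(−β_ik), the conditional likelihood involves the elementary
symmetric functions γ_r of the ε's, computed by polynomial convolution.
Newton iterations use the exact gradient (observed minus conditionally
expected category counts) and Hessian (minus the summed conditional
covariances of category indicators, via pairwise ESF exclusions), with
step-halving, a gradient-norm tolerance of 1e−6, and a cap of 200
iterations. The score-shift invariance of the conditional likelihood is
removed by a rank-one regularization of the Hessian plus recentring to
Σδ_i = 0 after each step. Persons with extreme totals carry no conditional
information and drop out identically.

CML is exact for the PCM, deterministic, and well-conditioned for 14 items
and for testlet super-items up to a maximum of 40. It replaces the pairwise
algorithm of the commercial package used in the original analysis;
data-dependent statistics therefore agree in decision logic, not digit for
digit.

**Null and sparse categories.** A category never observed in the
calibration sample cannot be estimated; it is collapsed with a warning and
the mapping is stored with the parameters (`score_map`), so raw totals stay
interpretable and anchored re-analyses can conform new data to the
calibrated space. Data containing categories absent from an anchor's map
are mapped to the nearest calibrated category, with a warning — at n ≈ 288 a
40-category super-item routinely leaves tail categories unobserved.

**Persons.** Given items, person measures solve the ML score equation
Σ_i E[X_i | θ] = r; the SE is the inverse square root of the information.
Extreme totals are shifted inward by 0.3 raw-score points (a widely used
convention the source analysis software also applies) and flagged. For
*short item subsets* — the two halves of the unidimensionality t-test and
the per-testlet estimates behind the subscale indices — we instead use
Warm's weighted likelihood (the score equation plus I′/(2I)): with 2–4
items the outward bias of ML materially miscalibrates the per-person
t-test, while WLE is finite at extreme subset scores and restores the
test's intended conservativeness.

## Fit machinery

**Standardized residuals** are z = (x − E)/√V with E, V evaluated at the
person's estimate. They feed the residual correlation matrix, the residual
PCA, and the DIF ANOVA.

**Fit residuals.** Sums of squared residuals are *not* treated as sums of
unit-mean cells: with complete data the total is fixed, so E[z² | r] is well
below 1 — drastically so for a two-testlet scale. We therefore standardize
U = Σz² by its exact conditional-on-total mean and variance, computed from
the ESF conditional category probabilities (including the pairwise
conditional covariances for the person-level sums), then apply the
Wilson–Hilferty cube-root transform with the Satterthwaite effective df,
falling back to linear standardization when that df drops below 2 (the
cube-root approximation is unstable there). Under the true model the item
and person fit residual SDs then sit near 1, which is what the ≤ 1.4
decision rule presumes.

**Item-trait chi-square.** Non-extreme persons are grouped into ability
class intervals (default count: floor(n/50) clamped to [2, 10], i.e. 5 at
n = 288; quantile cuts; intervals with fewer than 2 persons are merged).
Per item, χ²_i = Σ_c (O_c − E_c)²/V_c with sums of observed, expected and
variance over the interval; df = C − 1 per item, summed for the total, with
the Bonferroni cut-off 0.05/K.

**Monotonicity.** An item is flagged "disordered" when its adjacent-category
(Andrich) thresholds δ_i + τ_ik are not strictly increasing. Cumulative
(Thurstonian) thresholds are ordered by construction in a PCM, so they
cannot express this diagnostic.

**Local dependence.** Residual correlations are compared against the
relative cut-off LDRC = mean off-diagonal residual correlation + 0.2. The
relative form matters for scales under 20 items, where the compositional
negative baseline (≈ −1/(K−1)) hides dependence from absolute cut-offs.

**Unidimensionality t-test.** Items loading > 0.3 and < −0.3 on the first
principal component of the residual correlations form two subsets (sign
split as fallback; singleton subsets are admissible for super-items —
without this the two-testlet solution could not be assessed at all); per
person t = (θ⁺ − θ⁻)/√(SE⁺² + SE⁻²) with WLE subset estimates; PST = % with
|t| > 1.96, with the normal-approximation 95% binomial CI.

**Conditional total fit.** For the final two-testlet solution the
unconditional chi-square is known to be unreliable at n ≥ 200, so an
Andersen-type likelihood-ratio statistic is computed over raw-score groups.
Free per-group refits of 40-odd category parameters sit largely on the
asymptotic boundary, making the χ² reference unusable; the p-value is
therefore computed by **exact conditional Monte Carlo** — responses are
resampled given each person's total via sequential suffix-ESF draws, so the
reference distribution is correct by construction (asymptotic p reported
alongside). A known limitation: with only two super-items the conditional
family is locally close to saturated, and score-group comparisons have very
little power against smooth parameter drift between ability regions; the
statistic is a calibrated guard, not a sensitive detector (we verified that
location shifts of 1 logit injected into one ability region are absorbed by
the pooled calibration).

## Testlets and subscale indices

A testlet sums its member items into one polytomous super-item
(maxima 40 and 16 for the default partition {1–6, 8–11} and {7, 12–14}),
absorbing within-cluster dependence while conserving every person's total
score exactly. After the re-fit, with per-testlet person series t_k
(WLE), observed variances V_k, error variances E_k = mean SE², true
variances T_k = V_k − E_k, and common covariance C = cov(t₁, t₂):

- r = C/√(T₁T₂), the disattenuated latent correlation, capped to [−1, 1];
- A = C / mean(V_k), the non-error variance common to the subscales;
- c = mean over k of max(0, (T_k − C)/V_k), the average unique variance.

The source publication gives no formulas for c and A; these are our
documented reading of the subtest variance decomposition and are not
comparison surfaces.

## DIF and split impact

Per item and person factor, a two-way ANOVA of standardized residuals on
factor × class interval: the factor main effect is uniform DIF, the
interaction non-uniform, flagged below the Bonferroni cut-off
0.05/(K × factors × 2). Numeric factors (age, disease duration, falls) are
cut at tertiles by default — the original groupings are not reported.
Levels with fewer than 10 persons are dropped with a warning.

For a detected uniform DIF, the item is split into factor-level versions
re-estimated with all other items anchored, and the impact on person
measures is summarized. The textbook "Cohen's d of the paired t-test"
(mean/SD of the differences) is structurally degenerate here: the
level-specific shifts cancel in the overall mean by construction, and under
the null both numerator and denominator are estimation noise of the same
order. We report instead the largest *centred* factor-level mean shift
(common shift across levels is origin drift between solutions, not DIF)
standardized by the SD of the unsplit person measures — a Cohen's d on the
measurement scale with the intended decision behaviour: ≈ 0 without DIF,
above the 0.2 negligibility threshold for a 1-logit DIF on a
high-information super-item.

## Reliability, targeting, strata

PSI = (var(θ̂) − mean SE²)/var(θ̂), with and without extreme scorers;
Cronbach's α on raw item scores (reported N/A for super-item analyses);
SEM = SD·√(1 − PSI with extremes); targeting index = mean person measure /
SEM, with items centred at 0 (|TI| ≤ 1 good, ≤ 2 fair). Because the PSI
assumes a normally distributed sample and the BBS-MS population is
right-skewed, the distribution-free strata count (DLPA) walks the
raw-score-to-measure table and accepts a score whenever its measure exceeds
the last accepted one by 1.96·√(SE_a² + SE_b²); DI-PSI = G²/(1 + G²). This
greedy walk is our documented approximation of the cited distribution-free
method.

The conversion table solves the ML score equation for every raw total under
the anchored calibration and rescales linearly so the extreme measures map
exactly to 0 and 100, with 95% CIs carried through.

## The synthetic world

The generator states the conditions the analysis presumes, once:

- **Ability**: skew-normal, mean +0.75 logits above the item centre,
  SD 1.3, skewness 0.22 — a mistargeted sample with the pooled skewness and
  the ≈ 1.9 targeting index of the motivating population. The
  (location, scale, shape) triple is solved from these moments.
- **Items**: sum-zero locations spanning ≈ 3.8 logits with ordered centred
  thresholds (±1.5 base pattern, deterministic per-item spread), giving an
  item-threshold continuum ≈ 5.5–6.5 logits wide. The sum-zero
  identification makes the default span symmetric where the clinical
  scale's is asymmetric; only the width matters to the pipeline.
- **Local dependence**: a person-level cluster random effect (SD
  `testlet_sd`) added to ability within each of the two item clusters;
  `testlet_sd = 0` yields an exactly specified PCM (the super-item of
  independent PCM items is itself PCM-distributed).
- **Repeated observations**: 1–3 per patient in the cohort's 477:268:69
  proportions; observation-level ability perturbation SD 0.3 logits (the
  within-person correlation is not reported anywhere; any positive value
  exercises the splitter).
- **DIF**: optional uniform shift (logits) of one item for one factor
  level.
- **Covariates**: Gaussian-copula links with latent correlations −0.60
  (EDSS, discretized to 0.5 steps) and +0.55 (ABC), chosen once via
  2·sin(πρ_s/6) plus discretization slack to land the Spearman correlations
  near −0.57 and +0.52; falls are Poisson with log-rate 0.1 − 0.6·z(θ).

Not emulated: dropout or item missingness beyond one demonstrative record,
inter-centre parameter drift, rater effects, and the deposited dataset's
exact marginals. A green test therefore establishes that the *pipeline*
behaves correctly in a world with the assumed structure — not that the
clinical instrument itself has these properties.

## Numerical choices

- Newton/CML: gradient tolerance 1e−6, max 200 iterations, step-halving.
- Person/root solves: `uniroot` on [−15, 15], tolerance 1e−9.
- Polychoric correlations: two-step estimator; thresholds from marginal
  normal quantiles, per-pair ML via 32-node Gauss–Legendre quadrature of
  the bivariate normal identity; +0.5 continuity correction on empty cells.
- One-factor CFA: unweighted least squares on the polychoric matrix
  (L-BFGS-B, loadings bounded at ±0.995), fit indices from the ULS
  discrepancy scaled by (n − 1); modification indices approximated by
  residual correlations > 0.1. The commercial WLSMV estimator is not
  replicated, so those published fit indices are not comparison surfaces.
- Monte Carlo conditional test: 199 draws by default; ties handled by the
  (1 + #{≥ obs})/(B + 1) rule.
- Class intervals, collapse rules, extreme adjustment: as above, all
  surfaced as arguments; decision thresholds live in `pipeline_config()`
  and nowhere else.

## Known limitations

- Tail calibrations of sparse super-item categories are poorly determined
  at n ≈ 288; measures and SEs for rarely observed raw totals are unstable,
  which can depress small-sample PSI for testlet solutions.
- The conditional total fit statistic is calibrated but weak against
  ability-region-specific drift (see above).
- The AISP implementation is the deterministic grow-by-H variant without
  the sampling-based significance screens of the full published procedure.
- Shapiro–Wilk is undefined above n = 5000 and reported NA there.
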