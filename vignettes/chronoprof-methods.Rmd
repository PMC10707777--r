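---
title: "Chrono-nutritional profiling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chrono-nutritional profiling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoprof)
```

## The problem

Patients with severe obesity often eat in erratic temporal patterns that a
simple meal count cannot capture. `chronoprof` implements a pipeline that
turns a binary 24-hour meal-contact diary — eleven predefined eating
occasions, each with a fixed clock window — into *chrono-nutritional
profiles*: groups of patients who eat at similar times of day. The profile
labels then enter descriptive comparisons and regression models for
metabolic and psychological outcomes.

The eleven slots are the three main meals (breakfast 7–8, lunch 12–13,
dinner 19–20), four planned snacks (morning 10–11, afternoon 16–17, evening
21–22, night 3–4) and four nibbling slots — unplanned, constant
between-meal eating (morning 9–12, afternoon 14–18, evening 21–24, night
1–6). A window `[a, b]` marks every integer hour `a..b` inclusive on the
grid `t = 1..24`; whether the endpoints are inclusive is a convention we
had to choose, since clock ranges do not say. Overlapping windows (each
snack sits inside its nibbling window) combine by union because the hourly
indicator is declared binary.

## From flags to curves

Each patient's flags expand to a step function $y(t) \in \{0, 1\}$,
$t = 1,\dots,24$. The eating-probability curve is approximated by a Fourier
basis of order 2 and period 24 h,

$$f(t) = \alpha + \sum_{n=1}^{2} a_n \cos(2\pi n t/24) + b_n \sin(2\pi n t/24),$$

with coefficients estimated per patient by penalized least squares,

$$\sum_{t=1}^{24} (f(t) - y(t))^2 + \lambda \int (D^2 f)^2\,dt .$$

The curvature penalty matrix is computed in closed form over the full
period $[0, 24]$, where the basis is orthogonal
($W = \mathrm{diag}(24,12,12,12,12)$,
$R = \mathrm{diag}(0, c_1, c_1, c_2, c_2)$, $c_n = (2\pi n/24)^4 \cdot 12$),
rather than over the 23-hour window $[1, 24]$: a periodic basis integrated
over a partial period loses orthogonality for no modelled reason. A test
verifies both matrices against composite-Simpson quadrature.

One $\lambda$ is shared by all subjects and selected by minimizing the
pooled generalized cross-validation score
$\mathrm{GCV}(\lambda) = \frac{\sum_i SSE_i / (24N)}{(1 - \mathrm{edf}(\lambda)/24)^2}$
over a 30-point log-spaced grid on $[10^{-4}, 10^3]$ (the source analysis
names no grid); ties go to the smaller $\lambda$. Fitted curves may leave
$[0, 1]$ and are deliberately not clipped — a logistic-smoothed variant was
considered and rejected upstream for over-flattening. Note that because the
same invertible linear smoother is applied to every subject, the choice of
$\lambda$ barely affects the *clustering* geometry; it matters for display
and for the isotropic-noise assumption discussed next.

## Clustering the curves

Curves are compared in the $L^2$ metric by embedding the coefficients as
$z = W^{1/2}\gamma$, so Euclidean distance between embeddings equals
$L^2$ distance between curves. The embeddings are clustered with a
parsimonious Gaussian subspace mixture ("high-dimensional data clustering"
for functional data): cluster $k$ has mean $\mu_k$, an orthonormal basis
$Q_k$, intrinsic dimension $d_k$ chosen by the Cattell scree test
(threshold 0.2), signal variances $a_{kj}$ and isotropic residual noise
$b_k$. The model is fitted by EM from 25 seeded k-means starts; the number
of clusters $K \in 2..6$ is selected by minimizing
$\mathrm{BIC} = -2\ell + m \log N$, ties to the smaller $K$. Hard labels
come from the maximum posterior; for reporting, clusters are relabelled in
decreasing size order so profile 1 is always the largest.

Three numerical choices deserve explanation because the data make them
sharp:

* **Degenerate components.** Several slot probabilities are exactly 0 or 1,
  so identical diaries — hence identical curves — are common, and one
  profile is a literal point mass. A Gaussian component shrinking onto
  duplicated points drives its noise variance $b_k$ to zero and the
  likelihood to $+\infty$; this is the classical mixture collapse, and
  flooring $b_k$ merely converts it into a BIC that always selects the
  largest $K$. The EM therefore *halts at the last valid iterate* when the
  next update would push a component's noise variance to the floor
  ($10^{-6}$). A common-noise sub-model (one pooled $b$), which bounds the
  likelihood by construction, is available via
  `em_settings(model = "common_noise")`.
* **Frozen intrinsic dimensions.** Re-running the scree test at every
  M-step changes the model family mid-run and can decrease the likelihood.
  Each restart therefore selects $d_k$ once, at its first M-step, and keeps
  it fixed, restoring the EM monotonicity guarantee (tested on 50 seeded
  runs).
* **Order-invariant initialization.** k-means is run on a lexicographically
  sorted copy of the embeddings, so permuting the input rows permutes the
  assignments identically under the same seed; hard-start responsibilities
  are softened (0.9 / 0.1) so a start on a cluster of duplicates is not
  immediately singular.

## What the synthetic generator emulates — and what it does not

No patient-level data are distributable, so the package ships a calibrated
generator. Its defaults encode the published cohort: profile weights
80/173, 11/173, 55/173, 27/173; per-profile slot probabilities as the exact
published count ratios (e.g. 74/80, not the rounded 92%), so large-sample
prevalences hit the printed percentages without rounding ambiguity; 68%
female; age from a shifted log-normal truncated to 17–71 calibrated to
median 46 and IQR 39–55; BMI from a log-normal truncated to 32.9–80.3
calibrated to median 43 with tertile cuts 40.2/46.2 (distribution families
are our choice; only the printed summaries are contractual). Binary
comorbidities follow logistic models with the published odds ratios as
generating coefficients; continuous outcomes are a linear predictor plus
right-skewed noise with *exact median zero* (`scale * (LogNormal(0, 0.5) - 1)`,
scales set from the printed IQRs), so median regression — not least
squares — recovers the coefficients. Missingness is injected
missing-at-random through a logistic model on age and gender whose
intercept is root-found to hit the published marginal rates (dyslipidemia
14.5%, shift work 0.6%, BIS-11 2.9%, TC 14.5%, HDL 15.0%, LDL 15.0%,
TG 14.5%, HOMA 15.0%).

One feature of real diaries is deliberately *not* emulated: within-profile
dependence between slots. Contacts are independent Bernoulli draws given
the profile, which is the simplest reading of the published parameters but
makes each profile a product measure rather than a coherent behavioural
cluster. The consequence is visible and documented: a Gaussian-mixture BIC
tends to subdivide the discrete "atoms" of these product measures, so the
selected number of clusters concentrates on 5–6 rather than the published
4 (we confirmed the same inflation with an independent mixture
implementation). A green clustering test therefore establishes that the EM
and BIC machinery work — exact recovery on separated data, monotone
likelihood, correct closed forms — not that four profiles are the
BIC-optimum of this simplified generative world; the largest-profile share
(≈46% of the cohort) is nevertheless reproduced. Smoking is
profile-independent by default (the source reports an association but no
generative rates).

## Imputation

Chained-equation imputation completes missing cells under MAR: predictive
mean matching (5 donors, type-1 matching) for continuous targets, logistic
draws for binary ones, 50 cycles by default, targets visited in increasing
missingness order, one completed dataset returned (the downstream analysis
pools nothing, which matches the single-dataset reading of the source;
"iterated 50 times" is read as cycles). Parameter uncertainty is
propagated by refitting on a bootstrap resample each cycle — simpler than a
posterior draw, distribution-free, same contract. Per-cycle means and SDs
of the imputed cells form the convergence trace
(`plot_imputation_trace()`). Observed cells are never modified, and PMM
values are members of the observed value set by construction.

## Association models

Median (τ = 0.5) regression minimizes the pinball loss, solved by
majorize–minimize iterations polished by an exact vertex search (an
optimal basic solution interpolates *p* observations); a
complete-enumeration LP oracle verifies the attained objective to 1e-8 on
random small instances. Confidence intervals use a pairs bootstrap
(B = 999, percentile) — the CI method is unstated in the source, and the
bootstrap is distribution-free. The quantile AIC uses the
asymmetric-Laplace working likelihood,
$2p + 2n\log(\tfrac1n\sum\rho_{0.5}(r_i))$; goodness of fit is
$R_1 = 1 - V_{full}/V_{null}$. Logistic models are ordinary IRLS fits with
Wald intervals and exponentiated odds ratios. Backward AIC selection
removes whole treatment-coded factor blocks (a 3-level diabetes factor
enters and leaves as one unit), ties broken toward the earliest declared
block; psychometric-score models additionally start from the comorbidity
indicators, the physiological models do not. Intercept-only median fits
return the conventional sample median (the minimizer set is an interval
for even *n*; its midpoint is reported).

## Descriptive battery

BMI is weight/height²; HOMA is insulin × glucose / 22.5 and undefined under
insulin treatment; LDL follows the Friedewald equation in mmol/L
(TG/2.2) with the conventional 4.52 mmol/L (400 mg/dL) validity bound.
Group comparisons use Kruskal–Wallis (Wilcoxon rank-sum for two groups) for
continuous rows and Pearson chi-squared for categorical rows, switching to
a Monte-Carlo exact test — tables drawn conditional on both margins,
$p = (1 + \#\{X^2_{sim} \ge X^2_{obs}\})/(reps+1)$ — whenever any expected
count is below 10. Full network-algorithm exact tests are out of scope at
this table size. BMI tertiles cut at inverse-ECDF (type-1) terciles, so the
cuts are observed values and intervals are right-closed; the published
fixed cuts (40.2, 46.2) are available by argument.

## Limitations

* The generator's independence assumptions (contacts within profile,
  covariates across patients, profiles vs covariates) are modelling
  choices, not published facts; associations other than those explicitly
  parameterized will be absent from synthetic cohorts.
* Cluster-number selection on synthetic cohorts inherits the atom-splitting
  bias discussed above.
* HOMA's additive noise can rarely dip below zero in the synthetic tails;
  the value is a stand-in for distribution shape, not physiology.
* p-values from the regression layer are not calibrated against the source
  tables; only table *shape* and parameter recovery are claimed.
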