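---
title: "Methods: multimodal PLS lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal PLS lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic post-stroke aphasia is assessed with batteries whose subtests are
strongly inter-correlated (here: WAB-R spontaneous speech, naming,
repetition and auditory comprehension, pairwise r = 0.63-0.84), and the
middle-cerebral-artery strokes that cause it damage spatially contiguous
sets of regions. Mass-univariate lesion-symptom mapping cannot separate
anatomy that degrades *all* subtests (shared substrates of the perisylvian
network) from anatomy tied to *one* subtest (unique substrates).
`lesionpls` implements a latent-variable alternative: per neuroimaging
modality, a partial least squares regression (PLSR) of the four subtest
scores on region-level features, followed by variable-importance
consensus across modalities (shared anatomy), beta-contrast calling
(unique anatomy), and a two-stage variance decomposition.

## The PLS model

Let $X$ ($n \times p$, subjects by features) and $Y$ ($n \times 4$) be
column-centered and unit-variance scaled. Components $a = 1, \dots, A$
are extracted sequentially: the weight vector $w_a$ is the leading left
singular vector of the current cross-covariance $S_a = X_a^\top Y$,
scores are $t_a = X_a w_a$, X-loadings $p_a = X_a^\top t_a / t_a^\top
t_a$, Y-loadings $q_a = Y^\top t_a / t_a^\top t_a$, and $X$ is deflated
by score regression ($X_{a+1} = X_a - t_a p_a^\top$). The implementation
never copies the deflated $n \times p$ block: because $X_{a+1}^\top Y =
X_a^\top Y - p_a (t_a^\top Y)$, it updates the $p \times 4$
cross-covariance instead, which keeps connectome matrices
($p = 73{,}536$ edges) cheap. This is the classical regression-mode PLS2
fixed point; predictions and VIP scores agree with an independent NIPALS
implementation (mixOmics) to $10^{-6}$ in the tests, and with ordinary
least squares at full rank. Whether $Y$ is additionally deflated is
immaterial: $X_{a+1}^\top t_a = 0$ exactly, so the weight sequence is
unchanged.

Regression coefficients are $B = W (P^\top W)^{-1} Q^\top$ on the
standardized scale, back-transformed to original units for prediction.
Each weight vector's sign is fixed so its largest-magnitude entry is
positive; predictions and VIP are invariant to these sign choices, which
exist only to make stored loadings deterministic.

Variable importance in projection is the standard Wold form
$$\mathrm{VIP}_j = \sqrt{p \, \frac{\sum_a \mathrm{SSY}_a \,
(w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},\qquad
\mathrm{SSY}_a = (t_a^\top t_a)\lVert q_a \rVert^2,$$
so $\sum_j \mathrm{VIP}_j^2 = p$ exactly. Explained covariance per
component is the squared singular value of the deflated cross-covariance
over the squared Frobenius norm of the initial one; the per-modality
"components to 50% covariance" table uses this quantity. Components are
extracted in decreasing covariance order, which for every case we
examined coincides with decreasing explained-Y order; the explained
X-variance and Y-variance columns are both reported so either ranking
can be read off.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_components` | 20 | latent variables computed per model |
| `n_retained` | 5 | components used for VIP, betas and LOOCV |
| `vip_threshold` | 1.5 | minimum VIP for selection |
| top-$N$ | 50 / 30 | selected features, connectivity / other modalities |
| `beta_threshold` | 0.2 | cut on the min-max-rescaled \|beta\| |
| `min_models` / `min_models_core` | 4 / 6 | consensus thresholds (of 11 models) |
| `min_modalities` | 2 | supporting models for a unique call |
| `min_variant` | 5 | minimum-affection filter (subjects deviating from the feature median) |

Both $X$ and $Y$ are z-scored by default: VIP comparisons across regions
(and across modalities with different units) are only meaningful on a
common scale. A flag disables scaling for already-commensurate inputs.

## Cross-validation and selection modes

Model accuracy is the Pearson correlation between observed scores and
leave-one-out predictions (centering, scaling and fitting re-estimated
inside each fold), with the exact t-transform p-value on $n-2$ df and a
supplementary Benjamini-Hochberg column. The VIP-restricted regression
is run in two modes: `paper` selects the high-VIP features once on the
full data and cross-validates the restricted matrix (the conventional
procedure, optimistic because selection has seen every subject), and
`nested` repeats the selection inside every fold (leakage-free, the
default headline). On pure-noise responses the paper mode's mean r
exceeds the nested mode's, which is quantified in the test suite; both
are reported so the selection optimism is visible rather than silent.

A minimum-affection filter precedes each modality fit: features whose
value deviates from the feature median in fewer than 5 subjects are
dropped. Zero-inflated lesion features damaged in one or two subjects
have no estimable variance inside folds, and a single held-out damaged
subject then receives an arbitrarily extreme standardized value; the
filter is the usual minimum-lesion-overlap criterion generalized to any
feature, uses $X$ only, and therefore leaks nothing about the responses.

## Shared and unique anatomy

Shared anatomy is the cross-modality consensus of VIP selections: a
region counts in a connectivity model when at least 2 selected edges
touch it (the incident-edge aggregation is our convention; connectivity
selections are edge-level), and the consensus set keeps regions selected
in at least 4 (core: 6) of the 11 models. Raising the threshold can only
shrink the set.

Unique anatomy is called from the standardized beta maps of the retained
components. Within each modality, \|beta\| values (edge betas aggregated
to regions by the incident maximum) are min-max rescaled to $[0, 1]$
jointly over the four subtest columns and thresholded at 0.2; a region
is modality-unique for a subtest when it passes for exactly that one
subtest, and the final map needs agreement in at least 2 modalities.
Magnitudes, not signs, are compared: damage raises MD but lowers FA and
CBF while implicating the same region. Two design points deserve
explanation:

* *Order of operations.* A raw threshold of 0.2 on standardized PLS
  betas never fires at $p = 384$: coefficient mass is shared across
  correlated features, so individual betas are $O(10^{-2})$. The
  threshold is therefore applied to the rescaled magnitudes (the
  threshold-first variant is available via `rescale_first = FALSE` for
  comparison, and the per-subtest rescaling variant via
  `rescale_scope = "subtest"`).
* *Rescaling scope.* Rescaling each subtest column separately makes the
  weakest column's small maximum the denominator and floods it with
  false calls; one rescale per modality preserves between-subtest
  magnitude contrasts and is the default.

The two-stage decomposition regresses each subtest on the proportional
lesion (damage/100) of the top-4 core-consensus regions (ordinary least
squares; shared $R^2$), then the stage-1 residuals on MD of that
subtest's unique regions (residual $\Delta R^2$ with per-predictor
p-values). Stage-2 predictors are capped at the 10 best-supported
regions: with predictor counts approaching $n = 86$ the residual
regression saturates mechanically. Near-singular shared blocks
(condition number above $10^8$) fall back to a pseudoinverse fit with a
warning.

## The synthetic cohort generator

No patient data are distributable, so the pipeline is exercised on a
generator that reproduces the cohort's printed statistical structure:

* **Behaviour.** Scores are a censored Gaussian copula: latent normal
  margins clipped to $[0, \text{max}]$ (20/10/10/10), reproducing the
  ceiling effects of bounded clinical scales. Latent means/SDs are
  solved against the closed-form moments of the doubly censored normal
  (fixed point, tolerance $10^{-3}$, at most 25 iterations); latent
  pairwise correlations are solved by `uniroot` against the
  post-clipping correlation evaluated with 80-node Gauss-Hermite
  quadrature; the latent correlation matrix is `nearPD`-repaired if
  needed. Calibration targets are the cohort means (11.4, 5.4, 5.2,
  7.7), SDs (4.9, 3.0, 2.9, 1.8) and the six pairwise correlations
  (0.63-0.84). The AQ spread (SD 23.0) and the AQ-spontaneous-speech
  correlation (0.96) are *not* calibrated; they emerge from the pairwise
  structure and are asserted as emergent-consistency checks.
* **Severity and lesions.** A single latent severity factor (the first
  principal component of the latent correlation, sign-flipped) couples
  behaviour to anatomy. Damage spreads from a random seed position along
  an ordered 60-region left-hemisphere territory with a linear ramp
  edge; the extent is `pnorm(severity)` plus jitter, so minimal severity
  gives an empty lesion and maximal severity damages the whole territory
  at >= 90%. Outside the territory, incidental damage occurs at rate
  0.02 per region.
* **Modalities.** Each regional modality is a monotone link of damage
  (FA, CBF, VBM, pALF and the task-fMRI contrast decrease; MD, in
  $10^{-3}\,\mathrm{mm^2/s}$, increases), with Gaussian noise at 25% of
  the healthy dynamic range. Connectome edges attenuate by
  $(1 - 0.95\,d_i)(1 - 0.95\,d_j)$ in the endpoint damage fractions, so
  an edge touching a destroyed region keeps at most 5% of its healthy
  weight. i3mT1 is the damage fraction plus blur.
* **Planted effects.** A shared factor adds damage variance to 4
  territory regions across every lesion-linked channel and shifts all
  four subtests by 0.5 target-SD per unit; per subtest, an independent
  factor perturbs 3 unique regions in three channels (MD +0.50, FA
  -0.18, CBF -20 per unit - chosen so the planted effects dominate
  their beta columns and the recovery analyses are well-posed) and
  shifts only that subtest by its slope (SS 0.15, N 0.35, R 0.35,
  AC 0.55 SD - ordered to mirror the observed residual-variance
  hierarchy, in which auditory comprehension carries the most unique
  variance and spontaneous speech the least).

What the generator deliberately does **not** emulate: voxel-level
signal, spatial smoothness within regions, multi-territory or bilateral
strokes, and the rich multi-factor latent structure of real multimodal
imaging. Its covariance is dominated by the single severity factor, so
cross-validated accuracies (r around 0.5-0.8) run higher than is
realistic for clinical cohorts, and a single latent variable often
already explains half the brain-behaviour covariance. Passing recovery
tests therefore demonstrates the pipeline's correctness and its
behaviour under collinearity - not expected real-data effect sizes.

## Numerical choices and degenerate inputs

Constant columns are centered but not scaled and are flagged; constant
responses make VIP undefined and raise an error. Score collapse
(`t^T t < 10^{-12}`) truncates the component sequence. VIP ties in the
selection ranking are broken by feature index. The symmetry tolerance
for connectome input is $10^{-6}$ relative; asymmetric input is an
error, nominally-symmetric input is symmetrized. Correlations with
undefined variance are flagged rather than silently zeroed. Seeds flow
from a single `cohort_spec` seed through every generator stage;
identical seeds give bitwise-identical cohorts and output files.

## Problem sizes in the test suite

The suite exercises the generator-default study conditions (n = 86, 384
regions, 11 modalities, 20/5 components) for the recovery analyses, with
10 replicate cohorts; oracle comparisons run on small instances
(n <= 60, p <= 40) where brute-force enumeration, fold-by-fold OLS and
dense SVD are exact. The end-to-end default pipeline (including both
restricted-CV modes for both connectome modalities) completes in about
3 minutes on one CPU; the analysis drivers under `analysis/` print the
same tables they write under `results/`.

## Known limitations

* Shared-anatomy consensus is robust (planted territory regions are
  recovered in the core consensus in every tested replicate), but
  unique-region calling at the 0.2 rescaled-beta threshold operates at
  the sampling-noise floor of beta maps at n = 86: auditory-comprehension
  effects (the largest planted slope, and the least collinear subtest)
  are recovered reliably, while spontaneous-speech/naming/repetition
  contrasts - inter-correlated at 0.83-0.84 - are frequently smeared
  across each other, and the unique maps contain noise regions supported
  by chance agreement between two modalities. This mirrors the intrinsic
  difficulty the latent-variable approach is designed to expose, and the
  acceptance suite reports it rather than hiding it.
* The incident-edge aggregation of connectivity selections and betas to
  regions is a convention, not an identified quantity.
* The severity-dominated generator cannot probe how the pipeline ranks
  multiple comparable latent factors.
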