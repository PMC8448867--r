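---
title: "Prognostic modelling of anomia treatment response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modelling of anomia treatment response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anomiaPLS)
```

## The problem

Roughly a third of stroke survivors are left with aphasia, and naming
difficulty (anomia) is its most common expression. Computerised massed-practice
therapies improve naming on trained items at the group level, but individual
responses vary enormously, and clinicians have had little basis for predicting
who will benefit. This package implements a complete prognostic-modelling
workflow for that question: given pre-treatment structural lesion data,
demographics, initial naming severity and the therapy dose actually delivered,
how well can a model predict each patient's improvement on trained items — and
is it reliably better than predicting everyone to improve by the group mean?

The workflow has five stages, each exposed as ordinary R functions and
exercised end to end by the scripts under `analysis/`:

1. **Lesion encoding** (`encode_cohort()`): binary lesion masks are reduced to
   *lesion loads* — for each anatomical region, the fraction of its voxels the
   lesion covers. Probabilistic atlas regions are first binarized at an
   inclusive 50% threshold. Regions in which *no* patient has any damage carry
   no information and are removed (and recorded); in a single-hemisphere
   cohort this typically prunes over half of a whole-brain parcellation.
2. **Modelling** (`fit_model()`): partial least squares (PLS) regression over
   any combination of predictor blocks, against a group-mean null model.
3. **Evaluation** (`cross_validate()`): repeated k-fold cross-validation with
   fold plans shared across all models.
4. **Comparison** (`paired_permutation_test()`, `fwe_adjust()`): paired
   signed-rank statistics thresholded by a within-pair sign-flip permutation
   null, with familywise error control.
5. **Interpretation** (`perturb_and_weigh()`, `proxy_region_analysis()`):
   data-perturbation influence weights for a *fixed* fitted model.

## The model

With $n$ patients and $p$ predictors (possibly $p \gg n$ once ~10^2 region
loads enter), ordinary regression overfits catastrophically at $n \approx 18$.
PLS regression extracts $A$ latent components $t_a = X w_a$ chosen to maximise
covariance with the response, then regresses the response on those components;
back-substitution gives coefficients in the original variable space, so a
fitted model is a single affine map. The implementation is the classical
NIPALS sequence for a univariate response, with three contractual properties
the tests pin down:

* at $A = \operatorname{rank}(X)$ the fit equals ordinary least squares
  (tolerance 1e-8 in the tests);
* a constant response (zero covariance at the first step) yields a zero
  coefficient vector and an intercept equal to that constant, so degenerate
  training folds never error;
* predictions are invariant to predictor order, to affine rescaling of any
  predictor, and to appending constant predictors — consequences of the
  z-scoring convention below.

**Number of components.** $n = 18$ forbids more than a few components. The
default is `ncomp = 2`, applied to every model in the grid; it is capped
automatically at `min(n_train - 1, p)` inside small training folds. An
optional nested selection (`select_ncomp = TRUE`) chooses `1:ncomp` by a
deterministic internal 5-fold split of the training sample, so selection never
sees test data. Two components is a deliberate bias-variance compromise, not
an optimum: the planted-truth simulations recover the signal at 2 components,
and sweeping the choice is a one-argument change.

**Standardization.** All predictors are z-scored before entering a model
(sample sd, $n-1$ denominator; zero-sd columns map to zero). The response is
centred on the training data but never scaled. In cross-validation the scaling
statistics come, by default, from the whole cohort
(`standardize_scope = "cohort"`), the usual "standardised prior to entry into
models" convention. The alternative `"training"` scope recomputes them inside
every training fold. The cohort scope is the default for a numerical reason
worth understanding: lesion loads are bounded in $[0,1]$ and often sparse — a
region substantially damaged in a single patient has near-zero sd in any
training fold that excludes that patient, so the fold-internal z-value of the
held-out patient can reach $|z| \sim 30$–50 and a single squared error of
several thousand then dominates the loss. Cohort-scope scaling bounds every
z-value by $\sqrt{n-1}$. The leakage this admits is of predictor moments only
(never the response), and in a prognostic application the predictor
distribution is available at prediction time anyway; users who want strictly
fold-internal statistics set one argument.

**Sex coding.** 0/1; z-scoring makes the reference level irrelevant to
predictions.

## Evaluation and comparison

`make_fold_plan()` draws $R$ independent balanced partitions of the patients
into $k$ folds (defaults $R = 1000$, $k = 10$; for 18 patients each partition
is eight folds of two and two folds of one). The same plan is reused for
every model, so the per-repetition losses are paired. Within a repetition,
out-of-fold predictions for all patients are pooled into one mean squared
error (the pooled convention, fixed and documented; with near-equal folds it
differs negligibly from averaging per-fold losses). Both MSE and RMSE are
stored; summary tables report median and inter-quartile range across
repetitions, since CV losses are right-skewed.

Because repetitions share training data, they are far from independent and a
naive paired test across the $R$ losses is not trustworthy. The comparison
therefore uses the Wilcoxon signed-rank statistic (zero differences dropped,
mean ranks for ties) thresholded against a *within-pair label permutation*
null: each pair's model labels are swapped independently with probability
one half — equivalently the sign of each paired difference is flipped — and
the statistic recomputed (default 10,000 permutations). The two-sided p-value
compares absolute centred statistics with add-one smoothing, so it never
falls below $1/(B+1)$. Familywise error over the model grid is controlled by
Bonferroni by default; a max-statistic joint permutation (`fwe_maxT()`) is
available and less conservative under the strong positive dependence of a
shared fold plan.

A calibration caveat the tests make explicit: with exchangeable pairs the
test holds its level (the suite verifies a rejection rate near 5% and a
familywise rate at or below nominal). What no within-dataset permutation can
control is *dataset-level* chance: at $n = 18$ with strongly collinear lesion
loads, the dominant load direction aligns with pure noise to $|r| \sim 0.7$
in a sizeable fraction of cohort realizations, every fold learns that
alignment, and the model genuinely beats the null *on that dataset*. In
global-null simulations this happens in roughly a fifth of 18-patient
cohorts, falling to the nominal rate by $n \approx 48$. A significant
comparison therefore supports predictability of this cohort's responses; only
external validation supports generalisation — a limitation inherent to the
design, not an implementation artefact.

## Interpretation by data perturbation

PLS component weights are awkward to read (multiple components, arbitrary
signs), so influence is estimated behaviourally. Holding the fitted
coefficients fixed, each of 1000 iterations selects every predictor
independently with probability 0.5 (unselected predictors keep their
empirical values), shuffles each selected predictor's values across patients
(preserving its marginal distribution; bootstrap resampling is available
behind a flag), and records the model's predictions. All
$n \times 1000$ rows are pooled and each predictor's *influence weight* is
the Pearson correlation between its column and the predictions (Spearman
behind a flag). The per-variable inclusion probability 0.5 maximises the
variance of inclusion patterns and is symmetric across variables; it is
exposed as a parameter.

The weights are correlations, so they measure *marginal* association with the
model's behaviour, not causal coefficients. That is exactly what makes the
counter-intuitive ("proxy") weights interpretable: when damage in region A
statistically implies sparing of region B whose damage predicts poor
response, A acquires a positive weight. `proxy_region_analysis()` quantifies
this by correlating a target region's column of pairwise load correlations
with the other regions' influence weights; on the default synthetic cohort
the strongest positive-weight region yields a summary correlation around 0.8
(typically 0.6–0.95 across generator seeds, occasionally lower when a
realization plants little counter-intuitive structure).

Stability: `stability_check()` repeats the whole procedure with independent
sub-seeds and reports the minimum pairwise correlation between weight
vectors. At 1000 iterations ten repetitions agree to better than 0.99 on the
default cohort (the acceptance script recomputes this); at 10 iterations they
visibly do not, and the suite checks the improvement with iteration count.

## The synthetic cohort generator

No patient data ship with the package; `simulate_cohort()` generates cohorts
with the statistical structure the analysis assumes, plus ground truth for
recovery tests. Defaults (all overridable through `synthetic_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 18 | the small-cohort regime the method targets |
| `grid`, `n_regions` | 20×20×20, 40 | desk-scale stand-in for a multi-atlas parcellation |
| `territory_frac` | 0.5 | lesions confined to half the grid, so the encoder prunes the untouched regions (the single-hemisphere analogue) |
| `n_blobs`, `blob_size` | 3, 180 | contiguous random-walk blobs; neighbouring regions damaged together |
| `hours_mean`, `hours_sd` | 73, 25 | the reported therapy-dose distribution for this treatment |
| `n_negative_regions`, `weight_scale` | 6, −25 | a spatially coherent damage cluster whose lesioning costs naming-count points |
| `beta_hours` | 0.25 | dose effect sized so its marginal correlation with the response is ≈ 0.3 — large enough to be identifiable at n = 18, matching the modest dose weight such models report |
| `beta_interaction` | 0 | additive ground truth by default; an hours×lesion interaction is available |
| `noise_frac` | 0.1 | noise sd = 10% of the noiseless signal's sd |
| `n_behavioural` | 28 | assessment scores as noisy mixtures of lesion loads, emulating behaviour–lesion collinearity |

Three structural choices matter most. Each patient's blobs are seeded near
one of two foci inside the territory, with a patient-specific U-shaped mixing
proportion: loads near focus A then anticorrelate with loads near focus B
across the cohort, which is what lets a spared region act as a proxy for
damage elsewhere. A patient-level lognormal severity factor scales all of a
patient's blobs together, reproducing the heavy-tailed lesion volumes of real
cohorts and the resulting positive correlations among neighbouring regions.
And the planted weights sit on the regions nearest focus A, so the ground
truth is a coherent damage cluster rather than scattered single regions. The
resulting response scale (null-model CV MSE of roughly 200–300 at default
settings) matches the order of magnitude such treatment studies report.

What the generator does **not** emulate: registration and segmentation error
in the masks, non-linear dose–response, floor/ceiling effects in naming
scores (responses are continuous by default; integer rounding is a flag),
measurement error in the behavioural battery beyond simple Gaussian noise,
and any true hours×lesion interaction unless requested. Passing tests on this
generator therefore demonstrate that the *pipeline* recovers planted
structure under the stated assumptions — not that real anomia responses are
this predictable.

## Numerical choices and degenerate inputs

* NIPALS stops early when the residual covariance norm falls below
  `1e-12 × max(1, ‖E‖², ‖f‖²)`; remaining components are zero.
* Zero-sd predictor columns z-score to zero everywhere (train and apply).
* The signed-rank statistic drops zero differences and mean-ranks ties; an
  all-zero difference vector is flagged degenerate with p = 1.
* Permutation p-values use add-one smoothing; the two-sided comparison uses
  absolute centred statistics with a 1e-9 tolerance so floating-point ties
  count as exceedances.
* Voronoi ties in the toy atlas resolve to the lowest region index;
  fold-size remainders go to the lowest fold indices — both deterministic.
* Every stochastic stage takes a seed; `spawn_seeds()` derives independent
  sub-seeds from one master seed, and `run_grid()` outputs are byte-identical
  across reruns with the same master seed.

## Problem sizes used by the tests

The suite favours many seeds over long chains: parameter-recovery runs use
20 generator seeds at 100×10-fold CV (the headline convention is 1000
repetitions; the ranking stabilises far earlier), calibration uses 1000
marginal and 500 familywise simulations at 999 permutations, and the
analysis scripts default to 200 repetitions with 10,000 permutations. These
sizes were chosen so the whole suite documents the method's behaviour in a
few minutes on one CPU while leaving every convention (repetitions,
permutations, iterations) a single argument away from the full-scale run.

## Known limitations

* Dataset-level type-I inflation at very small n, discussed above: the
  permutation threshold validates within-cohort predictability, not
  generalisation.
* Influence weights are marginal correlations; planted coefficients whose
  marginal association is flipped by lesion collinearity are reported with
  the flipped sign — by design, and the proxy-region analysis exists to
  diagnose exactly this.
* The pipeline models a scalar response; multivariate responses (e.g.
  trained and untrained items jointly) would need a PLS2 extension.
* No spatial normalisation or lesion segmentation: masks and atlases must
  already share a grid, enforced by the `space_tag` contract.
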