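# anomiaPLS

Prognostic modelling of individual responses to computerised anomia therapy
after left-hemisphere stroke — from atlas-encoded lesion damage and therapy
dose, with honest small-sample evaluation.

## The scientific problem

Anomia (impaired naming of common objects) is the most common language
deficit after stroke, and massed-practice naming therapy helps — but some
patients improve dramatically and others barely at all. The question this
package operationalises: **can a patient's improvement on trained items be
predicted, before therapy starts, from where and how much lesion damage they
have and how many hours of practice they complete?** It is aimed at
researchers building or stress-testing such prognostic models on small,
precious treatment cohorts (n ≈ 20).

The core method, in the field's standard notation:

* **Lesion load.** For patient $i$ and region $r$ on a shared 2 mm grid,
  $L_{ir} = |{\rm lesion}_i \cap r| / |r| \in [0,1]$; probabilistic atlas
  regions are binarized at an inclusive 50% threshold, and regions with zero
  load in every patient are removed.
* **Models.** PLS regression (NIPALS, response centred, predictors z-scored)
  of treatment response $\Delta y_i$ (change in trained-item naming count) on
  any combination of predictor blocks — demographics, initial severity,
  therapy hours, behavioural scores, lesion loads — against the **null
  model** $\hat y_i = \bar y_{\rm train}$.
* **Evaluation.** $R$×$k$-fold cross-validation (default 1000×10) with fold
  plans shared across models, per-repetition pooled MSE; models compared by
  the paired Wilcoxon signed-rank statistic thresholded against a
  within-pair sign-flip permutation null, Bonferroni-corrected over the
  model grid.
* **Interpretation.** Data perturbation: with the fitted coefficients
  frozen, random predictor subsets are shuffled across patients and each
  predictor's influence weight is the Pearson correlation between its
  (perturbed) values and the model's predictions over the pooled
  patients×iterations sample — including the diagnostic for
  counter-intuitive "proxy" lesion weights.

Because treatment cohorts of this kind are not publicly shareable, the
package ships a synthetic cohort generator (`simulate_cohort()`) that
reproduces the structure the analysis assumes — contiguous lesion blobs in a
restricted territory, correlated region loads, therapy hours ≈ 73 ± 25, a
planted region-weight map plus dose term, 10% noise — with ground truth
retained, so every stage is testable and every number below is reproducible
from a seed.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the default
synthetic cohort and write tables under `results/`. Stage 3 evaluates all 15
block combinations plus the null model on one shared 200×10-fold plan:

```sh
$ Rscript analysis/03_grid.R
model grid, ordered by median CV MSE (IQR in brackets):
  hours+lesions                                   107.4 (11.6)
  hours+initial_severity+lesions                  112.7 (12.7)
  hours+demographics+lesions                      115.9 (14.9)
  ...
  null                                            197.5 (10.9)
  ...
  initial_severity+demographics                   249.9 (29.6)

15 of 15 models differ significantly from the null after FWE correction
best model: hours+lesions
predicted vs empirical response: r = 0.64 (95% CI 0.40, 0.85)
```

Reading this: the null model's median MSE (198) is the variance-level
baseline; the planted truth (lesion damage + therapy hours) is correctly
identified as the best configuration (107, a 46% loss reduction), lesion-free
models hover near or above the null, and the best model's mean out-of-fold
predictions correlate r = 0.64 with the "empirical" responses — with a
percentile-bootstrap 95% CI from 2000 resamples.

Stage 4 interprets the winning model:

```sh
$ Rscript analysis/04_interpret.R
therapy-hours influence weight: 0.42
strongest negative region weights (planted damage cluster):
 variable_id     weight
         R14 -0.5204484
         R10 -0.3751769
         ...
stability: minimum pairwise weight correlation over 10 runs = 0.9983
proxy region R22: weight 0.36; correlation between its load-correlation profile
  and the influence weights of the other regions: r = 0.57
```

More practice hours predict more improvement (weight +0.42); the planted
damage cluster carries the strongest negative weights; ten independent
perturbation runs agree to r > 0.99; and the strongest *positive* lesion
weight is largely explained by that region's load correlations with the rest
of the cohort — damage there is a proxy for sparing of the regions that
matter. The methods vignette
(`vignettes/prognostic-modelling.Rmd`) explains each design choice and its
limits.

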