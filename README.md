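# monktone

Continuous skin-tone estimation on the 10-point **Monk Skin Tone (MST)
Scale** from RGB face images captured under varied illumination.

Perceived skin colour mixes two things: pigmentation and the light it was
photographed under. A light source tints every pixel multiplicatively (the
von Kries / diagonal illuminant model), so a model that reads tone off raw
colour alone breaks the moment the lamps change. `monktone` is for
researchers in computational skin-colour measurement, fairness auditing of
face pipelines, and imaging method development who need a *tested, fully
reproducible* pipeline for this estimation problem: a seeded synthetic
studio standing in for a private capture corpus, deterministic
preprocessing and ablation operators, CNN regression/classification
estimators with transfer-learning mechanics, and an evaluation framework
built on threshold accuracies and CIELAB error.

## The model and metrics

A continuous tone index `x ∈ [1, 10]` maps to sRGB by linear interpolation
between the MST anchor colours `C_1 … C_10` (light → dark):

    Ĉ = C_n + (C_{n+1} − C_n) · (x − ⌊x⌋),  n = ⌊x⌋

A VGG-style CNN (conv + batch norm + ReLU blocks, sigmoid/dropout FC
head) is trained with SGD-with-momentum on MSE loss
`(1/N) Σ (x̂_i − x_i)²` to regress `x` from LAB-converted face crops; a
10-class softmax variant handles the classification comparison.
Estimates are scored by

* **threshold accuracy** `A_n` — the percentage of samples with
  `|x̂_i − x_i| ≤ n·0.1`, collected over a threshold grid (headline
  thresholds 0.5, 1, 2);
* **LAB error** `μ ± σ` — estimates and targets are mapped through the
  scale to CIELAB (D65, float convention) and summarised by the mean and
  *population* standard deviation of the Euclidean distances, broken down
  per light type and per tone group (1–3, 4–7, 8–10).

## Worked example

A desk-scale experiment — 30 synthetic identities under all 15 lighting
conditions, identity-disjoint 65:35 split, tiny regression profile at
64 px — runs in about a minute on one CPU:

```r
library(monktone)

cfg <- experiment_config(
  seed = 42,
  simulator = list(n_identities = 30L, rotations = "front", size = 64L),
  input = list(colour_mode = "LAB", side = 64L),
  model = list(profile = "tiny"),
  train = list(learning_rate = 1e-3, epochs = 8L),
  ablation = list(augment = FALSE)
)
ex <- run_experiment(cfg, quiet = TRUE)
glance(ex$report)
#> # A tibble: 1 × 6
#>   accuracy_0.5 accuracy_1 accuracy_2 lab_mu lab_sigma     n
#>          <dbl>      <dbl>      <dbl>  <dbl>     <dbl> <dbl>
#> 1         57.6       87.3        100   7.80      6.42   165
tail(tidy(ex$fit), 3)
#> # A tibble: 3 × 4
#>   epoch  loss train_acc val_acc
#>   <int> <dbl>     <dbl>   <dbl>
#> 1     6  1.94      29.8    46.1
#> 2     7  1.49      29.5    55.8
#> 3     8  1.41      35.4    57.6
```

Reading: on 165 held-out images of unseen identities, 57.6% of tone
estimates land within 0.5 Monk units of the truth (chance at that
threshold is roughly 10%), every estimate is within 2 units, and the mean
LAB colour error is 7.8 ± 6.4 — the network has largely separated tone
from the illuminant colour cast. `autoplot(ex$fit)` and
`accuracy_distribution(class_distances(ex$estimates$estimate,
ex$estimates$true_tone)) |> autoplot()` plot the training curves and the
accuracy distribution; `tidy(ex$report)` holds the per-light and
per-group breakdowns.

Other entry points: `build_dataset()` (the synthetic studio),
`split_identities()`, `augment_flips()`, `grey_world_balance()`,
`shuffle_pixels()` (ablation operators), `build_model()` /
`train_model()` / `freeze_layers()` / `fine_tune()` (estimators), and
`run_ablation()` for the dataset-permutation arms. A thin CLI wraps the
same functions: `exec/monktone simulate --identities 10 --seed 1 --out
dir/`. See `vignettes/monktone-methods.Rmd` for the full methods
account.

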