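# milsurv

Attention-based multiple instance learning (MIL) for survival risk
prediction from histopathology tissue-microarray (TMA) images, in R.

## The problem

Predicting disease-specific survival from H&E-stained tissue is a weakly
supervised problem: one label per patient — follow-up time and event
indicator $(t_i, \delta_i)$ — versus hundreds of image patches per
patient, of which only some carry prognostic signal. `milsurv` treats each
patient as a *bag* of patch feature vectors and learns a patient-level
risk score with attention pooling:

$$z=\sum_{i=1}^{C} a_i h_i,\qquad
a_i=\frac{\exp\{w^\top\tanh(V h_i)\}}{\sum_j \exp\{w^\top\tanh(V h_j)\}},$$

where $h_i$ is a shared conv→ReLU→global-average-pool embedding of an
input unit (a single patch encoding, or a k-means phenotype stack of them)
and the risk head maps $z$ to a scalar $o_i$. Training minimises the Cox
negative partial log-likelihood

$$L(o)=\sum_i \delta_i\Big(-o_i+\log\sum_{j:t_j\ge t_i} e^{o_j}\Big)$$

with a pairwise ranking refinement $-\log\sigma(o_i-o_j)$ added after a
configurable number of epochs. Evaluation uses the concordance index
$\hat c=(C+R/2)/(C+D+R)$ over permissible pairs under right-censoring, and
downstream prognostic significance is assessed by median-cutoff
dichotomisation, Kaplan–Meier curves and univariate/multivariate Cox
proportional-hazards regression in three stages (test split, test +
validation, full cohort).

The package covers the whole pipeline: tissue masking (Otsu → closing →
selective hole suppression at 1470 µm²) and non-overlapping patch tiling
of core images; geometric/colour dataset augmentation (4× and 13×
schemes); a pluggable patch-encoder contract with a deterministic
synthetic stand-in (256 px patch → ×2 downsample → 128-d vector, with
2×2×128 super-patch assembly); per-patient k-means phenotype clustering;
both MIL variants (phenotype-level and instance-level attention);
attention heatmap rendering; and a synthetic cohort simulator with known
proportional-hazards risk structure so everything is testable without
clinical data. Who it is for: computational-pathology researchers who want
a transparent, fully tested reference implementation of attention-MIL
survival modelling, and methodologists who need a simulator-backed harness
for this class of models.

## Worked example

Simulate a 200-patient cohort in which ~20% of instances per bag carry a
risk motif (log hazard ratio 2 per SD of signal burden, 30% censoring),
train the instance-level model on fold 1 of a 5-fold plan, and assess the
predictions:

```r
library(milsurv)
library(dplyr)

sim  <- simulate_cohort(sim_config(seed = 1))
plan <- make_folds(sim$truth, n_folds = 5, seed = 1)
cfg  <- train_config(learning_rate = 1e-3, epochs = 100,
                     rank_loss_start_epoch = 50, seed = 1)
fit  <- mil_train(sim$bags, plan, fold = 1, config = cfg,
                  variant = "instance", M = 16, L = 32, dropout_rate = 0.5)
glance(fit)
#> # A tibble: 1 × 6
#>   variant      k learning_rate epochs best_epoch best_val_cindex
#>   <chr>    <int>         <dbl>  <int>      <int>           <dbl>
#> 1 instance    NA         0.001    100         22           0.750

test_ids <- plan |> filter(fold == 1, role == "test") |> pull(patient_id)
preds <- predict(fit, sim$bags[test_ids])
lab <- bag_labels(sim$bags[test_ids])
concordance_index(preds$risk, lab$time, lab$event)
#> # A tibble: 1 × 5
#>   c_index concordant discordant tied_risk n_permissible
#>     <dbl>      <int>      <int>     <int>         <int>
#> 1   0.773        478        140         0           618
```

The best checkpoint (epoch 22, validation c-index 0.750) ranks the
held-out test patients with c-index 0.773: 478 of 618 permissible pairs
are ordered correctly. The staged statistical analysis dichotomises
predictions at each stage's own median and fits Cox models on the
high/low indicator:

```r
all_preds <- predict(fit, sim$bags)
staged <- staged_analysis(all_preds[c("patient_id", "risk")],
                          sim$truth, plan, fold = 1)
tidy(staged) |> select(stage, cutoff, n_high, n_low, hr, ci_low, ci_high, p_value)
#> # A tibble: 3 × 8
#>   stage cutoff n_high n_low    hr ci_low ci_high  p_value
#>   <int>  <dbl>  <int> <dbl> <dbl>  <dbl>   <dbl>    <dbl>
#> 1     1  0.351     20    20  3.55   1.58    7.96 2.14e- 3
#> 2     2  0.369     44    44  3.85   2.25    6.59 8.93e- 7
#> 3     3  0.346    100   100  5.39   3.69    7.88 3.00e-18
```

High-risk patients have a 3.6–5.4-fold hazard of disease-specific death
across the three stages, with confidence intervals excluding 1 — the
model's dichotomised output is prognostic on the simulated cohort, as it
should be since the cohort was generated with a real signal. Each stage's
cutoff differs because it is recomputed from the patients that stage
includes. `autoplot(kaplan_meier(...))`, `autoplot(fit)` and
`render_heatmap()` provide the standard visual outputs; see the methods
vignette (`vignettes/milsurv-methods.Rmd`) for the full model description,
design choices and limitations.

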