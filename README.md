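# fusesurv

Multimodal cross-attention fusion models for right-censored survival
prediction, in pure R.

## What this is for

In hormone receptor-positive, HER2-negative early breast cancer, several
routinely collected data sources carry complementary prognostic signal:
digitized pathology slides (patch-level deep features plus handcrafted
nuclear-morphology and cell-graph topology descriptors), preoperative
ultrasound (a deep feature map, a radiomics vector, an embedding of the
report text) and structured clinical variables. `fusesurv` is for
researchers who want to study how such feature streams should be *fused*
into a single recurrence-risk score: it implements a hierarchical
cross-attention fusion network trained end-to-end with the Cox partial
likelihood, a learnable compensation mechanism for missing modalities, a
synthetic multimodal cohort generator with planted proportional-hazards
risk, and the full survival evaluation battery (C-index, time-dependent
AUC, IPCW Brier and calibration, Kaplan–Meier / log-rank / hazard-ratio
stratification, bootstrap CIs, decision curves), plus cross-validation
and ablation harnesses.

## The model

Every stream is projected token-wise to a shared width *E*. Cross-attention
is scaled dot-product attention with learnable query/key/value/output maps,

    CA(Q, K) = softmax( (Q Wq)(K Wk)ᵀ / √d ) (K Wv) Wo ,

single-headed by default. Three stages compose the risk score:

1. **Intramodality:** the modality's query stream (pathology deep
   features; ultrasound deep features) attends in parallel to each of its
   other streams; outputs are element-wise summed with the query tokens
   (residual) and pooled → `F_path`, `F_us`.
2. **Intermodality:** `F_path` and `F_us` are affine-aligned and combined
   (concatenation by default; add / multiply / bidirectional single-token
   cross-attention as config options), with dropout 0.2 during training.
3. **Clinical residual:** the intermodal vector attends over per-variable
   clinical tokens; the output is added back residually, and the
   attention weights double as a variable-importance readout.

A single affine head yields the scalar log-relative-hazard; training
minimizes the Breslow-ties negative log Cox partial likelihood with Adam
(weight decay 4e-6). When a modality is flagged unavailable, its fused
vector is replaced through the availability mask by a learnable,
zero-initialized embedding trained jointly with the network.

Gradients come from a small reverse-mode autodiff tape over batched
arrays, written for this package and verified against finite differences
in the test suite.

## Worked example

```r
library(fusesurv)

cfg <- cohort_config(n_patients = 720, seed = 1,
                     signal_weights = c(pathology = 1.5, ultrasound = 0.5,
                                        clinical = 0.5))
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic multimodal survival cohort
#>   patients: 720   events: 117 (16.2%)
#>   streams:  wsi_deep, wsi_morph, wsi_top, us_deep, us_omic, us_text
#>   missing:  clinical=0, pathology=0, ultrasound=0

sp <- split_cohort(cohort, split_spec(seed = 1))   # stratified 5:1 -> 600/120
fit <- fusesurv(sp$train,
                fusion = fusion_config(embed_dim = 64),
                training = train_config(learning_rate = 1e-3, max_epochs = 60,
                                        early_stop_patience = 10,
                                        valid_fraction = 0.2, seed = 1))
fit
#> Multimodal cross-attention fusion survival model
#>   trained on 600 patients (97 events), 15 epochs
#>   embed_dim 64, heads 1, intermodal strategy "concat", dropout 0.20
#>   modalities: pathology, ultrasound, clinical
#>   final training loss (per event): 4.8719
#>   best validation C-index: 0.932 (epoch 5)

evaluate(fit, sp$test, horizons = c(12, 24, 36), n_boot = 500, seed = 1)
#> Survival evaluation report
#>   test patients: 120 (20 events)
#>   C-index: 0.837  [0.764, 0.902]  (bootstrap cv 4.3%)
#>   time-dependent AUC: 12m 0.864  24m 0.817  36m 0.856
#>   Brier: 12m 0.036  24m 0.076  36m 0.096
#>   high vs low HR: 12.96 [3.00, 55.91], log-rank p = 8.7e-06
```

The generator plants a known log-hazard (here pathology-dominant); the
held-out C-index of 0.837 sits near the planted risk's own information
ceiling (~0.85 under these weights), the high-vs-low groups split on the
*training* median score, and the hazard ratio / log-rank test quantify the
resulting stratification. `predict(fit, cohort)` returns risks,
`predict(fit, cohort, type = "survival")` Breslow-based survival
probabilities, `residuals(fit)` martingale residuals, and
`predict(fit, cohort, type = "fused", record_attention = TRUE)` the
per-stage representations and attention weights
(`attention_table()` exports them as a long table).

Ablation and robustness harnesses:

```r
run_ablation_grid(cohort, fusion_config(embed_dim = 32), train_config(seed = 1),
                  grid = list(full = list(),
                              drop_pathology = list(drop_modality = "pathology"),
                              swap_query = list(wsi_query = "morph")),
                  split = split_spec(seed = 1))
cross_validate(cohort, k = 5, repeats = 10)   # stratified, per-repeat means
```

Config-file driven runs (`run_simulate`, `run_train`, `run_evaluate`,
`run_ablate`) write delimited cohorts, checkpoints and JSON manifests; a
thin shell wrapper lives at `inst/scripts/fusion-cli.R`.

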