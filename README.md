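# agfn

Adaptive graph fusion networks for multi-outcome ICU risk prediction in R.

`agfn` predicts six binary intensive-care endpoints — in-hospital mortality,
sepsis, acute kidney injury, respiratory failure, cardiac arrest, prolonged
stay — from irregular clinical time series, for methodologists who need a
fully inspectable, leakage-safe reference implementation of graph-based
temporal risk modelling. The package is self-contained: a synthetic ICU
cohort generator reproduces the statistical structure the pipeline assumes
(sub-hourly vitals, informatively missing labs, correlated outcomes with
onset times, rare phenotypes), so every stage is testable without access to
any clinical database.

## The model

Patients are nodes of a similarity graph built in a learned, outcome-aligned
embedding space. A supervised contrastive objective

$$\mathcal{L} = -\frac{1}{N}\sum_i \frac{1}{|P(i)|} \sum_{p\in P(i)}
\log \frac{\exp(\mathrm{sim}(h_i,h_p)/\tau)}{\sum_{a\neq i}\exp(\mathrm{sim}(h_i,h_a)/\tau)}$$

pulls same-outcome patients together (one-vs-rest per endpoint,
inverse-prevalence weighted, τ = 0.1). Local embedding density
ρ<sub>i</sub>, estimated by a Gaussian KDE, sizes each patient's
neighborhood adaptively:

$$k_i = \min(k_{\max}, \max(1, \lfloor k_{\text{base}}\cdot\bar\rho/\rho_i \rfloor)),$$

so rare phenotypes in sparse regions get broader relational support while
dense clusters avoid redundant edges; edges carry Gaussian weights
exp(−‖h<sub>i</sub>−h<sub>j</sub>‖²/2σ²). Each patient's hourly sequence is
read twice: a gated short-term convolution (acute events, max-pooled) and a
long-term GRU whose extra gate mixes the previous hidden state with an
exponential moving average of earlier states (slow trends, stabilized
memory). Node representations are fused by multi-head attention restricted
to graph neighborhoods, softmax(QKᵀ/√d_k + log A)V, and a sigmoid head
emits six independent probabilities trained with summed binary
cross-entropy (AdamW, cosine annealing, gradient clipping, early stopping
on validation AUC).

Everything data-dependent — winsorization bounds, robust scaling, decay
imputation baselines, embeddings, densities, graph topology — is fitted on
the training partition of each cross-validation fold and frozen before any
held-out patient is touched; features recorded at or after an outcome's
onset are censored from the model's inputs. Interpretability comes from
gradient-based Shapley attribution (expected gradients with an exact
additivity guarantee) with seed/background stability auditing.

All trainable components run on a small reverse-mode automatic
differentiation engine included in the package and validated against
numerical gradients.

## A worked example

```r
library(agfn)

cohort <- simulate_cohort(sim_config(n_patients = 400, seed = 4))
labels <- outcome_labels(cohort, cohort$statics$patient_id)
plan   <- make_folds(labels, K = 5, seed = 2)

pts       <- cohort$statics$patient_id
test_ids  <- pts[plan$folds[[1]]]
val_ids   <- pts[plan$val[[1]]]
train_ids <- setdiff(pts, c(test_ids, val_ids))

res <- agfn_fold_run(cohort, train_ids, val_ids, test_ids,
                     fusion = fusion_config(hidden = 64, channels = 16,
                                            gru_hidden = 24, lr = 1e-3,
                                            max_epochs = 40, seed = 7),
                     boot_B = 200, seed = 3)
res$metrics
```

```
Per-outcome metrics:
         outcome threshold   auc auc_lower auc_upper auprc precision recall
1      mortality     0.500 0.911     0.826     0.971 0.502     1.000  0.125
2         sepsis     0.563 0.914     0.843     0.971 0.532     0.583  0.583
3            aki     0.151 0.949     0.890     0.990 0.844     0.667  0.889
4   resp_failure     0.171 0.930     0.869     0.978 0.704     0.609  0.933
5 cardiac_arrest     0.206 0.944     0.883     0.987 0.413     0.333  1.000
6 prolonged_stay     0.462 0.943     0.882     0.989 0.773     0.727  0.500
...
Mean: AUC 0.932 | AUPRC 0.628 | Brier 0.075
```

Each row is one endpoint evaluated on the held-out test fold: rank-based
ROC-AUC with a percentile-bootstrap 95% interval, area under the
precision–recall curve, and precision/recall/F1 at a decision threshold
selected on the internal validation subset (never on the test fold). The
Brier score and the calibration columns summarize probability reliability.

Attributions for the mortality head, pooled over time and patients:

```r
shap <- gradient_shap(res$model, res$tensors$train, patients = 1:20,
                      outcome = 1, background = res$tensors$train,
                      background_ids = 1:50, seed = 1)
head(sort(shap$global, decreasing = TRUE))
#>            age            ckd       sex_male            cvd           copd
#>        0.00670        0.00555        0.00227        0.00186        0.00153
#> rare_phenotype
#>        0.00124
```

On this synthetic cohort the static severity correlates (age, chronic
kidney disease) dominate mortality risk, which is exactly how the generator
was built; `temporal_contribution_map()` breaks per-patient attributions
into hyperacute (0–6 h), acute (6–24 h) and subacute (24–72 h) phases.

A thin command-line wrapper over these functions lives in
`inst/scripts/agfn.R` (`simulate`, `evaluate`, `explain`).

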