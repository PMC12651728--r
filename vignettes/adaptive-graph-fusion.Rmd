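---
title: "Adaptive graph fusion for multi-outcome ICU risk prediction: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive graph fusion for multi-outcome ICU risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agfn)
```

## The problem

Patients in intensive care generate irregular multivariate time series —
near-continuous vitals, sparsely ordered labs whose very ordering is
informative, static demographics and comorbidities — and face several
correlated adverse outcomes at once (death, sepsis, acute kidney injury,
respiratory failure, cardiac arrest, prolonged stay). Two structural facts
make this hard for conventional models. First, prognosis depends on both
acute fluctuations (a lactate spike over an hour) and slow drifts (creatinine
creeping up over days), which sit at different temporal scales. Second,
patients are not independent draws from one homogeneous population: rare
phenotypes live in sparse regions of feature space and a model that treats
every patient in isolation, or that wires a fixed-size neighborhood graph,
either isolates them or smooths them away.

`agfn` implements a pipeline that addresses both: outcome-aligned patient
embeddings define a similarity graph whose per-patient neighborhood size
adapts to local density, two temporal encoders read the sequences at short
and long horizons, and attention-based message passing over the graph fuses
individual dynamics with population context into six independent outcome
probabilities. Every data-dependent statistic is fitted inside a
cross-validation fold and frozen before it touches held-out patients.

## The model, stage by stage

### Preprocessing

Measurements are aligned to hourly bins over `[0, horizon)`; duplicates
within a bin are averaged. The grid width is our choice — sub-hourly vitals
need aggregation and no finer scale is warranted by the downstream encoders.
Per variable, the training partition supplies:

* **Winsorization bounds** at the 0.5th/99.5th percentiles, clipping
  measurement artifacts while keeping pathological-but-real extremes.
  Quantiles use linear interpolation between order statistics (type 7),
  stated explicitly because the unit tests depend on it.
* **Robust scaling** by the training median and IQR, which heavy-tailed labs
  need; a zero IQR maps the variable to 0 with a warning.

Missing bins are filled by decay-aware exponential smoothing,

$$\tilde x_t = m_t x_t + (1 - m_t)\,[\alpha \tilde x_{t-1} + (1-\alpha)\bar x],$$

with the observation mask $m_t$, the patient-specific baseline $\bar x$ (the
mean of that patient's observed pre-censoring values, falling back to the
training median when none exist), and decay $\alpha$. The first element's
predecessor is taken to be $\bar x$, so a series that starts missing decays
from the baseline; long gaps relax geometrically toward it. The package
defaults to $\alpha = 0.7$ — recent enough to track acute change, stable enough not to
chase noise — and exposes it in the configuration.

Two derived features expose rate-of-change information: the long-range slope
$(x_{t_n} - x_{t_1})/(t_n - t_1)$ over the observed pre-censoring window, and
stepwise differences $\Delta_t = x_t - x_{t-1}$. A slope needs two distinct
timepoints; with fewer the sentinel 0 is returned together with a
defined-flag, so downstream consumers see "no trend information" rather than
an arbitrary magnitude.

**Outcome-onset censoring.** For each patient, every bin whose interval
reaches the first onset among that patient's positive outcomes is masked and
excluded from imputation, baselines, slopes and deltas. Censoring at the
*earliest* onset is deliberately stronger than the per-outcome rule it
implements: masking everything from the first complication onward guarantees
that no feature recorded at or after *any* outcome's onset can reach the
model input for that patient–outcome pair, at the cost of discarding some
legitimately usable late data for later outcomes. With one joint multi-label
model this is the conservative resolution, and it keeps the leakage audit a
one-line mask check.

### Supervised contrastive embeddings

Raw feature distance is a poor notion of clinical similarity; two patients
can look alike in admission features and diverge completely in outcome. The
package therefore learns embeddings $h_i$ on the unit sphere with a
supervised contrastive objective,

$$\mathcal{L} = -\frac{1}{N}\sum_i \frac{1}{|P(i)|}\sum_{p \in P(i)}
\log \frac{\exp(\mathrm{sim}(h_i,h_p)/\tau)}
{\sum_{a \neq i} \exp(\mathrm{sim}(h_i,h_a)/\tau)},$$

where $\mathrm{sim}$ is cosine similarity and, per outcome in a one-vs-rest
scheme, $P(i)$ holds the other patients sharing patient $i$'s label. The six
one-vs-rest losses are summed; positive-class anchors of each outcome are
reweighted by its inverse prevalence so rare complications shape the space.
Anchors with empty $P(i)$ are skipped — the term is undefined there. The
temperature defaults to $\tau = 0.1$, the centre of the empirically stable
0.05–0.2 band. The encoder itself is a two-layer perceptron with a tanh
hidden layer and L2-normalized output — the smallest network that can warp
the feature space; nothing in the objective demands more capacity. Its inputs are the statics plus per-variable pre-censoring summaries
(mean, slope, last value, delta variability) — the graph must be built
before the temporal encoders are trained, so embeddings cannot consume
trained temporal features.

### Density-adaptive graph

Local density is estimated by a Gaussian-kernel KDE over the training
embeddings, $\rho_i = (N h^d)^{-1} \sum_j K(\lVert h_i - h_j\rVert / h)$,
with bandwidth $h = 0.25$ by default (the midpoint of the band in which
density estimates are neither unstable nor oversmoothed for unit-sphere
embeddings). Neighborhood sizes then scale inversely with relative density,

$$k_i = \min(k_{\max}, \max(1, \lfloor k_{\text{base}} \cdot \bar\rho / \rho_i \rfloor)),$$

with $k_{\text{base}} = 15$ and $k_{\max} = 30$. Flooring is the documented
rounding rule (conservative: fewer redundant edges), the lower bound of one
neighbor keeps every node connected, and anchoring at the cohort mean
density $\bar\rho$ keeps the population mean of $k_i$ near
$k_{\text{base}}$. Edges are directed ($i$ attends over its own neighbor
list, since symmetrization would destroy the per-node degrees) and weighted
by the Gaussian kernel $A(i,j) = \exp(-\lVert h_i - h_j\rVert^2 / 2\sigma^2)$.
The edge bandwidth $\sigma$ defaults to the median nearest-neighbor
distance of the training embeddings, the classic self-tuning choice. Raw weights are stored rather than row-normalized
because the attention softmax renormalizes anyway; they enter attention as
additive log-biases on the logits, which preserves both the Gaussian
similarity structure and the softmax normalization.

During training the graph is refreshed every 5 epochs (the cadence is a
free parameter):
$k_{\text{base}}$ anneals linearly from 5 to its target over the first 20%
of epochs to avoid degenerate early neighborhoods, and per-node degree
changes are clipped to $|\Delta k_i| \le 2$ between refreshes to prevent
abrupt topology shifts. Held-out patients attach to the frozen graph using
the training-fit $h$, $\bar\rho$ and $\sigma$, with neighbors drawn only
from training nodes — no edge from a held-out patient exists at training
time.

An optional density estimator (`density_method = "edge_mean"`) replaces the
KDE by the mean Gaussian edge weight to the $k_0$ nearest neighbors;
$k_0$ defaults to $k_{\text{base}}$.

### Dual-scale temporal encoders

The **short-term branch** is a gated 1-D convolution over windows of
$w$ hourly bins, $y_t = \sigma(W_g * X_{t:t+w}) \odot \phi(W_c * X_{t:t+w})$
with logistic gate and ReLU content, max-pooled over time — acute-event
detection semantics: the pooled channel fires if the pattern occurred
anywhere. The default window is $w = 6$ bins, matching the hyperacute 0–6 h
phase in which catastrophic outcomes concentrate.

The **long-term branch** is a GRU with an extra stabilizer gate fed by an
exponential moving average of earlier hidden states:

$$g_t = \sigma(W_g x_t + U_g[\beta h_{t-1} + (1-\beta)\,\mathrm{EMA}(h_{t-2})]),
\qquad h_t = (1 - z_t \odot g_t) \odot h_{t-1} + (z_t \odot g_t) \odot \tilde h_t.$$

Formulations of EMA-gated recurrences differ on whether the gate's memory
argument runs through $t-1$ or $t-2$; this implementation maintains the
running EMA through $t-2$ for the gate at $t$, so the gate only ever sees
states that were final before the previous update.
A single $\beta$ (default 0.9) serves both the EMA recursion
($\mathrm{EMA}_t = \beta h_t + (1-\beta)\mathrm{EMA}_{t-1}$,
$\mathrm{EMA}_0 = h_0 = 0$) and the gate mixing weight; one decay
factor is enough to control both memories. Because $z_t \odot g_t \in (0,1)$ elementwise, $h_t$
is a convex combination of $h_{t-1}$ and the tanh-bounded candidate — the
state cannot blow up, which the tests assert directly. The final state is
the long-term readout (trend semantics). Imputed values enter the encoders
with the observation mask appended as extra input channels, so the model
can distinguish measured values from imputations.

### Graph attention fusion and output

Node representations concatenate the pooled short-term features, the final
long-term state and the static vector, are projected to the hidden width,
and pass through two neighborhood-restricted multi-head attention layers
($\mathrm{softmax}(QK^\top/\sqrt{d_k} + \log A)V$ over each node's neighbor
list plus a self-loop, residual connections, ReLU, dropout). Self-loops are
added so a node's own temporal representation always contributes; attention
restricted strictly to neighbors would discard it. Two layers give two-hop
relational reach. The head is a fully connected layer with sigmoid
activation producing six *independent* probabilities — the endpoints are
multi-label, not mutually exclusive — which forces the training loss:
summed per-outcome binary cross-entropy.

Training uses AdamW with cosine learning-rate annealing and global-norm
gradient clipping at 1.0, early stopping on mean validation ROC-AUC with
patience 10. Validation patients are attached to the frozen graph and their
labels drive only the stopping decision, never a gradient (the tests verify
that poisoning validation labels leaves the loss trajectory bit-identical).
Defaults sit at the midpoints of the validated search ranges: 4 heads,
hidden 128, $d_k$ = hidden/heads, dropout 0.3, learning rate 3e-4.

All trainable stages run on a small reverse-mode automatic-differentiation
engine included in the package (matrix tape, fused recurrent step, gather /
scatter / grouped-softmax primitives), validated op-by-op against central
finite differences.

### Evaluation

Cross-validation is stratified at the patient level by iterative multi-label
stratification over the six outcomes (scarcest label first, each patient to
the fold with the greatest remaining demand); 10% of each fold's training
patients form an internal validation subset for early stopping and
threshold selection. ROC-AUC is the rank statistic with half credit for
ties — stated because tests pin it down — and the reported mean AUC is the
arithmetic mean of the six per-outcome AUCs. Decision thresholds are chosen
on the validation subset only, either F1-optimal or sensitivity-constrained
(≥ 0.92 for high-stakes screening). Calibration reports the Brier score,
a 10-bin equal-width reliability table, and slope / calibration-in-the-large
from a logistic recalibration of the outcome on the logit of the prediction
(the standard Cox-style recalibration; slope fixed at 1 for the offset fit).
Confidence intervals are percentile bootstrap over patients (1000 resamples
by default).

### Attribution

Feature attributions use expected gradients: for each sampled baseline
patient, the prediction gradient is integrated along the straight path from
baseline to the explained patient (deterministic trapezoid rule) and scaled
by the input difference, then averaged over baselines. Two implementation
decisions matter:

* **What is attributed.** The attributed function is the trained model's
  prediction for the patient with the graph topology *and* the neighborhood
  representations held at their observed values, so $\phi$ reflects the
  patient's own features only — sequence values per (bin, variable) plus
  statics; the observation mask is a constant of the function, and
  attributions are computed on the preprocessed (scaled, imputed) inputs the
  model actually consumes.
* **Efficiency by construction.** The trapezoid estimate of each path
  segment is adjusted, proportionally to attribution magnitude, so the
  segment sums telescope exactly to $f(z_{s+1}) - f(z_s)$. This absorbs the
  quadrature error that ReLU kinks introduce and makes the additivity
  property $\sum_j \phi_j = f(x) - E_b[f]$ hold to machine precision at any
  step count, instead of only in the many-steps limit. The exact
  coalition-enumeration oracle (feasible to 10 features) is what the
  estimator is audited against in the tests.

Global rankings pool mean $|\phi|$ over patients and time; the stability
audit recomputes them under 5 seeds and two background sizes (50 and 100
training patients) and reports pairwise Spearman correlations and the
coefficient of variation of the top features. Temporal contribution maps
sum $|\phi|$ per bin and summarize the hyperacute (0–6 h), acute (6–24 h)
and subacute (24–72 h) phases.

## What the synthetic cohort emulates — and what it does not

The generator (`simulate_cohort()`) is first-class, tested code, and its
defaults are the study conditions of every end-to-end check. Each patient
carries a latent severity process: an hourly AR(1) with coefficient 0.95
around a patient-specific baseline plus a slow drift, so both acute jumps
and gradual deterioration exist for the two encoders to find. Vitals
(default every 0.5 h, < 5% missing completely at random) and labs (default
every ~8 h with jitter) are noisy linear loadings on severity. Lab
observation probability increases with concurrent severity through a
logistic model whose intercept is calibrated so flagged labs exceed 40%
missingness and the rest sit near 20% — informative missingness of the kind
lactate or bilirubin show in practice. Each of six outcomes thresholds a
noisy copy of the severity trajectory; the threshold is calibrated by
quantile (with a bounded correction loop) to hit the target prevalence, and
onset is the first threshold crossing, so onsets exist exactly for positive
labels and the six labels are correlated through shared severity but not
identical. After a patient's first onset the *measured* severity ramps up
(deterioration after the complication), which is precisely the post-onset
signal outcome censoring must remove — and what the leakage-control
experiment measures. A rare-phenotype subpopulation (5%) draws statics,
baselines and loadings from a shifted distribution, creating the sparse
embedding region the density-adaptive graph is for. Default prevalences
(mortality 0.10, sepsis 0.15, AKI 0.22, respiratory failure 0.18, cardiac
arrest 0.06, prolonged stay 0.20) and demographics (age 63.4 ± 14.9, 54.7%
male) mirror a large multi-center ICU cohort.

What it does not emulate: pharmacokinetics and treatment feedback loops,
waveform-resolution signals, inter-variable lead–lag structure beyond the
shared severity factor, multi-site coding heterogeneity, and the outcome
correlation structure of any real cohort (the shared-factor
construction is a stand-in and is flagged as such).
Passing tests on this cohort therefore demonstrate that the pipeline's
machinery is correct and leakage-safe under realistic statistical structure
— not that real-data discrimination numbers would be reproduced.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen once as part of the study
conditions: the graph-adaptivity audit on the default cohort of 2000
patients; end-to-end training on 600 patients over 72 hourly bins with a
compact configuration (hidden 64, 16 convolution channels, recurrent state
24, learning rate 1e-3, at most 60 full-batch epochs with patience 10); the
leakage-control pair on 400 patients; the attribution audit on 20 patients
with 16 baselines and 8 path segments per baseline. Training is full-batch,
so "epoch" equals one optimizer step; the learning rate sits at the top of
the validated range because full-batch training takes far fewer steps per
epoch than the mini-batch regime the range was validated in.

Other numerical conventions, collected in one place: type-7 quantiles
everywhere; ties in ROC-AUC get half credit; the undefined slope sentinel is
0 with a flag; zero-IQR variables scale to 0 with a warning; the attention
softmax subtracts the per-neighborhood maximum before exponentiation;
probabilities are clamped away from 0/1 only inside the logistic
recalibration; all randomness flows through scoped, seeded generators that
restore the caller's RNG state.

## Known limitations

* Full-batch training bounds the cohort size at a few thousand patients;
  the approximate-nearest-neighbor and random-feature accelerations that
  would lift graph construction beyond that are deliberately out of scope.
* The contrastive encoder sees summary features, not learned temporal
  representations; embeddings and graph cannot react to what the temporal
  encoders later discover (the refresh machinery supports evolving
  embeddings, but within a fold the embedding space is frozen after stage
  two).
* Censoring at the earliest onset discards some usable late data for
  patients with multiple, well-separated complications.
* Attribution freezes the neighborhood context; indirect effects of a
  patient's features on its neighbors' representations are by design not
  part of $\phi$.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(sim_config(n_patients = 600, seed = 4))
labels <- outcome_labels(cohort, cohort$statics$patient_id)
plan <- make_folds(labels, K = 5, seed = 2)

pts <- cohort$statics$patient_id
test_ids <- pts[plan$folds[[1]]]
val_ids <- pts[plan$val[[1]]]
train_ids <- setdiff(pts, c(test_ids, val_ids))

res <- agfn_fold_run(cohort, train_ids, val_ids, test_ids,
                     fusion = fusion_config(hidden = 64, channels = 16,
                                            gru_hidden = 24, lr = 1e-3,
                                            max_epochs = 60, seed = 7),
                     boot_B = 200, seed = 3)
res$metrics

shap <- gradient_shap(res$model, res$tensors$train, patients = 1:20,
                      outcome = 1, background = res$tensors$train,
                      background_ids = 1:50, seed = 1)
head(sort(shap$global, decreasing = TRUE))
```
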