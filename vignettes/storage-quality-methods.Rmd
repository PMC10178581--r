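---
title: "Methods: forecasting and grading pesticide residue decay in stored wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting and grading pesticide residue decay in stored wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices behind
them: what is simulated and why, how the forecaster works, how quality is
graded, and what the test suite does and does not establish.

## The problem

Wheat is stored for months in sealed, dark silos. Residues of the field
pesticides dimethoate and chlorpyrifos and the storage protectant
chlorpyrifos-methyl degrade over that period, faster at higher temperature
and higher relative humidity. Daily monitoring gives, per silo condition, a
six-dimensional record: day, temperature, humidity, and the three residue
concentrations. Two analysis tasks follow: forecast each residue days
ahead, and convert concentrations plus forecasts into an ordered storage
quality grade.

## Synthetic monitoring data

Real silo monitoring data of this kind is not publicly deposited, so the
package ships a generator that reproduces the *structure* such analyses
assume, as first-class, tested code.

**Kinetic law.** Residue decay is modelled as first order,
$C(t) = C_0\,e^{-k\,t}$, with the rate constant modulated exponentially by
temperature and linearly by humidity around a reference condition
(25&nbsp;°C, 65&nbsp;% RH):

$$k(T, H) = k_0 \; e^{a (T - T_\mathrm{ref})} \, \big(1 + b (H - H_\mathrm{ref})\big).$$

This is the simplest law consistent with the qualitative observations the
generator must emulate: monotone decay, acceleration with temperature and
with humidity, temperature the stronger factor. The exponential temperature
modifier is the usual Arrhenius-style first-order correction; the humidity
modifier is linear because its effect is reported as real but weak. A
humidity modifier driven negative (far below reference with a large `b`) is
clamped to zero with a warning.

**Defaults.** Per-pesticide defaults (`default_pesticide_params()`) encode
the reported ordering: dimethoate ($C_0 = 0.05$ mg/kg, $k_0 = 0.020$/day,
$a = 0.06$/°C) and chlorpyrifos-methyl ($C_0 = 3.5$, $k_0 = 0.018$,
$a = 0.05$) decay fast and are strongly temperature-sensitive, chlorpyrifos
($C_0 = 0.35$, $k_0 = 0.006$, $a = 0.02$) decays slowly and responds weakly
to both drivers. Initial concentrations sit at the magnitudes of the
benchmark cluster centers (0.04 / 0.3 / 2–3 mg/kg). Humidity sensitivities
are 0.010/%RH (0.004 for chlorpyrifos). Noise is multiplicative Gaussian
with relative SD 0.05 — a typical assay relative error — and concentrations
are clipped at zero. The condition grid is the 3 × 3 crossing of
{10, 25, 35} °C and {54, 65, 75} % RH over 90 days.

**Split.** With $N$ records and ratios 7:2:1, counts follow
floor/round/remainder: $\lfloor 0.7N \rfloor$, $\mathrm{round}(0.2N)$,
remainder — the rule that partitions 2655 records into (1858, 531, 266).
The split is chronological within each series (earliest days to training)
because the task is temporal: a random split would leak future values into
training. A small epsilon guards the floor against binary-fraction
artefacts (`0.7 * 90` evaluates below 63).

**Residue limits.** Default maximum residue limits are 0.05 mg/kg
(dimethoate), 0.5 (chlorpyrifos), 5 (chlorpyrifos-methyl). The source
regulation list that motivated these defaults names chlorpyrifos twice at
0.05 and 0.5 mg/kg; the package maps 0.05 to dimethoate as the only
consistent reading, and treats this as an assumption, not a fact. A record
exactly at its limit is *not* flagged (strict inequality), matching the
convention that "below the limit" includes the boundary.

**What the generator does not emulate.** Silo spatial structure (layers and
sampling points), pest populations, CO₂, non-stationary temperature
schedules, assay drift, and the gap between the benchmark's 2655 records
and the grid's 3 × 9 × 90 = 2430 (the benchmark's composition is
unexplained; the generator exposes the count rather than forcing it).
Consequently, passing tests show the *methods* behave correctly on data
with the assumed kinetic structure — not that the models are accurate on
real monitoring data.

## Series decomposition

The decomposition block splits a length-$L$, $d$-channel sequence
additively: the trend is a centered moving average over an odd window, the
seasonal part is the residual, and reconstruction is exact by construction.
Padding replicates the edge values $(\text{kernel}-1)/2$ times on each
side, keeping length $L$ without injecting zeros that would bend the trend
at the boundaries. Channels are handled independently. The window length is
a hyperparameter (default 25, clipped to the largest odd window legal for
the shortest sequence the model sees); the mechanism's source architecture
never fixes it.

## The auto-correlation mechanism

Instead of dot-product attention, dependencies are discovered between
whole sub-series at lag offsets. For query and key sequences $Q, K$ the lag
scores are computed in the frequency domain via the Wiener–Khinchin
relation,

$$R(\tau) = \mathcal{F}^{-1}\!\big(\overline{\mathcal{F}(Q)}\,\mathcal{F}(K)\big)(\tau)
          = \sum_t Q_t K_{t+\tau \bmod L},$$

averaged over channels. The top $k = \lfloor c \ln L \rfloor$ lags are kept
(default $c = 1$; ties to the smaller lag; lag 0 eligible), their scores
softmax-normalized, and the value sequence aggregated as a weighted sum of
circularly rolled copies. The roll wraps rather than truncating: every
rolled copy then has the same per-channel mean, so aggregation preserves
it — an invariant the tests exploit. In cross mode (decoder attending to
encoder output) the key/value source is resampled to the query length by
truncation or zero-padding at the end. Lag scores are pooled across all
channels before selection, so a single shared lag set and weight vector is
used; this makes the `n_heads` setting a pure partition of the projections
with no effect on the result, and it is documented as such rather than
silently dropped.

## The forecaster

The encoder embeds the (standardized concentration, scaled temperature,
scaled humidity) channels by a linear value projection plus a sinusoidal
positional encoding. Each encoder layer applies self auto-correlation with
a residual connection, keeps the seasonal part of a decomposition, applies
a position-wise feed-forward (ReLU) with residual, and decomposes again,
discarding trends — the encoder models the seasonal signal only.

The decoder receives two initializations built from the trailing
`label_length` steps of the context: their seasonal part extended by
`horizon` zeros, and their trend part extended by `horizon` copies of the
context mean. Each decoder layer runs self auto-correlation, cross
auto-correlation against the encoder output, and a feed-forward, each
followed by a decomposition; the three trend parts are projected to the
value channel by learned per-layer weights and accumulated onto the trend
placeholder, while the seasonal branch continues. The prediction is the
projected seasonal output plus the accumulated trend on the last `horizon`
steps. With all trend projections zero the trend output equals the
placeholder exactly, and with all sub-layer output projections zero each
encoder layer collapses to repeated seasonal extraction — both degenerate
contracts are asserted in the tests.

**Training.** No deep-learning framework is assumed: the package carries a
small reverse-mode autodiff tape (nodes record a value and a backward
closure; creation order is the topological order), with every backward rule
— including the bilinear auto-correlation score and the rolled-copy
aggregation — validated against central finite differences through complete
forward passes of all four architectures. Optimization is Adam on
mean-squared error over sliding windows of `context_length + horizon` days
drawn from the training prefix of each series; windows are shuffled per
epoch with a seeded RNG, and initialization, batching and dropout all
derive from `config$seed`, making two fits bit-identical. Concentrations
are z-scored per series with train-split statistics only (scale leakage
from the future would otherwise flatter every model); temperature and
humidity enter through fixed affine scalings centred on the grid.
Validation loss is traced per epoch and optional early stopping restores
the best parameters.

**Baselines.** The RNN and LSTM encode the context with a single recurrent
layer and map the final hidden state linearly to the horizon (the LSTM's
forget-gate bias starts at 1, the standard trick to keep long-range state
trainable early). The Transformer uses the same embedding and width with
single-head scaled dot-product self-, cross- and feed-forward blocks and
residual connections, without layer normalization — at these widths it is
unnecessary and its omission keeps the autodiff surface small. The naive
forecaster repeats the last observation; it is the reference every learned
model must beat. Training protocols are per-model choices: default desk
scale uses 120 epochs at learning rate 0.01 (batch 8); the LSTM converges
slower and uses 150 epochs at 0.02.

**Problem sizes.** Package defaults are deliberately small (width 16, one
encoder and one decoder layer, context 24, horizon 7); the test fixtures
are smaller still (width 8, context 16, horizon 4, one pesticide, two grid
conditions, 60 days), sizes at which a full train-and-compare cycle of all
four architectures runs in about two minutes on one CPU. These are the
package's supported desk-scale conditions; nothing in the architecture caps
larger configurations.

## Error metrics

MAE, MSE, RMSE follow their standard formulas. MAPE and SMAPE are reported
as *decimals* (0.04681, not 4.681 %), matching the convention of the
benchmark tables this package mirrors, with a `percent` flag for display.
Points with a zero true value are excluded from MAPE with a warning and an
adjusted count, never imputed. SMAPE's default denominator is
$(|\hat d_i| + |d_i|)/2$; a printed variant with a minus sign in the
denominator exists in circulation but divides by ~0 whenever predictions
are accurate and cannot reproduce any published error table, so it is
implemented only as an explicit `smape = "literal"` audit mode.
Comparison tables store full-precision values and subtract them exactly;
CSVs are written at five decimals and round-trip losslessly at that
precision.

## Quality grading

For each day $i$ with a full context behind it, the quality index pairs the
observed concentration $d_i$ with $\bar d_i$, the mean of the model's
predictions for the next $n$ days (default $n = 7$, configurable; the index
source never states it). Days lacking a full forecast window are dropped
and counted.

Each pesticide's $(d_i, \bar d_i)$ table is clustered separately — the
benchmark's per-pesticide cluster sizes each sum to the full sample count,
implying independent 2-D clusterings rather than one 6-D clustering.
Clustering is K-means++: the first center uniform, subsequent centers drawn
with probability $D(x)^2 / \sum D(x)^2$ (distance to the nearest chosen
center), then Lloyd iterations to convergence with WCSS non-increasing by
construction; an emptied cluster is re-seeded at the point farthest from
its center. Distances are Euclidean in the raw mg/kg space — the benchmark
centers are reported unscaled, implying unstandardized clustering — and the
package runs 10 seeded restarts per $k$, keeping the lowest-WCSS fit.

The cluster count is selected over $k = 2,\dots,7$ (2 is included so that
"3 clusters" can be a discovery rather than an assumption) by maximizing
the silhouette coefficient; the Davies–Bouldin minimizer is reported
alongside and a disagreement is flagged, not resolved. Singleton clusters
take $a(i) = 0$ in the silhouette, the common convention. Finally clusters
are ordered by ascending observed-concentration center (ties by the
forecast coordinate): Level 1 — lowest residue — is the best storage
quality.

On smooth synthetic decay the quality table has no strong planted
structure, and silhouette selection tends to small $k$; the
planted-structure tests therefore use explicit Gaussian blobs to verify
recovery, and the pipeline reports whatever the criteria actually choose.

## Numerical and degenerate-input choices

* Moving-average windows must be odd (a centered window has no center
  otherwise) and at most $2L - 1$.
* Additive reconstruction of the decomposition is exact up to one ulp
  (`(x - t) + t` in floating point); tests assert it at $10^{-15}$ relative
  tolerance.
* Lag-selection ties break toward the smaller lag, making selection
  deterministic.
* `split_counts` errors when a split would be empty rather than silently
  returning zeros.
* Coincident cluster centers make the Davies–Bouldin ratio undefined and
  raise an error naming the pair.
* All stage seeds derive from one global seed through a documented
  stage-name hash (`derive_seed`), so any stage can be reproduced alone.

## Known limitations

The generator's kinetics are stationary and noise is i.i.d.; real silo
series show regime changes (aeration, fumigation) and correlated assay
error. The forecaster is univariate per series — the three pesticides are
modelled independently, matching the per-pesticide grading, and no joint
multivariate head is provided. Training at desk scale demonstrates
learnability and correct gradients, not state-of-the-art accuracy; no
hyperparameter search is performed. The quality grade is relative to the
fitted clustering: levels are ordinal within a dataset, not absolute
regulatory categories.
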