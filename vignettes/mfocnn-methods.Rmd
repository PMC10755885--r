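---
title: "Moth-flame optimized 1D-CNNs for EEG seizure classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moth-flame optimized 1D-CNNs for EEG seizure classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-channel EEG can distinguish healthy, interictal (between
seizures) and ictal (during seizure) brain states, but convolutional
classifiers for this task are sensitive to half a dozen architectural
and training hyperparameters that are usually hand-tuned.  `mfocnn`
automates that tuning: a moth-flame optimization (MFO) metaheuristic
searches a six-dimensional mixed discrete-continuous space of CNN
hyperparameters, scoring each candidate by the validation cross-entropy
of a short training run, and the winning configuration is then trained
at full budget with best-validation checkpointing.

The reference data layout is the Bonn University corpus: five subsets
(A/B healthy with eyes open/closed, C/D interictal from different
recording sites, E ictal), each holding 100 single-channel segments of
4,097 samples at 173.61 Hz.  A defining physical feature is amplitude:
ictal voltages exceed 1,000 µV while the other classes live near the
100 µV scale.  The package never downloads anything; it reads the
corpus layout if present (`load_subsets()`) and otherwise generates a
synthetic stand-in with the same geometry (`generate_corpus()`).

## Windowing

Long segments are cut into non-overlapping one-second chunks
(`window_segment()`, `build_windowed_dataset()`).  The chunk length is
178 samples — the input length the network consumes — so each 4,097
sample segment yields exactly `floor(4097/178) = 23` chunks and the
five-subset corpus yields 11,500 labeled rows.  One second at
173.61 Hz is nominally ~174 samples; we follow the network's exhibited
input shape (178) and discard the 3-sample remainder of each segment.
Chunks inherit the label of their source subset (A→0 … E→4).

Splits (`split_dataset()`, `kfold_indices()`) are stratified by class
and seeded.  By default the split granularity is the chunk, so chunks
of one source segment may land on both sides; `by_segment = TRUE`
assigns whole segments to one side for leakage-free evaluation.  The
chunk-level default matches the common practice for this corpus;
segment-level numbers are systematically lower and should be preferred
when estimating clinical generalization.

## The search space

The tuned vector is `[delta, s, a, d, log10(eta), m]`:

| dimension | kind | range | decoded meaning |
|---|---|---|---|
| `n_kernels` (delta) | integer | 40–100 | first-block conv filters |
| `kernel_size` (s) | integer | 1–20 | conv taps |
| `activation` (a) | categorical | {0,1,2} | ReLU / sigmoid / tanh |
| `dropout` (d) | continuous | 0–0.6 | dropout probability |
| `log10_eta` | log-continuous | [-5, 0) | Adam learning rate 10^x |
| `pool_size` (m) | integer | 2–20 | max-pool window |

The optimizer works in a continuous box; `decode_position()` clips,
rounds the integer dimensions half away from zero (banker's rounding
would make .5 boundaries platform-dependent), rounds the categorical
coordinate to a code, and exponentiates the learning-rate coordinate.
The learning rate is searched in log10 space because its admissible
range spans four decades; a linear parameterization would concentrate
nearly all random mass above 0.1.  Published hyperparameter tables
print dropout as an integer index; `report_row()` renders
`round(10*d)` alongside the continuous value for comparison.

## The network

`build_model_spec()` constructs `n_blocks` (default 6) repetitions of
conv → batch-norm → dropout → max-pool, then flatten → dense softmax:
26 layers at the defaults.  Per-block filter counts follow
`delta, delta-10, delta-15, delta-20, delta-25, delta-30`, clamped at
1 — the linear generalization of the single exhibited instance
(50, 40, 35, 30, 25, 20); the decrement rule is a design choice, not a
published formula.  Convolutions use length-preserving (same) padding
and pooling uses ceiling-length output: both conventions are forced by
the exhibited shape table, where 178-length inputs stay 178 through
convolutions and pooling maps 45 → 23 and 23 → 12 (floor would give 22
and 11).  `infer_shapes()` implements this arithmetic natively and is
cross-checked, layer for layer, against the actual activation
dimensions reported by the compiled engine (`model_shapes()`).

## The training engine

No deep-learning framework is a dependency: the package ships a
compact double-precision 1D-CNN engine (Rcpp/RcppArmadillo) that
implements same-padded convolution via im2col and BLAS matrix
products, batch normalization, inverted dropout, ceiling-mode max
pooling, a dense softmax head, and Adam (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁷).  Weights are Glorot-uniform, drawn — like shuffling and
dropout masks — from one 64-bit Mersenne Twister per call, so a fixed
seed gives bit-identical training on a fixed platform.  Two numerical
choices matter on small datasets:

- batch-norm running statistics use momentum 0.9 (a ~10-step window)
  rather than the common 0.99, because with few minibatches per epoch
  the inference-mode statistics must track quickly-moving weights or
  validation metrics lag training by several epochs;
- cross-entropy clamps predicted probabilities at 10⁻¹², so a
  confidently wrong model yields a large finite loss instead of
  infinity, and a run whose loss becomes non-finite aborts with its
  history preserved.

Inputs are standardized by the global training mean and standard
deviation (one scalar pair, stored with the model).  This preserves
the between-class amplitude ordering — the ictal class's defining
feature — while keeping first-layer activations in a trainable range.

`train_model()` checkpoints after every epoch: the returned model is
the snapshot with the highest validation accuracy, never the last
epoch.  The training data supplies the validation set; when none is
given, a stratified 10% of the training portion is carved out, giving
an overall 72% train / 8% validation / 20% test partition.

## Fitness for the optimizer

Training every candidate at full budget inside the metaheuristic
(hundreds of trainings × hundreds of epochs) is neither stated in
enough detail to reproduce nor desk-feasible, so the objective is a
deliberately short proxy: `evaluate_fitness()` trains for
`search_epochs` (default 10) with small batches and returns the final
validation cross-entropy.  The budget is configurable up to the full
schedule.  Scores are cached on the *decoded* vector, so
rounding-equivalent positions never retrain, and a candidate whose
architecture cannot be built or whose training diverges scores `+Inf`.

## The optimizer

`run_mfo()` is a from-scratch MFO: per iteration it evaluates the
population, merges moths into the sorted flame set (keeping the best
`flame_count(t, T, N) = round(N - t(N-1)/T)` records, clamped ≥ 1, so
the flame set shrinks linearly to a single incumbent), then moves each
moth along a logarithmic spiral `D e^{bt} cos(2πt) + F` with `t`
drawn uniformly on [-1, 1] per coordinate, clipping to bounds.
Choices on points the original formulation leaves open:

- `D` is the coordinate-wise *absolute* distance, matching the
  canonical algorithm; the signed variant is available via
  `signed_distance = TRUE` but is asymmetric in a way no analysis
  supports.
- Moth `i` pairs with flame `i` (index pairing), moths beyond the
  flame count with the last kept flame.  "Nearest-flame" pairing is
  sometimes described but never defined; index pairing is the standard
  scheme.
- The spiral constant `b` has no published value; the default is 1.
- Fitness merging pools moths with previous flames, so the best
  solution can never be lost (elitism) and the trace's best fitness is
  non-increasing by construction.

Population 20 and 30 iterations are the published defaults for this
application; the pipeline scales both down for desk-scale runs.

## The synthetic corpus

`generate_corpus()` emulates the corpus geometry with
phenomenological recipes: AR(1)-colored background noise plus an
alpha-band (8–13 Hz) rhythm for A/B (stronger in B, emulating eyes
closed), Poisson-timed biphasic sharp transients for C/D (rate 0.6/s
vs 2.2/s), and a high-amplitude 3–7 Hz oscillation for E whose peaks
exceed 1,000 µV — the one amplitude fact the reference corpus
documentation states.  Samples are quantized to integer microvolts so
the ASCII export (`export_corpus()`) round-trips losslessly through
`load_subsets()`.

A `separability` knob linearly interpolates every recipe toward the
class-A background: at 1 (default) the classes carry their full
structure; at 0 all five classes are statistically identical and any
classifier must fall to chance.  This gives the test suite both a
positive control (an easy corpus a small CNN must learn) and a
negative control (a no-signal corpus it must *not* appear to learn).
The recipes are not biophysical: they carry class-discriminative
band-power, transient and amplitude structure with the right
dimensions, nothing more.  Passing on them shows the pipeline's
machinery works end to end; it does not certify clinical performance
on real EEG, which has inter-subject variability, artifacts and
non-stationarity the generator does not model.

## Problem sizes used by the test suite

The suite and acceptance checks run at deliberately small scales,
chosen as the package's own desk-scale study conditions: windowing
arithmetic is verified on the full 5 × 100 × 4,097 grid (cheap); the
learnability control uses 10 segments per class (1,150 chunks), an
optimizer budget of 5 moths × 5 iterations × 3 search-epochs, and a
20-epoch final training with batch 32; reproducibility uses 2
segments per class with a 2 × 2 × 1 budget.  Full-scale runs (100
segments, 20 × 30 × 10, 256/500 final) use the same code paths and
the `default_run_config()` values.

## Known limitations

- The per-candidate fitness budget is a proxy; a configuration that
  trains well in 3–10 epochs is favored over a slow starter that would
  win at 500.
- Chunk-level splitting (the default, matching common practice on this
  corpus) lets chunks of one segment straddle the split; use
  `by_segment = TRUE` for leakage-free estimates.
- The engine is single-threaded CPU code; it is sized for the
  178-sample, ≤100-filter regime, not for large-scale deep learning.
- Bit-level reproducibility holds for a fixed platform/BLAS; across
  BLAS implementations results agree only to floating-point
  reassociation.
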