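# mmgmotion

Estimating human joint rotational acceleration from wearable muscle
signals, in R.

A skin-mounted accelerometer over a contracting muscle records three
superimposed processes: the gross limb motion ("pseudo-acceleration",
< 10 Hz), the muscle's own mechanical vibration (mechanomyography, MMG,
10–50 Hz), and wideband sensor noise. `mmgmotion` isolates the MMG,
conditions it together with surface electromyography (sEMG), and learns a
sequence model that maps the fused muscle envelopes to the joint's
3-axis rotational acceleration (rad/s²). It is aimed at researchers in
wearable sensing and neuromuscular signal processing who want a fully
inspectable, CPU-only reference implementation of this stack.

## What is inside

* **DE-VMD extraction** — variational mode decomposition
  (frequency-domain ADMM with Wiener-filter mode updates, compiled core)
  whose mode count `K` and bandwidth penalty `α` are tuned per channel by
  differential evolution (`DE/rand/1/bin`) minimizing the envelope entropy
  `E_e = −Σ e_j lg e_j`, `e_j = a(j)/Σ a(j)`, of the sparsest mode
  (`a` = Hilbert envelope, `lg` = log₁₀). IMFs are then labeled
  pseudo-acceleration / MMG / noise by the energy centroid of their
  marginal Hilbert spectrum and summed per label.
* **EMD baseline** — classical sifting with spline extrema envelopes, for
  method comparison.
* **Six-stage conditioning** — DC removal, 10–450 Hz zero-phase
  Butterworth bandpass, full-wave rectification, 5 Hz linear envelope,
  min–max normalization.
* **Windowing** — 1000 ms windows at 200 ms increments, summarized into
  length-20 sequences of 8 features (4 MMG + 4 sEMG envelopes) with
  aligned length-20 target sequences and leakage-free block splits.
* **Estimators** — an encoder-only transformer
  (`softmax(QKᵀ/√d_k)V` attention, sinusoidal position embedding,
  padding masks, residual + layer norm, flatten-and-project head; 2 heads,
  1 layer, batch 64 by default) with single-layer RNN and LSTM baselines,
  trained by Adam on MSE with hand-derived, numerically verified
  gradients; evaluation reports per-trial R² as highest/lowest/mean.
* **Synthetic recordings** — a seeded generator of multimodal trials
  (raw 3-axis accelerations, sEMG, joint-acceleration targets) with exact
  ground truth for every stage, used by the test suite in place of human
  recordings.

## Worked example

```r
library(mmgmotion)

# 1. decompose a two-tone signal (2 Hz + 30 Hz, 4 s at 1000 Hz)
t <- seq_len(4000) / 1000
x <- sin(2 * pi * 2 * t) + sin(2 * pi * 30 * t)
dec <- vmd_decompose(x, rate_hz = 1000, vmd_config(K = 2, alpha = 2000))
dec
#> <decomposition_result: vmd> 2 IMF(s) x 4000 samples, 8 iter(s), converged=TRUE
#>   center freqs (Hz): 1.93, 29.99

# 2. extract MMG from a synthetic raw-acceleration channel
sr <- assemble_recording(synthetic_config(duration_s = 20, seed = 42))
ch <- sr$ground_truth$primary_axis[1]
ex <- extract_mmg(sr$recording$raw_accel$samples[ch, ], 1000,
                  de_config(pop_size = 12, generations = 12,
                            patience = 5, seed = 42),
                  tune_seconds = 4, fitness_max_iter = 100)
ex
#> <extraction_result> K=8, alpha=10000.0 | labels: PSEUDO_ACCELERATION, MMG,
#>   NOISE, NOISE, NOISE, NOISE, NOISE, NOISE
cor(ex$mmg, sr$ground_truth$mmg[ch, ])
#> [1] 0.955
```

The decomposition recovers the tone frequencies to within 0.1 Hz, and the
DE-tuned extraction reconstructs the (known, synthetic) muscle vibration
with correlation 0.95 against ground truth — the low-frequency IMF is the
limb motion, one mid-band IMF carries the MMG, and the high-centroid IMFs
are rejected as noise.

The full experiment — simulate a session, extract, condition, window,
train and evaluate all models — is one call:

```r
session <- simulate_session(n_trials = 5, base_seed = 1, duration_s = 60)
res <- run_experiment(session, models = c("transformer", "rnn"),
                      signal_modes = c("fusion", "mmg_only"), seed = 1)
res            # per-model highest/lowest/mean R^2 across trials
glance(res)    # the same as a tibble
```

`autoplot()` methods exist for traces, decompositions, fitness traces,
training histories and evaluation reports; `tidy()`/`glance()` methods
cover fitted estimators, extractions and reports.

A thin command-line tool wraps the same functions
(`inst/cli/mmgmotion.R`): `mmgmotion simulate|extract|preprocess|train|
evaluate --config cfg.yaml [--seed N] [--out DIR]`, each subcommand
writing its artifacts plus a JSON run summary.

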