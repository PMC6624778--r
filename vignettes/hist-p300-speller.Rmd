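---
title: "Decoding a P300 speller from gradient-orientation histograms of signal plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a P300 speller from gradient-orientation histograms of signal plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300hist)
```

## The model

The P300 is a positive EEG deflection about 300 ms after a rare, attended
stimulus. In a 6×6 speller, rows (locations 1–6) and columns (7–12) flash in
random 12-permutations; the attended character's row and column flashes carry
the P300, whose raw amplitude (~5 µV) sits roughly 15 dB below background
EEG. The package decodes letters from the *shape* of the averaged waveform:
each averaged location signal is rendered as a small binary line plot, that
plot is summarised by a 128-dimensional histogram of pixel-gradient
orientations (a SIFT-style descriptor without keypoint detection, orientation
assignment, or Gaussian weighting), and a k-nearest variant of the
Naive-Bayes-Nearest-Neighbor rule matches the 12 location descriptors of a
trial against calibration templates. The row and column with the smallest
accumulated distance identify the letter.

This chain assumes (i) the P300 shape is reasonably stable within a subject,
(ii) averaging `k_a` time-locked epochs raises its SNR by roughly
`sqrt(k_a)`, and (iii) standardizing the averaged trace before plotting makes
the rendered shape insensitive to overall amplitude and to how many epochs
survived averaging.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `gamma` | 4 | px per sample (and per σ/γ step) | plot magnification; 1 px = 1/4 µV vertically, 1/64 s horizontally at 16 Hz |
| `s` | 3 | blocks of 3·s px | patch of 12·s = 36 px covers 9 µV × 0.56 s, one whole P300 transient |
| `k` | 7 | neighbours | k-NBNN accumulation depth |
| `k_a` | 10 | sequences | epochs averaged per trial |
| `t_max` | 1 | s | epoch length from flash onset |
| `target_fs` | 16 | Hz | working rate after decimation; 16 samples/epoch |
| `artifact_uV` | 70 | µV | sequence rejection threshold |
| `notch_hz` | 50 | Hz | mains removal (set 0 to disable) |
| `metric` | cosine | — | template distance; descriptors are sparse, and cosine distance separates them better than squared Euclidean (available via `metric = "sqeuclidean"`) |

The patch-scale identities are exposed by `patch_scale()`: with γ = 4, a
0.56 s span at 16 Hz and a 9 µV amplitude both give the integer scale s = 3.
The fixed keypoint sits at pixel column `floor(0.55 · target_fs · gamma)` =
35 — just past the expected P300 peak, so the 36-px patch straddles the
transient — on the image row of the signal's zero line.

## Design choices where the design was open

* **Filter chain and causality.** Notch → 10 Hz lowpass Butterworth (order
  4) → order-30 FIR decimation to 16 Hz, all causal (forward-only), since an
  online speller cannot filter acausally. The mains frequency is not
  intrinsic to the method; we default to 50 Hz with a Q = 30 RBJ biquad
  (r-signal provides no notch designer, so the 5-line biquad is computed
  in-package). The FIR taps are normalized to unity DC gain. For rates that
  are not integer multiples of 16 Hz (e.g. 250 Hz), the equivalent rational
  polyphase resampling (8/125) is used instead of integer decimation.
* **Artifact rejection on the enhanced signal.** The ±70 µV scan runs after
  filtering/decimation, matching the pipeline order in which it is applied;
  whole sequences are dropped, never single epochs. When sequences are
  rejected, the ensemble average divides by the number of survivors.
* **Plot geometry.** Ordinates map to rows screen-style: larger ordinate =
  lower on screen, so a positive deflection plots downward. Only
  calibration/query consistency matters, and the convention is fixed. The
  canvas is tight to the ordinate range plus one black pixel of padding per
  side, so finite differences at extreme pixels have support; `z1 = γ·n`
  leaves γ−1 empty columns between samples that Bresenham (classic integer
  8-connected midpoint variant) fills. The vertical offset formula is applied
  literally, including its degenerate value for constant signals — which
  never arises because constant signals are rejected earlier as degenerate.
* **Descriptor conventions.** Gradient angles are measured from the +x
  (column) axis with +y pointing down, mapped to [0, 360)°. The histogram
  index is `8·(4·i + j) + θ/45` with block row `i` and block column `j` —
  row-major, top-left origin. The leading 3·s factor of the accumulation is
  kept literally (it cancels under normalization but preserves the printed
  identity, which the oracle tests check). Spatial and angular weights are
  the bilinear/linear interpolation weights with centres at ±1/2, ±3/2 block
  units and the three-term circular wrap; pixels whose spatial weights all
  vanish are skipped — mathematically identical, measurably faster.
* **Descriptor normalization.** A raw orientation histogram is nonnegative,
  so "normalize to [−1, 1]" is realised as division by the maximum absolute
  entry, landing in [0, 1]; the zero descriptor maps to itself and the
  operation is idempotent. Unit-L2 normalization was considered and rejected
  as the default because max-abs keeps the sparsity pattern interpretable;
  the cosine metric is scale-invariant anyway.
* **k-NBNN details.** Row and column templates share one pool per channel
  (the decision compares each query against the whole template set).
  Although the matching rule is written with a squared norm, the distance
  actually used is the cosine distance, which performs better on these
  sparse descriptors; squared Euclidean remains available for ablation.
  Argmin ties break to the lowest location index. The best performing
  channel is chosen by leave-one-trial-out recognition within the
  calibration set — self-templates are excluded, otherwise every channel
  would match itself perfectly.
* **Indexing.** Sample indices are 1-based (R convention) throughout the
  data model; pixel coordinates are 0-based (`pixels[y + 1, x + 1]`) so the
  printed keypoint column 35 is literal.

## What the simulator emulates — and what it does not

`simulate_session()` generates: random 12-permutation flash schedules at the
0.125 s flash / 0.125 s ISI cadence, `k_a` sequences per letter with an
inter-trial pause; per-channel background noise, pink (1/f-amplitude shaped)
by default because basal EEG is low-frequency dominated — which stresses the
10 Hz lowpass far more realistically than white noise (also available); and,
on the responsive channels (default Cz, Pz), a positive half-sine bump of
400 ms span peaking 300 ms (± 20 ms uniform jitter) after every target
flash. Overlapping bumps from consecutive target flashes (SOA 250 ms < span
400 ms) add linearly. Defaults are 8 channels at 256 Hz with the standard
montage, 5 µV peak on 28 µV noise — the ≈ −15 dB regime quoted for real
recordings (`snr_db()` reports the nominal value).

It does **not** model: volume conduction or inter-channel correlation
(channels are independent noise plus an identical bump), eye-blink/EMG
artifacts (only optional amplitude spikes for testing rejection),
trial-to-trial shape variability of the P300 beyond latency jitter,
habituation, or alpha rhythms. Consequently, passing end-to-end tests shows
the pipeline is *correct* (it recovers exactly the structure it is told is
there), not that it attains any particular recognition rate on real
patients. Notably, at the −15 dB default with single-channel templates the
synthetic task is close to chance — real P300 decoding at that nominal SNR
succeeds partly because real background EEG is more structured (and hence
more filterable) than pink noise; the end-to-end validation therefore uses a
high-SNR condition (8 µV on 4 µV noise) where recovery must be nearly
perfect, and separate statistical checks at amplitude 0 where it must drop
to the 1/36 chance level.

## Numerical choices and degenerate inputs

Event onsets are the first sample of a run of equal nonzero stimulus codes;
epoch windows are half-open `[onset, onset + n_max)`; rate conversion maps
onsets by `floor`. Constant (zero-variance) averaged signals cannot be
standardized and raise a degenerate-signal error, which calibration converts
into a skipped template (with a warning) and decoding into an `NA`-letter
trial rather than an abort; the CRR counts such trials as errors. If fewer
templates than `k` exist, `k` is truncated with a warning. All randomness
flows through explicit seeds; identical seeds give bit-identical sessions,
and the session CSV serializer round-trips samples (readr's shortest
round-trip doubles, parsed back with base R's correctly rounded reader) and
the event list exactly.

## Validation problem sizes

The test suite validates the descriptor against a literal per-pixel
brute-force evaluation on 100 random 36×36 gradient fields (agreement to
1e-9 relative), the partition-of-unity identity of the trilinear weights,
ensemble averaging against a naive loop plus the ≈1/`k_a` variance
shrinkage over 200 replicates, five-letter word recovery at high SNR,
chance-level behaviour over 500 zero-amplitude trials against the binomial
99 % interval around 1/36, and the improvement of CRR from `k_a` = 1 to 10
on a 60-trial ensemble at intermediate SNR (5 µV on 15 µV noise — chosen
where single-sequence decoding is hard but averaging visibly helps). These
sizes keep the whole suite under a minute while leaving the statistical
checks well-powered.

## Known limitations

Single fixed keypoint and single-channel decision (multichannel fusion of
descriptors is explicitly out of scope); no dynamic stopping or language
model; no ICA/regression artifact correction; the public ALS dataset adapter
is a stub that reports an explicit unsupported-format error since no MATLAB
container reader is available to this build — the native CSV path is the
supported interchange format.
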