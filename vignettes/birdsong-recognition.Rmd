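---
title: "Birdsong recognition for centralized acoustic sensor networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birdsong recognition for centralized acoustic sensor networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A wireless acoustic sensor network (WASN) for wildlife monitoring streams
audio from simple microphone nodes to one central processing platform, which
must decide — in real time and for every node — which bird species is
singing. `wasnbird` implements the full recognition computation for such a
centralized deployment, built around the detection of the common bittern
(*Botaurus stellaris*), an endangered heron whose male booming call is
narrowband around 150 Hz, among 19 cohabiting wetland species whose calls
reach up to 15 kHz. Alongside the recognizer, the package implements the
analytic deployment budget that determines whether the computation fits a
given FPGA platform and how many sensors it can serve in real time.

## The recognition chain

Audio at 48 kHz is cut into 30 ms frames (1440 samples) advanced by 50%
overlap (720-sample hop). Because field recordings are mostly silence or
background, a corpus-level energy gate keeps only the 35% highest-energy
frames of each file (energy = sum of squared samples, computed on raw,
unwindowed frames) and discards the rest; `ceiling(0.35 R)` frames are kept,
ties going to the earlier frame so the rule is deterministic.

Retained frames are Hamming-windowed (symmetric convention,
`0.54 - 0.46 cos(2 pi n/(L-1))`, endpoints 0.08), zero-padded to a 2048-point
transform, and reduced to a one-sided power spectrum. A 48-filter triangular
bank integrates the spectrum: filter centers are spaced *linearly* from
20 Hz to 1 kHz and on the Mel scale (`mel(f) = 2595 log10(1 + f/700)`) from
1 kHz to 16 kHz, with each triangle spanning the previous to the next center
(50% overlap). The number of linear-band filters is the number of Mel-spaced
centers that would fall at or below 1 kHz (14 of the 50 node frequencies at
the defaults). The natural log of each filter output (floored at 1e-12 so
digital silence stays finite) is followed by an orthonormal DCT-II, and the
first 13 coefficients — c0 included — form the frame's MFCC vector. Higher
coefficients are discarded: the low-order cepstrum carries the spectral
envelope that separates these calls.

Two readings of the band-allocation rule are defensible (how many of the 48
filters sit below 1 kHz is ambiguous); the hybrid linear/Mel bank above is
the default, and a pure Mel bank is available by setting
`split_freq <= fmin`. Likewise the energy gate could be applied before or
after overlap framing; it is applied to the overlapped frame sequence, as
corpus pre-processing upstream of windowing, and `mfcc_config()` exposes the
fraction (or `NULL` to disable).

## The classifier

One Gaussian mixture model per species: `P_i(x) = sum_k w_k N(x; mu_k,
Sigma_k)` with `M = 32` full-covariance components in `d = 13` dimensions,
and classification of a frame is the argmax of the mixture log-likelihood
over the `n = 20` models (ties, which have measure zero in floating point,
go to the lowest species index). Full rather than diagonal covariance is
deliberate: the deployment cost model counts `n M (d^2 + d + 1)`
multiplications per frame, a d-by-d Mahalanobis product per component, and
the classifier mirrors that structure. `|Sigma_k|` and `Sigma_k^{-1}` are
computed once at training time and cached in the model object; scoring a
frame never refactorizes a covariance, and a model whose caches are missing
raises an error rather than silently recomputing.

Training is k-means-initialized expectation-maximization:

* **k-means**: k-means++ seeding under a fixed seed (default 0), Lloyd
  iterations, and empty clusters reseeded at the point farthest from its
  assigned center. Determinism here makes every downstream fit reproducible.
* **EM**: means/covariances/weights initialized from the cluster means,
  per-cluster scatter plus `reg I`, and cluster fractions. Each M-step adds
  `reg = 1e-6` to the covariance diagonal — a guard against collapse on
  sparse classes whose perturbation of the log-likelihood is orders below
  the convergence tolerance. Scoring is done in the log domain with
  log-sum-exp; the linear-domain mixture density underflows at `d = 13`,
  while the argmax is unchanged. EM stops when the relative log-likelihood
  gain falls below `tol = 1e-6` or at `max_iter = 200`; the full
  log-likelihood trace is recorded so the ascent property is *asserted* on
  every run, not assumed. A component whose covariance loses positive
  definiteness despite the ridge aborts the fit naming the component; a
  component starved of responsibility is reseeded at the worst-explained
  point.

The EM inner loop is implemented in C++ (RcppArmadillo), with both the
E-step and the M-step arranged as one large matrix product per iteration
rather than M small ones; at `d = 13` this keeps the BLAS efficient and
makes the full cross-validation run tractable on one CPU.

## Evaluation protocol

`make_folds()` builds stratified 10-fold assignments: within every class,
fold sizes differ by at most one. The default `frame` mode stratifies
individual frames — training on 90% of the audio frames and testing on the
rest, which is the protocol the recognizer is specified against — but frames
of one clip then appear on both sides of the split, so a `clip` mode that
assigns whole clips to folds is provided as the sounder alternative for
real data. `run_cv()` fits all per-species models per fold, classifies the
held-out frames, and pools confusion counts; row percentages are kept
unrounded internally and rounded to two decimals only at presentation.
Accuracy from the pooled matrix diagonal and accuracy recomputed from raw
predictions are both exposed, and the test suite checks they agree.

## The synthetic corpus

No recording collection ships with the package; `corpus_spec()` +
`generate_corpus()` synthesize one with the statistical structure the
recognizer assumes. Four call archetypes cover the qualitative contrast of
the target soundscape: `tonal_boom` (narrowband low tone with slow vibrato —
the bittern surrogate at 150 Hz, bandwidth 50 Hz), `harmonic_stack` (a
dominant tone with weak upper harmonics), `chirp_train` (repeated 90 ms
sweeps across the species band), and `broadband_clatter`
(amplitude-modulated band-shaped noise). The default table holds the bittern
surrogate plus 19 species spread geometrically over 300 Hz–15 kHz.

Each 10 s clip places calls at the species' repetition period over additive
white Gaussian noise scaled to the requested SNR (default 20 dB, measured as
call power over noise power); half of each clip is guaranteed call-free
(`silence_fraction = 0.5`), silence being true digital silence plus the
noise floor so the energy gate has a well-defined target. Thirty clips per
species is the default corpus shape. The call archetypes' duty cycles are
chosen so calls occupy roughly half of each clip, which means the 35% gate
retains essentially call frames. Defaults the source protocol does not pin —
SNR, silence fraction, call durations — were fixed once at values a field
bioacoustician would call a clean but realistic recording, and are
configurable.

Determinism is structural: every clip's samples derive from a per-clip seed
computed from the corpus seed and the clip's position, so identical specs
give byte-identical WAV files, and the streaming feature path
(`corpus_mfcc()`, which never holds the full audio in memory) reproduces the
on-disk corpus exactly.

What the generator does *not* emulate: syllable grammars and song variation,
reverberation and propagation over the species' 2 km audible range,
overlapping singers, and non-stationary background. Passing the
cross-validation surface on this corpus therefore demonstrates that the
pipeline is implemented correctly and separates spectrally distinct sources
at moderate SNR — not that it would reach the same accuracy on field
recordings, where the published experience with comparable systems is
per-class accuracies in the 82–92% range.

## The deployment budget

The budget module reproduces the deployment arithmetic analytically.
Per-frame operation counts of the GMM stage follow the three closed-form
counts above (225,920 operations at n=20, M=32, d=13); system throughput is
`ops x sensors / hop`, giving 451,840,000 FLOPS at 30 sensors and a 15 ms
hop. Real-time capacity is `floor(hop / latency)` with latency
`cycles / clock` — 49,156 cycles at 100 MHz is 491.56 microseconds per
frame, commonly quoted as 500 microseconds; capacity is computed from the
exact cycle count (the result, 30 sensors, is the same either way). Resource
fit divides the packaged IP's requirements (31 DSP, 73 BRAM, 4489 LUT,
7677 FF) by each device's capacity; the Zynq-7000 catalog ships as package
data. Per-component resource rows are also shipped, but they come from
blocks implemented separately for inspection and do not sum to the packaged
total — that is a property of the data, not an arithmetic error, and fit
computations use the total row. Percentages are rounded half-even to two
decimals; one published cell (121.66% block RAM on the XC7Z010) reflects
final-digit truncation of 121.67 and is tolerated at ±0.01.

## Numerical choices and test scale

* Log floor 1e-12 before the filter-bank log; covariance ridge 1e-6;
  log-sum-exp for all mixture sums.
* The 2048-point transform is zero-padded from 1440 samples; a power of two
  matching the reference hardware's FIFO depth.
* The test suite verifies the spectrum and DCT stages against direct
  quadratic-time oracles (tolerances 1e-8 and 1e-10 on 100 random frames),
  EM parameter recovery on seeded draws (means within 3 standard errors,
  covariance within 10% Frobenius at 5000 samples, mixture weights within
  0.05), and Monte-Carlo normalization of a two-dimensional mixture within
  1%.
* The acceptance surface runs the *full* default corpus — 600 clips, ten
  seconds each, about 140,000 retained frames — through frame-level 10-fold
  cross-validation with all defaults, asserting mean per-class accuracy at
  or above 0.90 with the bittern surrogate at or above the class median.
  Unit tests use a four-species, two-second variant of the same generator,
  which keeps them interactive while exercising every archetype.

## Limitations

Frame-level decisions only: no clip-level aggregation, no temporal modelling
(a hidden Markov layer is the natural extension for the bittern's repetitive
boom), no delta features or cepstral mean normalization, and no fixed-point
emulation of the reference hardware datapath. The corpus generator's realism
limits are listed above; conclusions about field performance require field
recordings.
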