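# wasnbird

Birdsong recognition and deployment budgeting for centralized wireless
acoustic sensor networks (WASN).

A centralized WASN streams raw audio from simple microphone nodes to one
processing platform that must identify, in real time, which bird species is
singing at each node. `wasnbird` implements that recognition computation
end to end for a wetland monitoring scenario targeting the endangered common
bittern (*Botaurus stellaris*) — a narrowband booming caller around 150 Hz —
among 19 cohabiting species with calls up to 15 kHz, together with the
analytic budget that says whether the computation fits a given FPGA platform
and how many sensors it can serve.

The pipeline:

1. **Audio frontend** — 30 ms frames (1440 samples at 48 kHz), 50% overlap;
   the 35% highest-energy frames of each file are kept as birdsong, the rest
   discarded.
2. **MFCC features** — Hamming window, 2048-point power spectrum, 48
   triangular filters (centers linear 20 Hz–1 kHz, Mel-spaced to 16 kHz),
   log energies, DCT-II, first 13 coefficients per frame.
3. **Classifier** — one Gaussian mixture model per species,
   `P_i(x) = Σ_k w_k N(x; μ_k, Σ_k)` with M = 32 full-covariance components
   in d = 13 dimensions, trained by k-means-initialized EM with `|Σ_k|` and
   `Σ_k⁻¹` cached for scoring; a frame is assigned to
   `argmax_i log P_i(x)`.
4. **Evaluation** — stratified 10-fold cross-validation, per-class fold
   accuracies and a row-percentage confusion matrix.
5. **Deployment budget** — per-frame operation counts
   (`n·M·d` subtractions, `n·M·(d²+d+1)` multiplications,
   `n·M·((d−1)²+d)` additions), system FLOPS, real-time sensor capacity
   `floor(hop / latency)`, and resource-fit percentages for the Zynq-7000
   device family.

Because no recording collection ships with the package, a seeded synthetic
corpus generator (`corpus_spec()`, `generate_corpus()`) produces labelled
multi-species audio with the structure the recognizer assumes: per-species
call archetypes with distinct spectral envelopes, silence gaps, and white
noise at a prescribed SNR. See the methods vignette
(`vignettes/birdsong-recognition.Rmd`) for the model, its assumptions, and
what the synthetic corpus does and does not demonstrate.

## Worked example

```r
library(wasnbird)

# Deployment budget at the reference operating point
print(budget_report())
#> <budget_report>
#>   per-frame ops: 8320 sub + 117120 mul + 100480 add = 225920
#>   hop 15.0 ms, frame latency 491.56 us -> capacity 30 sensors
#>   system load at 30 sensors: 451,840,000 FLOPS
#>   XC7Z020 fit: DSP 14.09%, BRAM 52.14%, LUT 8.44%, FF 7.22% (fits)
```

Scoring 20 species models of 32 Gaussians on a 13-dimensional frame costs
225,920 floating-point operations; with a new frame every 15 ms from each of
30 sensors that is 451.84 MFLOPS, and the feature-extraction engine
(49,156 cycles per frame at 100 MHz) keeps exactly 30 sensors real-time.
The packaged IP uses about half the block RAM and under a sixth of every
other resource of a mid-range XC7Z020 device.

A desk-scale recognition run — four species, four 4-second clips each:

```r
cs <- corpus_spec(default_species_table()[c(1, 8, 14, 20)],
                  clip_duration = 4, clips_per_species = 4, seed = 42)
dat <- corpus_mfcc(cs)                       # gate + MFCC, streaming
plan <- make_folds(dat$labels, k = 4, seed = 42)
cv <- run_cv(dat$features, dat$labels, plan, gmm_config(M = 4))
print(cv)
#> <cv_report> 4-fold (frame mode), 1488 test frames
#>   overall accuracy: 0.9785
#>   mean per-class accuracy: 0.9785 (range 0.9570-1.0000)
round(cv$mean_accuracy, 3)
#>  bittern_surrogate  species_08_1105hz  species_14_4072hz species_20_15000hz
#>              0.995              0.957              1.000              0.962
```

`cv$row_percent` holds the confusion matrix as row percentages (actual
classes on rows): 99.46% of bittern-surrogate frames are recognized
correctly here, with the residual confusion between the two broadband
species.

A command-line wrapper with `synth`, `extract`, `train`, `classify`,
`evaluate` and `budget` subcommands is installed at
`system.file("cli", "wasnbird.R", package = "wasnbird")`.

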