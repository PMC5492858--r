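test_that("power spectrum matches the transform eigenfunction and zero cases", {
  nfft <- 2048; rate <- 48000
  k <- 100
  x <- cos(2 * pi * k * (0:(nfft - 1)) / nfft)
  ps <- power_spectrum(x, nfft, rate)
  expect_equal(which.max(ps$values) - 1, k)
  expect_equal(ps$values[k + 1], (nfft / 2)^2, tolerance = 1e-9)
  expect_true(all(power_spectrum(numeric(1440))$values == 0))
  expect_equal(length(ps$values), nfft / 2 + 1)
  expect_error(power_spectrum(numeric(4096), nfft = 2048), "exceeds")
})

test_that("power spectrum agrees with a direct O(n^2) DFT", {
  set.seed(21)
  nfft <- 256
  for (i in 1:5) {
    x <- rnorm(200)
    fast <- power_spectrum(x, nfft)$values
    slow <- naive_dft_power(x, nfft)
    expect_lt(max(abs(fast - slow)) / max(slow), 1e-8)
  }
})

test_that("filter bank geometry: 48 hybrid filters from 20 Hz to 16 kHz", {
  bank <- build_filterbank()
  expect_equal(bank$n_filters, 48)
  expect_equal(nrow(bank$weights), 48)
  expect_equal(ncol(bank$weights), 1025)
  expect_gte(min(bank$center_freqs), 20)
  expect_lte(max(bank$center_freqs), 16000)
  expect_true(all(diff(bank$center_freqs) > 0))
  expect_true(all(bank$weights >= 0))
  expect_true(all(rowSums(bank$weights) > 0))
  # centers below the split are linearly spaced, above it Mel-spaced
  low <- bank$center_freqs[bank$center_freqs < 1000]
  expect_gt(length(low), 3)
  expect_equal(diff(low), rep(diff(low)[1], length(low) - 1), tolerance = 1e-9)
  high <- bank$center_freqs[bank$center_freqs > 1000]
  mel_steps <- diff(hz_to_mel(high))
  expect_equal(mel_steps, rep(mel_steps[1], length(mel_steps)),
               tolerance = 1e-6)
  # each filter responds unimodally along frequency
  for (i in seq(1, 48, by = 7)) {
    w <- bank$weights[i, ]
    peak <- which.max(w)
    expect_true(all(diff(w[1:peak]) >= 0))
    expect_true(all(diff(w[peak:length(w)]) <= 0))
  }
  expect_error(build_filterbank(fmax = 30000, rate = 48000), "Nyquist")
})

test_that("degenerate and toy banks match hand-computed triangle areas", {
  one <- build_filterbank(n_filters = 1, fmin = 100, split_freq = 50,
                          fmax = 10000, nfft = 2048, rate = 48000)
  expect_equal(nrow(one$weights), 1)
  expect_gt(sum(one$weights), 0)

  # 3-filter toy bank on a flat spectrum: outputs equal the triangle areas
  toy <- build_filterbank(n_filters = 3, fmin = 1000, split_freq = 0,
                          fmax = 9000, nfft = 2048, rate = 48000)
  flat <- structure(list(values = rep(1, 1025), nfft = 2048, rate = 48000,
                         bin_hz = 48000 / 2048), class = "spectrum_frame")
  got <- as.vector(toy$weights %*% flat$values)
  bin_freqs <- (0:1024) * 48000 / 2048
  nodes <- mel_to_hz(seq(hz_to_mel(1000), hz_to_mel(9000), length.out = 5))
  expected <- vapply(1:3, function(i) {
    l <- nodes[i]; c0 <- nodes[i + 1]; r <- nodes[i + 2]
    sum(pmax(0, pmin((bin_freqs - l) / (c0 - l), (r - bin_freqs) / (r - c0))))
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("log energies floor silence and scale with amplitude", {
  bank <- build_filterbank()
  silent <- power_spectrum(numeric(1440))
  expect_equal(log_energies(silent, bank), rep(log(1e-12), 48))

  t <- (0:1439) / 48000
  tone <- sin(2 * pi * bank$center_freqs[30] * t) *
    wasnbird:::hamming_window(1440)
  le <- log_energies(power_spectrum(tone), bank)
  expect_equal(which.max(le), 30)

  le2 <- log_energies(power_spectrum(2 * tone), bank)
  expect_equal(le2 - le, rep(log(4), 48), tolerance = 1e-9)

  wrong <- build_filterbank(nfft = 1024)
  expect_error(log_energies(power_spectrum(tone), wrong), "nfft")
})

test_that("DCT stage matches its definition and a direct oracle", {
  const <- dct_cepstra(rep(3, 48))
  expect_equal(const[1], 3 * sqrt(48))
  expect_equal(const[-1], rep(0, 12), tolerance = 1e-12)

  # one full period across the filters concentrates in coefficient index 3
  osc <- cos(pi * (2 * (0:47) + 1) / 48)
  cep <- dct_cepstra(osc)
  expect_equal(which.max(abs(cep)), 3)
  expect_lt(sum(cep[-3]^2) / cep[3]^2, 1e-20)

  set.seed(31)
  for (i in 1:5) {
    le <- rnorm(48)
    expect_lt(max(abs(dct_cepstra(le) - naive_dct2(le, 13))), 1e-10)
  }
  expect_error(dct_cepstra(rnorm(10), n_coeffs = 13), "exceeds")
})

test_that("full extraction yields one 13-vector per retained frame", {
  set.seed(41)
  clip <- audio_clip(rnorm(48000, sd = 0.1), 48000)
  feats <- extract_mfcc(clip)
  expect_equal(dim(feats$vectors), c(65, 13))
  expect_true(all(is.finite(feats$vectors)))
  expect_identical(feats$vectors, extract_mfcc(clip)$vectors)

  gated <- extract_mfcc(clip, mfcc_config(energy_fraction = 0.35))
  expect_equal(nrow(gated$vectors), ceiling(0.35 * 65))
})

test_that("amplitude scaling shifts only the zeroth cepstral coefficient", {
  set.seed(43)
  clip <- audio_clip(rnorm(48000, sd = 0.05), 48000)
  f1 <- extract_mfcc(clip)$vectors
  f2 <- extract_mfcc(audio_clip(3 * clip$samples, 48000))$vectors
  expect_equal(f2[, 2:13], f1[, 2:13], tolerance = 1e-8)
  expect_equal(f2[, 1] - f1[, 1], rep(2 * log(3) * sqrt(48), 65),
               tolerance = 1e-8)
})

test_that("distinct call archetypes separate in mean MFCC space", {
  boom <- generate_call(tiny_species()[[1]], seed = 2)
  chirp <- generate_call(tiny_species()[[3]], seed = 2)
  mb <- colMeans(extract_mfcc(boom)$vectors)
  mc <- colMeans(extract_mfcc(chirp)$vectors)
  expect_gt(sqrt(sum((mb - mc)^2)), 1)
  # low-order shape coefficients carry most of the contrast
  expect_gt(max(abs(mb - mc)[2:7]), max(abs(mb - mc)[8:13]))
})
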