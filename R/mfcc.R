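#' MFCC extraction configuration
#'
#' Defaults follow the recognizer's reference chain: 30 ms frames with 50%
#' overlap (1440 samples at 48 kHz), a 2048-point transform, a 48-filter bank
#' spanning 20 Hz to 16 kHz with centers linearly spaced up to `split_freq`
#' (1 kHz) and Mel-spaced above it, and the first 13 DCT coefficients.
#'
#' @param frame_ms Frame duration (ms).
#' @param overlap Fractional frame overlap.
#' @param nfft Transform length (frames are zero-padded up to it).
#' @param n_filters Number of filters in the bank.
#' @param fmin,split_freq,fmax Band edges in Hz; centers are linear on
#'   `[fmin, split_freq]` and Mel-spaced on `(split_freq, fmax]`. Setting
#'   `split_freq <= fmin` selects a pure Mel-spaced bank.
#' @param n_coeffs Number of cepstral coefficients kept (counting c0).
#' @param energy_fraction If non-`NULL`, fraction of highest-energy frames
#'   retained before feature extraction (the corpus pre-processing gate).
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_ms = 30, overlap = 0.5, nfft = 2048,
                        n_filters = 48, fmin = 20, split_freq = 1000,
                        fmax = 16000, n_coeffs = 13, energy_fraction = NULL) {
  cfg <- list(frame_ms = frame_ms, overlap = overlap, nfft = nfft,
              n_filters = n_filters, fmin = fmin, split_freq = split_freq,
              fmax = fmax, n_coeffs = n_coeffs,
              energy_fraction = energy_fraction)
  class(cfg) <- "mfcc_config"
  cfg
}

#' One-sided power spectrum of a windowed frame
#'
#' Zero-pads the frame to `nfft` samples, applies the discrete Fourier
#' transform and returns the squared magnitudes of bins `0..nfft/2`.
#'
#' @param frame Numeric vector (a single windowed frame) of length
#'   `<= nfft`.
#' @param nfft Transform length (default 2048).
#' @param rate Sampling rate in Hz (default 48000), carried for bin spacing.
#' @return A `spectrum_frame`: list with `values` (length `nfft/2 + 1`),
#'   `nfft`, `rate` and `bin_hz`.
#' @export
power_spectrum <- function(frame, nfft = 2048, rate = 48000) {
  frame <- as.numeric(frame)
  if (length(frame) > nfft)
    stop("frame of length ", length(frame), " exceeds nfft = ", nfft)
  padded <- c(frame, numeric(nfft - length(frame)))
  X <- fft(padded)
  values <- Mod(X[seq_len(nfft / 2 + 1)])^2
  structure(list(values = values, nfft = nfft, rate = rate,
                 bin_hz = rate / nfft),
            class = "spectrum_frame")
}

# Batch version: frames as rows; returns R x (nfft/2 + 1) power matrix.
power_spectrum_matrix <- function(frames, nfft = 2048) {
  R <- nrow(frames)
  padded <- matrix(0, nrow = nfft, ncol = R)
  padded[seq_len(ncol(frames)), ] <- t(frames)
  X <- mvfft(padded)
  t(Mod(X[seq_len(nfft / 2 + 1), , drop = FALSE])^2)
}

#' Mel-scale conversions
#'
#' `hz_to_mel(f) = 2595 log10(1 + f/700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return Converted values.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Node frequencies (filter edges/centers): n_filters + 2 points; linear on
# [fmin, split_freq] for as many nodes as a pure Mel spacing would place
# there, Mel-spaced above. Triangle i spans nodes i, i+1, i+2.
filterbank_nodes <- function(n_filters, fmin, split_freq, fmax) {
  n_nodes <- n_filters + 2L
  mel_nodes <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                             length.out = n_nodes))
  if (split_freq <= fmin) return(mel_nodes)  # pure Mel bank
  n_low <- sum(mel_nodes <= split_freq)
  if (n_low < 2L) n_low <- 2L
  if (n_low > n_nodes - 1L) n_low <- n_nodes - 1L
  low <- seq(fmin, split_freq, length.out = n_low)
  high <- mel_to_hz(seq(hz_to_mel(split_freq), hz_to_mel(fmax),
                        length.out = n_nodes - n_low + 1L))
  c(low, high[-1])
}

#' Build the triangular filter bank
#'
#' Constructs `n_filters` triangular filters on the one-sided spectrum grid.
#' Center frequencies are linearly spaced from `fmin` to `split_freq` for the
#' low-band share (the number of Mel-spaced centers that would fall at or
#' below `split_freq`) and Mel-spaced from `split_freq` to `fmax` for the
#' rest; adjacent triangles overlap 50% (each spans the previous to the next
#' center).
#'
#' @inheritParams mfcc_config
#' @param nfft Transform length the bank is sampled on.
#' @param rate Sampling rate in Hz.
#' @return A `mel_filterbank`: list with `weights` (`n_filters x (nfft/2+1)`
#'   matrix), `center_freqs`, `n_filters`, `nfft`, `rate` and the band edges.
#' @export
build_filterbank <- function(n_filters = 48, fmin = 20, split_freq = 1000,
                             fmax = 16000, nfft = 2048, rate = 48000) {
  if (fmax > rate / 2)
    stop("fmax = ", fmax, " Hz exceeds the Nyquist frequency ", rate / 2, " Hz")
  if (!(fmin < fmax)) stop("fmin must be below fmax")
  if (split_freq > fmin && !(split_freq < fmax))
    stop("split_freq must lie below fmax")
  nodes <- filterbank_nodes(n_filters, fmin, split_freq, fmax)
  if (any(diff(nodes) <= 0))
    stop("filter node frequencies are not strictly increasing; ",
         "reduce n_filters or widen the band")
  bin_freqs <- (0:(nfft / 2)) * rate / nfft
  W <- matrix(0, nrow = n_filters, ncol = nfft / 2 + 1)
  for (i in seq_len(n_filters)) {
    l <- nodes[i]; c0 <- nodes[i + 1]; r <- nodes[i + 2]
    up <- (bin_freqs - l) / (c0 - l)
    down <- (r - bin_freqs) / (r - c0)
    W[i, ] <- pmax(0, pmin(up, down))
  }
  structure(list(weights = W, center_freqs = nodes[2:(n_filters + 1)],
                 n_filters = n_filters, nfft = nfft, rate = rate,
                 fmin = fmin, split_freq = split_freq, fmax = fmax),
            class = "mel_filterbank")
}

#' Log filter-bank energies
#'
#' `LE(i) = ln(max(w_i . spectrum, floor))` with `floor = 1e-12`; the floor
#' keeps digital-silence frames finite.
#'
#' @param spec A `spectrum_frame` from [power_spectrum()].
#' @param bank A `mel_filterbank` built for the same `nfft` and `rate`.
#' @param floor Lower bound applied before the logarithm.
#' @return Numeric vector of length `bank$n_filters`.
#' @export
log_energies <- function(spec, bank, floor = 1e-12) {
  stopifnot(inherits(spec, "spectrum_frame"), inherits(bank, "mel_filterbank"))
  if (spec$nfft != bank$nfft || spec$rate != bank$rate)
    stop("filter bank built for nfft=", bank$nfft, "/rate=", bank$rate,
         " but spectrum has nfft=", spec$nfft, "/rate=", spec$rate)
  log(pmax(as.vector(bank$weights %*% spec$values), floor))
}

# Orthonormal DCT-II matrix, n_coeffs x n.
dct_matrix <- function(n_coeffs, n) {
  k <- 0:(n_coeffs - 1)
  i <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * i + 1) / (2 * n))
  D[1, ] <- sqrt(1 / n)
  D
}

#' Cepstral coefficients by DCT-II
#'
#' Orthonormal DCT-II of the log energies, keeping the first `n_coeffs`
#' coefficients (c0 included); the high-order coefficients are discarded.
#'
#' @param le Log-energy vector (length = number of filters).
#' @param n_coeffs Number of leading coefficients to keep (default 13).
#' @return Numeric vector of length `n_coeffs`.
#' @export
dct_cepstra <- function(le, n_coeffs = 13) {
  le <- as.numeric(le)
  if (n_coeffs > length(le))
    stop("n_coeffs = ", n_coeffs, " exceeds the number of filters ", length(le))
  as.vector(dct_matrix(n_coeffs, length(le)) %*% le)
}

#' Construct a feature matrix
#'
#' @param vectors R x d numeric matrix of per-frame cepstral vectors.
#' @param frame_times Frame start offsets in seconds.
#' @param label Optional species label.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(vectors, frame_times = NULL, label = NULL) {
  vectors <- as.matrix(vectors)
  if (any(!is.finite(vectors))) stop("feature matrix contains non-finite entries")
  structure(list(vectors = vectors, frame_times = frame_times, label = label,
                 d = ncol(vectors)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d coefficients%s\n",
              nrow(x$vectors), x$d,
              if (is.null(x$label)) "" else paste0("  [", x$label, "]")))
  invisible(x)
}

#' Extract MFCC features from a clip or frame matrix
#'
#' Runs the full chain: framing (if given a clip), optional high-energy frame
#' selection, Hamming windowing, power spectrum, log filter-bank energies and
#' DCT, producing one `n_coeffs`-dimensional vector per retained frame.
#'
#' @param x An [audio_clip()] or an unwindowed `frame_matrix`.
#' @param config An [mfcc_config()].
#' @param bank Optional pre-built filter bank (rebuilt from `config`
#'   otherwise); passing one avoids rebuilding it per clip in batch runs.
#' @return A [feature_matrix()] (zero rows if the input holds no full frame).
#' @export
extract_mfcc <- function(x, config = mfcc_config(), bank = NULL) {
  if (inherits(x, "audio_clip")) {
    label <- x$label
    fm <- frame_signal(x, frame_ms = config$frame_ms, overlap = config$overlap)
  } else if (inherits(x, "frame_matrix")) {
    label <- NULL
    fm <- x
  } else stop("x must be an audio_clip or frame_matrix")
  if (isTRUE(fm$windowed))
    stop("extract_mfcc expects unwindowed frames (the energy gate precedes windowing)")
  if (is.null(bank))
    bank <- build_filterbank(config$n_filters, config$fmin, config$split_freq,
                             config$fmax, config$nfft, fm$rate)
  keep <- if (!is.null(config$energy_fraction))
    select_high_energy_frames(fm, config$energy_fraction)
  else seq_len(nrow(fm$frames))
  if (length(keep) == 0L)
    return(feature_matrix(matrix(numeric(0), 0, config$n_coeffs),
                          frame_times = numeric(0), label = label))
  frames <- fm$frames[keep, , drop = FALSE]
  frames <- sweep(frames, 2, hamming_window(fm$frame_length), `*`)
  P <- power_spectrum_matrix(frames, config$nfft)          # R x bins
  LE <- log(pmax(P %*% t(bank$weights), 1e-12))            # R x n_filters
  D <- dct_matrix(config$n_coeffs, config$n_filters)
  feature_matrix(LE %*% t(D), frame_times = fm$frame_times[keep], label = label)
}
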