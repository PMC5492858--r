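# Desk-size fixtures built in code at test time.

tiny_species <- function() list(
  species_spec("bittern_surrogate", "tonal_boom", 150, 50, 0.6, 1.2, 0.8),
  species_spec("mid_harmonic", "harmonic_stack", 2000, 300, 0.5, 1.0, 0.7),
  species_spec("high_chirper", "chirp_train", 8000, 1200, 0.5, 1.0, 0.7),
  species_spec("clatterer", "broadband_clatter", 4000, 800, 0.5, 1.0, 0.7))

tiny_corpus_spec <- function(clips = 3, clip_duration = 2, snr_db = 25,
                             seed = 7)
  corpus_spec(tiny_species(), clip_duration = clip_duration,
              clips_per_species = clips, snr_db = snr_db,
              silence_fraction = 0.4, seed = seed)

# Two well-separated Gaussian point clouds in d dimensions.
two_clouds <- function(R = 400, d = 3, sep = 10, seed = 11) {
  set.seed(seed)
  rbind(matrix(rnorm(R / 2 * d), ncol = d),
        matrix(rnorm(R / 2 * d, mean = sep), ncol = d))
}

random_spd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) + diag(d)
}

# Minimal stereo 16-bit WAV writer used only to exercise the channel check.
write_stereo_wav <- function(path, left, right, rate = 48000) {
  pcm <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  path
}
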