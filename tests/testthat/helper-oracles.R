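# Independent brute-force references the fast implementations are checked
# against. These deliberately avoid fft()/matrix tricks: direct O(n^2) sums.

naive_dft_power <- function(x, nfft, rate = 48000) {
  x <- c(x, numeric(nfft - length(x)))
  n <- 0:(nfft - 1)
  vals <- vapply(0:(nfft / 2), function(k) {
    re <- sum(x * cos(-2 * pi * k * n / nfft))
    im <- sum(x * sin(-2 * pi * k * n / nfft))
    re^2 + im^2
  }, numeric(1))
  vals
}

naive_dct2 <- function(le, n_coeffs) {
  N <- length(le)
  vapply(0:(n_coeffs - 1), function(k) {
    s <- sum(le * cos(pi * (2 * (0:(N - 1)) + 1) * k / (2 * N)))
    if (k == 0) s * sqrt(1 / N) else s * sqrt(2 / N)
  }, numeric(1))
}

# Gaussian log density that refactorizes the covariance on every call.
naive_mvn_logpdf <- function(x, mu, sigma) {
  d <- length(x)
  z <- x - mu
  -d / 2 * log(2 * pi) -
    0.5 * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) -
    0.5 * as.numeric(t(z) %*% solve(sigma) %*% z)
}

spectral_centroid <- function(clip, nfft = 8192) {
  n <- min(length(clip$samples), nfft)
  p <- naive_or_fft_power(clip$samples[seq_len(n)], nfft)
  freqs <- (0:(nfft / 2)) * clip$rate / nfft
  sum(freqs * p) / sum(p)
}

naive_or_fft_power <- function(x, nfft) {
  x <- c(x, numeric(nfft - length(x)))
  Mod(stats::fft(x)[seq_len(nfft / 2 + 1)])^2
}
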