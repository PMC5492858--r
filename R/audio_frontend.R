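#' Construct an audio clip
#'
#' A labelled mono sample sequence at a fixed rate: the unit of corpus
#' storage, holding the raw signal fed to the analysis chain.
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param rate Sampling rate in Hz (default 48000).
#' @param label Optional species label.
#' @param source_path Optional provenance path.
#' @return An object of class `audio_clip` with fields `samples`, `rate`,
#'   `label`, `source_path` and `duration_s`.
#' @export
audio_clip <- function(samples, rate = 48000, label = NULL, source_path = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar")
  samples <- as.numeric(samples)
  structure(
    list(samples = samples, rate = rate, label = label,
         source_path = source_path, duration_s = length(samples) / rate),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %d Hz%s\n", x$duration_s,
              as.integer(x$rate),
              if (is.null(x$label)) "" else paste0("  [", x$label, "]")))
  invisible(x)
}

#' Cut a clip into fixed-length overlapped frames
#'
#' Splits the signal into analysis frames of `frame_ms` milliseconds advanced
#' by `frame_length * (1 - overlap)` samples. At the 48 kHz / 30 ms / 50%
#' defaults this yields 1440-sample frames with a 720-sample hop. Trailing
#' samples that do not fill a complete frame are discarded (the transform
#' stage needs fixed-length frames).
#'
#' @param clip An [audio_clip()].
#' @param frame_ms Frame duration in milliseconds (default 30).
#' @param overlap Fractional overlap between consecutive frames in `[0, 1)`
#'   (default 0.5).
#' @return A `frame_matrix`: list with `frames` (R x L matrix), `frame_length`,
#'   `hop`, `rate`, `windowed` flag, `frame_times` (start offsets in seconds)
#'   and `empty` flag (`TRUE` when the clip is shorter than one frame, which
#'   yields a zero-row result rather than an error).
#' @export
frame_signal <- function(clip, frame_ms = 30, overlap = 0.5) {
  stopifnot(inherits(clip, "audio_clip"))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  L_exact <- clip$rate * frame_ms / 1000
  if (abs(L_exact - round(L_exact)) > 1e-9)
    stop("rate * frame_ms must give an integer frame length (got ", L_exact, ")")
  L <- as.integer(round(L_exact))
  hop <- as.integer(round(L * (1 - overlap)))
  if (hop < 1) stop("overlap too large: hop would be below one sample")
  n <- length(clip$samples)
  n_frames <- if (n < L) 0L else (n - L) %/% hop + 1L
  starts <- if (n_frames > 0L) (seq_len(n_frames) - 1L) * hop else integer(0)
  frames <- if (n_frames > 0L) {
    idx <- outer(starts, seq_len(L), `+`)
    matrix(clip$samples[idx], nrow = n_frames, ncol = L)
  } else {
    matrix(numeric(0), nrow = 0, ncol = L)
  }
  structure(
    list(frames = frames, frame_length = L, hop = hop, rate = clip$rate,
         windowed = FALSE, frame_times = starts / clip$rate,
         empty = n_frames == 0L),
    class = "frame_matrix")
}

# Symmetric Hamming window, the common analysis convention:
# w[n] = 0.54 - 0.46 cos(2 pi n / (L - 1)), n = 0..L-1 (endpoints 0.08).
hamming_window <- function(L) as.numeric(signal::hamming(L))

#' Apply a Hamming window to every frame
#'
#' Multiplies each frame elementwise by a symmetric length-L Hamming window.
#' Windowing the same frame matrix twice is an error.
#'
#' @param fm A `frame_matrix` from [frame_signal()].
#' @return The windowed `frame_matrix` (`windowed = TRUE`).
#' @export
apply_window <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  if (isTRUE(fm$windowed)) stop("frame matrix is already windowed")
  w <- hamming_window(fm$frame_length)
  fm$frames <- sweep(fm$frames, 2, w, `*`)
  fm$windowed <- TRUE
  fm
}

#' Select the highest-energy frames of a clip
#'
#' Implements the corpus pre-processing rule that keeps the 35% highest
#' energy frames of each file as birdsong and discards the rest. Energy is
#' the sum of squared samples of the (unwindowed) frame. The retained count
#' is `ceiling(fraction * R)`; ties are broken in favour of earlier frames.
#' Indices are 1-based and returned in ascending time order.
#'
#' @param fm A `frame_matrix`; must not be windowed (selection operates on raw
#'   frame energy, upstream of the feature chain).
#' @param fraction Fraction of frames to retain, in `(0, 1]` (default 0.35).
#' @return Integer vector of retained frame indices (empty for an empty
#'   frame matrix).
#' @export
select_high_energy_frames <- function(fm, fraction = 0.35) {
  stopifnot(inherits(fm, "frame_matrix"))
  if (isTRUE(fm$windowed))
    stop("frame energy must be computed on unwindowed frames")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  R <- nrow(fm$frames)
  if (R == 0L) return(integer(0))
  energy <- rowSums(fm$frames^2)
  n_keep <- as.integer(ceiling(fraction * R))
  # order() with decreasing energy; ties resolved by earlier index.
  keep <- order(-energy, seq_len(R))[seq_len(n_keep)]
  sort(keep)
}

#' Frame energies
#'
#' Sum of squared samples per frame, the quantity the energy gate ranks.
#'
#' @param fm A `frame_matrix`.
#' @return Numeric vector of length `nrow(fm$frames)`.
#' @export
frame_energy <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  rowSums(fm$frames^2)
}
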