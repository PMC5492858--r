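#' Read a RIFF WAV file into an audio clip
#'
#' Minimal RIFF/WAVE reader for mono PCM recordings. Supports PCM 16-, 24- and
#' 32-bit integer encodings and IEEE float32. Samples are rescaled to
#' `[-1, 1]` by the full-scale integer value (`32768` for 16-bit, etc.), so a
#' full-scale positive 16-bit sample maps to `32767/32768`.
#'
#' @param path Path to a `.wav` file.
#' @param label Optional species label attached to the clip.
#' @param downmix If `TRUE`, multi-channel files are averaged to mono;
#'   otherwise a multi-channel file is an error.
#' @return An [audio_clip()] object.
#' @export
load_wav <- function(path, label = NULL, downmix = FALSE) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        rate         = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ") in ", path)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (fmt$audio_format == 3L) {
    if (fmt$bits != 32L) stop("float WAV must be 32-bit: ", path)
    x <- readBin(data_raw, "double", n, 4, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported PCM bit depth ", fmt$bits, " in ", path)
  }

  if (fmt$n_channels > 1L) {
    if (!downmix)
      stop(path, " has ", fmt$n_channels,
           " channels; mono required (set downmix = TRUE to average)")
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_clip(x, fmt$rate, label = label, source_path = path)
}

#' Write an audio clip as a 16-bit PCM mono WAV file
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(clip$rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
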