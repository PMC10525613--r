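# WAV input/output, resampling, pre-emphasis and framing.
#
# The RIFF/PCM reader and writer are self-contained so that recordings made
# under the usual clinical protocol (mono, 44.1 kHz, 16-bit) round-trip
# bit-faithfully without external audio dependencies.

#' Construct an audio signal
#'
#' The basic carrier of all acoustic computation: a numeric sample vector in
#' \eqn{[-1, 1]} together with its sampling rate in Hz.
#'
#' @param samples Numeric vector of samples; all values must be finite.
#' @param rate Sampling rate in samples per second (Hz), positive.
#' @return An object of class \code{audio_signal} with fields
#'   \code{samples} and \code{rate}.
#' @examples
#' s <- audio_signal(sin(2 * pi * 220 * seq(0, 1, by = 1/8000)), 8000)
#' audio_duration(s)
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(samples) && any(!is.finite(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$rate, audio_duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal An \code{audio_signal}.
#' @return Length divided by rate, in seconds.
#' @export
audio_duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$rate
}

read_u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}

read_u32 <- function(raw, off) {
  as.numeric(raw[off]) + 256 * as.numeric(raw[off + 1L]) +
    65536 * as.numeric(raw[off + 2L]) + 16777216 * as.numeric(raw[off + 3L])
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files holding integer PCM (8/16/24/32-bit) or 32-bit IEEE
#' float samples.  Multi-channel files are averaged down to mono; integer
#' samples are scaled to \eqn{[-1, 1]} (16-bit value 16384 becomes 0.5).
#'
#' @param path Path to a \code{.wav} file.
#' @return A mono \code{\link{audio_signal}}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    stop(sprintf("not a RIFF/WAV file (leading chunk '%s'): %s", hdr, path))
  invisible(readBin(con, "integer", size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("RIFF form is '%s', not WAVE: %s", wave, path))

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    szb <- readBin(con, "raw", n = 4L)
    if (length(szb) < 4L) break
    sz <- read_u32(szb, 1L)
    body <- readBin(con, "raw", n = sz)
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = read_u16(body, 1L),
        channels = read_u16(body, 3L),
        rate     = read_u32(body, 5L),
        bits     = read_u16(body, 15L))
      if (fmt$format == 65534L && length(body) >= 26L)  # WAVE_FORMAT_EXTENSIBLE
        fmt$format <- read_u16(body, 25L)
    } else if (identical(id, "data")) {
      data_raw <- body
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", n = 1L))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop(sprintf("no 'fmt ' chunk found in %s", path))
  if (is.null(data_raw)) stop(sprintf("no 'data' chunk found in %s", path))
  if (!fmt$format %in% c(1L, 3L))
    stop(sprintf("unsupported WAV codec (format tag %d) in 'fmt ' chunk: %s",
                 fmt$format, path))

  x <- decode_pcm(data_raw, fmt)
  if (fmt$channels > 1L) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- colMeans(matrix(x[seq_len(n)], nrow = fmt$channels))
  }
  audio_signal(clamp(x, -1, 1), fmt$rate)
}

decode_pcm <- function(raw, fmt) {
  nb <- fmt$bits %/% 8L
  n <- length(raw) %/% nb
  if (fmt$format == 3L) {
    if (fmt$bits != 32L) stop(sprintf("unsupported float bit depth %d", fmt$bits))
    return(readBin(raw, "double", n = n, size = 4L, endian = "little"))
  }
  switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(raw, "integer", n = n, size = 1L,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(raw, "integer", n = n, size = 2L, endian = "little",
                   signed = TRUE) / 32768,
    "24" = {
      m <- matrix(as.numeric(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "32" = readBin(raw, "integer", n = n, size = 4L, endian = "little") / 2147483648,
    stop(sprintf("unsupported PCM bit depth %d", fmt$bits)))
}

#' Write a WAV file
#'
#' @param signal An \code{\link{audio_signal}} (mono).
#' @param path Output path.
#' @param bit_depth \code{"16"} for 16-bit integer PCM (default) or
#'   \code{"32f"} for 32-bit IEEE float.
#' @return The path, invisibly.  \code{read_wav(write_wav(...))} reproduces
#'   the samples within one least-significant bit of the chosen depth and the
#'   rate exactly.
#' @export
write_wav <- function(signal, path, bit_depth = c("16", "32f")) {
  stopifnot(inherits(signal, "audio_signal"))
  bit_depth <- match.arg(bit_depth)
  x <- signal$samples
  write_wav_raw(if (length(x)) matrix(x, nrow = 1L) else
                  matrix(numeric(0), nrow = 1L, ncol = 0L),
                signal$rate, path, bit_depth)
  invisible(path)
}

# Low-level writer: `channels` is a matrix with one row per channel
# (interleaved on disk).  Used directly only by tests that need stereo files.
write_wav_raw <- function(channels, rate, path, bit_depth = "16") {
  n_ch <- nrow(channels)
  inter <- as.numeric(channels)  # column-major = frame-interleaved
  if (bit_depth == "16") {
    fmt_tag <- 1L; bits <- 16L
    q <- as.integer(clamp(round(inter * 32768), -32768, 32767))
    data_bytes <- writeBin(q, raw(), size = 2L, endian = "little")
  } else if (bit_depth == "32f") {
    fmt_tag <- 3L; bits <- 32L
    data_bytes <- writeBin(inter, raw(), size = 4L, endian = "little")
  } else stop("bit_depth must be '16' or '32f'")

  block_align <- n_ch * bits %/% 8L
  byte_rate <- rate * block_align
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36L + length(data_bytes))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(fmt_tag); w_u16(n_ch); w_u32(rate); w_u32(byte_rate)
  w_u16(block_align); w_u16(bits)
  writeChar("data", con, eos = NULL); w_u32(length(data_bytes))
  writeBin(data_bytes, con)
  invisible(path)
}

#' Resample an audio signal
#'
#' Band-limited rational-ratio resampling with anti-aliasing (polyphase FIR,
#' via \code{signal::resample}).  Duration is preserved within one sample
#' period of the target rate.
#'
#' @param signal An \code{\link{audio_signal}}.
#' @param target_rate Desired sampling rate in Hz, positive.
#' @return The resampled \code{audio_signal}.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("`target_rate` must be a single positive number")
  if (target_rate == signal$rate) return(signal)
  if (length(signal$samples) == 0L) return(audio_signal(numeric(0), target_rate))
  pq <- rational_approx(target_rate / signal$rate)
  y <- if (pq[["p"]] == 1L && pq[["q"]] > 1L)
    decimate_fir(signal$samples, pq[["q"]])
  else
    as.numeric(signal::resample(signal$samples, pq[["p"]], pq[["q"]]))
  audio_signal(clamp(y, -1, 1), target_rate)
}

# Integer-factor decimation: zero-phase FIR low-pass at the output Nyquist
# followed by subsampling.  Filters are cached per factor.
.fir_cache <- new.env(parent = emptyenv())

decimate_fir <- function(x, q) {
  key <- as.character(q)
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    h <- signal::fir1(64L, 0.9 / q)
    .fir_cache[[key]] <- h
  }
  half <- (length(h) - 1L) %/% 2L
  N <- length(x)
  M <- stats::nextn(N + length(h) - 1L, 2L)
  Y <- stats::fft(c(x, rep(0, M - N))) * stats::fft(c(h, rep(0, M - length(h))))
  y <- Re(stats::fft(Y, inverse = TRUE)) / M
  y <- y[(half + 1L):(half + N)]
  y[seq(1L, N, by = q)]
}

#' First-order pre-emphasis
#'
#' \eqn{y[n] = x[n] - \alpha x[n-1]} with \eqn{y[1] = x[1]}; the standard
#' high-frequency boost applied before LPC analysis.
#'
#' @param signal An \code{\link{audio_signal}}.
#' @param alpha Pre-emphasis coefficient in \eqn{[0, 1)}; 0 is the identity.
#' @return The filtered \code{audio_signal} (no amplitude re-normalization).
#' @export
preemphasize <- function(signal, alpha = 0.97) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("`alpha` must satisfy 0 <= alpha < 1")
  x <- signal$samples
  if (length(x) == 0L || alpha == 0) return(signal)
  y <- x - alpha * c(0, x[-length(x)])
  structure(list(samples = y, rate = signal$rate), class = "audio_signal")
}

#' Slice a signal into overlapping analysis frames
#'
#' Frame \eqn{i} covers \eqn{[(i-1) \cdot hop, (i-1) \cdot hop + frame\_len)};
#' a trailing partial frame is dropped, so the frame count is
#' \eqn{\lfloor (N - L) / H \rfloor + 1} for \eqn{N} samples, frame length
#' \eqn{L} and hop \eqn{H} samples.
#'
#' @param signal An \code{\link{audio_signal}}.
#' @param frame_len Frame length in seconds.
#' @param hop Hop (frame advance) in seconds, \code{0 < hop <= frame_len}.
#' @param window \code{"hamming"}, \code{"hann"} or \code{"rect"}, applied
#'   multiplicatively.
#' @return A \code{frame_sequence}: list with \code{frames} (matrix, one
#'   column per frame), \code{start_times}, \code{times} (frame centers),
#'   \code{frame_len}, \code{hop}, \code{rate}, \code{window}.
#' @export
frame_signal <- function(signal, frame_len = 0.025, hop = 0.010,
                         window = c("hamming", "hann", "rect")) {
  stopifnot(inherits(signal, "audio_signal"))
  window <- match.arg(window)
  if (hop <= 0 || hop > frame_len)
    stop("require 0 < hop <= frame_len")
  L <- max(1L, round(frame_len * signal$rate))
  H <- max(1L, round(hop * signal$rate))
  N <- length(signal$samples)
  if (L > N) stop("frame longer than signal")
  n_frames <- (N - L) %/% H + 1L
  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * H, `+`)
  frames <- matrix(signal$samples[idx], nrow = L) * window_vec(window, L)
  start_times <- (seq_len(n_frames) - 1L) * H / signal$rate
  structure(list(frames = frames,
                 start_times = start_times,
                 times = start_times + L / signal$rate / 2,
                 frame_len = L / signal$rate, hop = H / signal$rate,
                 rate = signal$rate, window = window),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence: %d frames of %.1f ms, hop %.1f ms, %s window>\n",
              ncol(x$frames), 1000 * x$frame_len, 1000 * x$hop, x$window))
  invisible(x)
}
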