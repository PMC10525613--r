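# Independent oracles and shared fixtures.  Every oracle here is a
# from-first-principles computation (enumeration, FFT measurement, pair
# counting) kept deliberately separate from the package's own code paths.

# --- audio helpers --------------------------------------------------------

sine_signal <- function(freq, duration, rate, amplitude = 0.8) {
  n <- round(duration * rate)
  audio_signal(amplitude * sin(2 * pi * freq * (0:(n - 1)) / rate), rate)
}

# Dominant non-DC spectral peak of a signal in Hz (periodogram argmax).
fft_peak_hz <- function(signal) {
  x <- signal$samples
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  sp[1] <- 0  # ignore the DC bin
  (which.max(sp) - 1) * signal$rate / n
}

# Spectral-envelope maxima of a voiced signal by cepstral smoothing: the
# log-magnitude spectrum is low-pass liftered below the glottal period's
# quefrency, which strips the harmonic ripple and leaves the vocal-tract
# envelope.  Returns the n_peaks largest local maxima below max_hz, sorted
# ascending.
envelope_peaks_hz <- function(signal, f0, max_hz, n_peaks = 2) {
  x <- signal$samples
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  logmag <- log(Mod(stats::fft(x * w)) + 1e-9)
  ceps <- stats::fft(logmag, inverse = TRUE) / n
  qc <- round(0.7 * signal$rate / f0)
  lifter <- numeric(n)
  lifter[seq_len(qc)] <- 1
  lifter[n - seq_len(qc - 1L) + 1L] <- 1
  env <- Re(stats::fft(ceps * lifter))
  hz <- (seq_len(n) - 1) * signal$rate / n
  keep <- hz > 0 & hz < max_hz
  locmax <- which(diff(sign(diff(env))) == -2) + 1L
  locmax <- locmax[keep[locmax]]
  locmax <- locmax[order(env[locmax], decreasing = TRUE)][seq_len(
    min(n_peaks, length(locmax)))]
  sort(hz[locmax])
}

# --- statistics oracles ---------------------------------------------------

# Mann-Whitney U by direct pair counting (ties one half).
pair_count_U <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# label assignments of the combined sample.
enum_mw_p <- function(x, y) {
  comb <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(comb), nx)
  us <- apply(idx, 2, function(ii) pair_count_U(comb[ii], comb[-ii]))
  u_obs <- pair_count_U(x, y)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# AUC by explicit pair counting over (positive, negative) score pairs.
pair_count_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  (sum(outer(sp, sn, `>`)) + 0.5 * sum(outer(sp, sn, `==`))) /
    (length(sp) * length(sn))
}

# Triangle area via the cross product of two edge vectors.
cross_area <- function(v) {
  e1 <- v[2, ] - v[1, ]
  e2 <- v[3, ] - v[1, ]
  unname(abs(e1[1] * e2[2] - e1[2] * e2[1]) / 2)
}

# --- shared synthetic cohort fixture -------------------------------------

.fixtures <- new.env(parent = emptyenv())

# A small cohort generated once per test session (2/3/2 patients + 3 HC).
small_cohort <- function() {
  if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
  dir <- file.path(tempdir(), "motorspeech-fixture-cohort")
  spec <- cohort_spec(n_hc = 3L, n_bulbar = 2L, n_spinal_bulbar = 3L,
                      n_spinal_only = 2L, n_pumn = 4L,
                      synth_rate = 20000, seed = 101L)
  gen <- generate_cohort(spec, dir)
  .fixtures$cohort <- list(gen = gen, dir = dir, spec = spec)
  .fixtures$cohort
}

fast_config <- function(n_boot = 200L, seed = 1L) {
  pipeline_config(formant = formant_config(hop = 0.020),
                  n_boot = n_boot, seed = seed)
}
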