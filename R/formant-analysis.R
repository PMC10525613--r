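# LPC formant estimation for sustained vowels.
#
# The all-pole model is fitted by the autocorrelation method
# (Levinson-Durbin recursion); formant candidates are the complex pole
# pairs of the prediction polynomial, converted to frequency/bandwidth and
# passed through a Praat-style admission filter.

#' Analysis configuration for formant tracking and phonation timing
#'
#' @param analysis_rate Internal analysis rate in Hz; input audio is
#'   resampled to this rate before LPC.  10 kHz keeps the first two or three
#'   formants below Nyquist while discarding fricative energy.
#' @param lpc_order Prediction order; default \code{2 + analysis_rate/1000}
#'   (the classic one-pole-pair-per-kHz rule, = 12 at 10 kHz).
#' @param preemphasis Pre-emphasis coefficient (see
#'   \code{\link{preemphasize}}).
#' @param frame_len,hop Analysis frame length and hop in seconds.
#' @param window Analysis window kind.
#' @param steady_fraction Central fraction of the voiced span used for
#'   per-vowel formant targets.
#' @param min_freq Lowest admissible formant frequency in Hz.
#' @param edge_margin Formants above \code{Nyquist - edge_margin} Hz are
#'   rejected as edge artefacts.
#' @param max_bandwidth Largest admissible formant bandwidth in Hz.
#' @param n_formants Number of admitted formants kept per frame.
#' @param voicing_offset_db A frame is voiced when its RMS level exceeds
#'   the recording's peak frame level minus this offset (dB).
#' @param voicing_floor_db Absolute voicing floor in dBFS; frames below it
#'   are never voiced.
#' @param bridge_gap Unvoiced gaps up to this length (s) are bridged when
#'   measuring the maximum phonation time.
#' @param mpt_threshold Eligibility threshold for the sustained-vowel
#'   protocol, in seconds of phonation.
#' @return A \code{formant_config} list.
#' @export
formant_config <- function(analysis_rate = 10000, lpc_order = NULL,
                           preemphasis = 0.97, frame_len = 0.025,
                           hop = 0.010, window = "hamming",
                           steady_fraction = 0.5,
                           min_freq = 90, edge_margin = 50,
                           max_bandwidth = 400, n_formants = 3L,
                           voicing_offset_db = 25, voicing_floor_db = -55,
                           bridge_gap = 0.150, mpt_threshold = 5.0) {
  if (is.null(lpc_order)) lpc_order <- 2L + as.integer(round(analysis_rate / 1000))
  structure(as.list(environment()), class = "formant_config")
}

#' Levinson-Durbin recursion on an autocorrelation sequence
#'
#' Solves the Yule-Walker equations for the forward prediction coefficients
#' \eqn{a_1, \ldots, a_p} (convention \eqn{\hat x[n] = \sum_k a_k x[n-k]}).
#'
#' @param r Autocorrelation sequence \code{r[0..p]} as a numeric vector of
#'   length at least \code{order + 1}; \code{r[1]} is the zero-lag term.
#' @param order Prediction order \eqn{p \ge 1}.
#' @return An \code{lpc_model}: list with \code{order}, \code{coefficients},
#'   \code{gain} (final prediction-error energy) and \code{reflection}
#'   coefficients.
#' @export
lpc_from_autocorrelation <- function(r, order) {
  if (length(r) < order + 1L) stop("need r[0..order]")
  if (!is.finite(r[1L]) || r[1L] <= 0)
    stop("degenerate autocorrelation: zero-lag term must be positive")
  a <- numeric(0)
  e <- r[1L]
  refl <- numeric(order)
  for (m in seq_len(order)) {
    acc <- r[m + 1L] - if (m > 1L) sum(a * r[m:2L]) else 0
    if (e <= 0) stop("autocorrelation sequence is not positive definite")
    k <- acc / e
    refl[m] <- k
    a <- if (m > 1L) c(a - k * rev(a), k) else k
    e <- e * (1 - k * k)
  }
  structure(list(order = as.integer(order), coefficients = a, gain = e,
                 reflection = refl), class = "lpc_model")
}

# Levinson-Durbin on many autocorrelation columns at once.  RM is a
# (order+1) x n matrix whose column j holds r_0..r_p of frame j.  Frames
# with a non-positive-definite sequence are flagged not-ok.
levinson_block <- function(RM, order) {
  n <- ncol(RM)
  ok <- is.finite(RM[1L, ]) & RM[1L, ] > 0
  A <- matrix(0, order, n)
  e <- RM[1L, ]
  e[!ok] <- NA_real_
  for (m in seq_len(order)) {
    acc <- RM[m + 1L, ] - if (m > 1L)
      colSums(A[seq_len(m - 1L), , drop = FALSE] *
              RM[m:2L, , drop = FALSE]) else 0
    ok[ok & e <= 0] <- FALSE
    k <- numeric(n)
    k[ok] <- acc[ok] / e[ok]
    if (m > 1L) {
      km <- matrix(k, m - 1L, n, byrow = TRUE)
      A[seq_len(m - 1L), ] <- A[seq_len(m - 1L), , drop = FALSE] -
        km * A[(m - 1L):1L, , drop = FALSE]
    }
    A[m, ] <- k
    e <- e * (1 - k * k)
  }
  list(A = A, e = e, ok = ok & is.finite(e))
}

#' LPC model of a windowed frame (autocorrelation method)
#'
#' @param frame Numeric vector of windowed samples, longer than
#'   \code{order} and not all zero.
#' @param order Prediction order.
#' @return An \code{lpc_model} (see \code{\link{lpc_from_autocorrelation}}).
#' @export
lpc_coefficients <- function(frame, order) {
  frame <- as.numeric(frame)
  n <- length(frame)
  if (n <= order) stop("frame must be longer than the LPC order")
  if (all(frame == 0)) stop("degenerate input: all-zero frame")
  r <- vapply(0:order, function(k)
    sum(frame[seq_len(n - k)] * frame[(k + 1L):n]), numeric(1))
  lpc_from_autocorrelation(r, order)
}

#' Convert an LPC model to formant candidates
#'
#' Roots of the prediction polynomial are computed; each complex pole with
#' positive angle \eqn{\theta} and radius \eqn{\rho} maps to frequency
#' \eqn{\theta \cdot rate / 2\pi} and bandwidth
#' \eqn{-(rate/\pi) \ln \rho}.  Real roots are discarded.
#'
#' @param model An \code{lpc_model}.
#' @param rate Sampling rate the frame was analyzed at, Hz.
#' @return A matrix with columns \code{frequency} and \code{bandwidth},
#'   sorted by frequency; zero rows when no complex pole pair exists.
#' @export
formants_from_lpc <- function(model, rate) {
  stopifnot(inherits(model, "lpc_model"))
  poles <- 1 / polyroot(c(1, -model$coefficients))
  ang <- Arg(poles)
  keep <- ang > 1e-8 & ang < pi - 1e-8
  freq <- ang[keep] * rate / (2 * pi)
  bw <- -(rate / pi) * log(Mod(poles[keep]))
  o <- order(freq)
  matrix(c(freq[o], bw[o]), ncol = 2L,
         dimnames = list(NULL, c("frequency", "bandwidth")))
}

#' Track formants across a sustained vowel
#'
#' Pipeline: resample to the analysis rate, pre-emphasize, slice into
#' windowed frames, fit an LPC model per voiced frame, convert poles to
#' formant candidates and keep the first admitted peaks (frequency within
#' \code{(min_freq, Nyquist - edge_margin)}, bandwidth below
#' \code{max_bandwidth}).
#'
#' @param signal An \code{\link{audio_signal}} at least two frames long.
#' @param config A \code{\link{formant_config}}.
#' @return A \code{formant_track}: list with \code{times} (frame centers),
#'   \code{formants} (list of per-frame candidate matrices), \code{voiced}
#'   (logical), \code{level_db}, \code{rate}, \code{config}.
#' @export
track_formants <- function(signal, config = formant_config()) {
  stopifnot(inherits(signal, "audio_signal"),
            inherits(config, "formant_config"))
  s <- resample_audio(signal, config$analysis_rate)
  if (audio_duration(s) < config$frame_len + config$hop)
    stop("signal too short for formant analysis")
  pre <- preemphasize(s, config$preemphasis)
  fr <- frame_signal(pre, config$frame_len, config$hop, config$window)

  # Voicing from the raw (un-pre-emphasized) frames.
  raw_fr <- frame_signal(s, config$frame_len, config$hop, "rect")
  level <- db_level(sqrt(colMeans(raw_fr$frames^2)))
  voiced <- level > pmax(max(level) - config$voicing_offset_db,
                         config$voicing_floor_db)

  p <- config$lpc_order
  X <- fr$frames
  n_frames <- ncol(X)
  L <- nrow(X)
  acf_mat <- vapply(0:p, function(k)
    colSums(X[seq_len(L - k), , drop = FALSE] *
            X[(k + 1L):L, , drop = FALSE]), numeric(n_frames))
  if (!is.matrix(acf_mat)) acf_mat <- matrix(acf_mat, nrow = n_frames)
  nyq <- config$analysis_rate / 2
  formants <- vector("list", n_frames)
  empty <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("frequency", "bandwidth")))
  # Levinson-Durbin run on all frames at once (recursion over the order,
  # vectorized over frames); numerically identical to the per-frame path.
  lev <- levinson_block(t(acf_mat), p)
  for (i in seq_len(n_frames)) {
    if (!voiced[i] || !lev$ok[i]) {
      formants[[i]] <- empty
      if (!lev$ok[i]) voiced[i] <- FALSE
      next
    }
    model <- structure(list(order = p, coefficients = lev$A[, i],
                            gain = lev$e[i]), class = "lpc_model")
    cand <- formants_from_lpc(model, config$analysis_rate)
    adm <- cand[, 1L] > config$min_freq &
      cand[, 1L] < nyq - config$edge_margin &
      cand[, 2L] < config$max_bandwidth
    cand <- cand[adm, , drop = FALSE]
    if (nrow(cand) > config$n_formants)
      cand <- cand[seq_len(config$n_formants), , drop = FALSE]
    formants[[i]] <- cand
  }
  structure(list(times = fr$times, formants = formants, voiced = voiced,
                 level_db = level, rate = config$analysis_rate,
                 config = config),
            class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf("<formant_track: %d frames, %d voiced, analysis rate %g Hz>\n",
              length(x$times), sum(x$voiced), x$rate))
  invisible(x)
}

#' Reduce a formant track to per-vowel (F1, F2) targets
#'
#' Restricts to the central \code{steady_fraction} of the voiced span (to
#' exclude onset/offset transitions) and takes the median of the first and
#' second admitted formants across usable frames.
#'
#' @param track A \code{formant_track}.
#' @param steady_fraction Central fraction of the voiced span used; default
#'   from the track's configuration.
#' @param vowel Vowel label (\code{"a"}, \code{"i"} or \code{"u"}).
#' @return A \code{vowel_formants}: list with \code{vowel}, \code{F1},
#'   \code{F2} (Hz) and \code{n_frames_used}.
#' @export
vowel_targets <- function(track, steady_fraction = NULL,
                          vowel = NA_character_) {
  stopifnot(inherits(track, "formant_track"))
  steady_fraction <- steady_fraction %||% track$config$steady_fraction
  usable <- track$voiced &
    vapply(track$formants, nrow, integer(1)) >= 2L
  if (sum(usable) < 5L)
    stop(sprintf("insufficient voicing: only %d usable frames (need 5)",
                 sum(usable)))
  tt <- track$times[usable]
  mid <- (min(tt) + max(tt)) / 2
  half <- steady_fraction * (max(tt) - min(tt)) / 2
  sel <- usable & track$times >= mid - half & track$times <= mid + half
  if (sum(sel) < 5L) sel <- usable
  f1 <- stats::median(vapply(track$formants[sel],
                             function(m) m[1L, 1L], numeric(1)))
  f2 <- stats::median(vapply(track$formants[sel],
                             function(m) m[2L, 1L], numeric(1)))
  if (!(is.finite(f1) && is.finite(f2) && f1 > 0 && f1 < f2))
    stop("formant targets are not ordered F1 < F2; analysis failed")
  structure(list(vowel = vowel, F1 = f1, F2 = f2,
                 n_frames_used = sum(sel)),
            class = "vowel_formants")
}

#' @export
print.vowel_formants <- function(x, ...) {
  cat(sprintf("<vowel_formants /%s/: F1 = %.0f Hz, F2 = %.0f Hz (%d frames)>\n",
              x$vowel, x$F1, x$F2, x$n_frames_used))
  invisible(x)
}

#' Maximum phonation time and protocol eligibility
#'
#' The phonation time is the duration of the longest contiguous voiced
#' region (unvoiced gaps up to \code{bridge_gap} seconds are bridged);
#' subjects are eligible for the sustained-vowel protocol when it exceeds
#' \code{mpt_threshold} (default 5 s).
#'
#' @param signal An \code{\link{audio_signal}}.
#' @param config A \code{\link{formant_config}}.
#' @return A \code{sustained_vowel_result}: list with \code{mpt} (s) and
#'   \code{eligible}.
#' @export
maximum_phonation_time <- function(signal, config = formant_config()) {
  stopifnot(inherits(signal, "audio_signal"),
            inherits(config, "formant_config"))
  if (audio_duration(signal) < config$frame_len + config$hop)
    return(structure(list(mpt = 0, eligible = FALSE),
                     class = "sustained_vowel_result"))
  fr <- frame_signal(signal, config$frame_len, config$hop, "rect")
  level <- db_level(sqrt(colMeans(fr$frames^2)))
  voiced <- level > pmax(max(level) - config$voicing_offset_db,
                         config$voicing_floor_db)
  mpt <- 0
  if (any(voiced)) {
    idx <- which(voiced)
    gap_frames <- ceiling(config$bridge_gap / fr$hop)
    run_start <- idx[1L]
    prev <- idx[1L]
    best <- 0L
    for (i in idx[-1L]) {
      if (i - prev > gap_frames) {
        best <- max(best, prev - run_start + 1L)
        run_start <- i
      }
      prev <- i
    }
    best <- max(best, prev - run_start + 1L)
    mpt <- (best - 1L) * fr$hop + fr$frame_len
  }
  structure(list(mpt = mpt, eligible = mpt > config$mpt_threshold),
            class = "sustained_vowel_result")
}
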