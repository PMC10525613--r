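# Diadochokinesis (DDK) analysis: amplitude envelope, syllable nucleus
# detection and AMR/SMR articulation rates (nine syllables divided by the
# elapsed duration of their span, reported to one decimal place).

#' Detection configuration for DDK analysis
#'
#' @param frame_len,hop Envelope frame length and hop in seconds.
#' @param smooth Moving-average smoothing width for the envelope, seconds.
#' @param floor_offset_db A peak must exceed the recording's silence floor
#'   (5th percentile of frame levels) by this many dB to count as a nucleus.
#' @param prominence_db Required prominence above the higher adjacent
#'   trough, dB.
#' @param min_separation Refractory interval between accepted nuclei,
#'   seconds.
#' @param skip_initial Nuclei within this initial interval (s) are excluded
#'   from rate measurement (initiation transient).
#' @param n_syllables Number of consecutive syllables used for the rate.
#' @return A \code{ddk_config} list.
#' @export
ddk_config <- function(frame_len = 0.020, hop = 0.005, smooth = 0.050,
                       floor_offset_db = 10, prominence_db = 3,
                       min_separation = 0.090, skip_initial = 0.250,
                       n_syllables = 9L) {
  structure(as.list(environment()), class = "ddk_config")
}

#' Smoothed amplitude envelope in dBFS
#'
#' Per-frame RMS level in dB relative to full scale (floored at -80 dB),
#' smoothed by a moving average of width \code{smooth} seconds.
#'
#' @param signal An \code{\link{audio_signal}} at least two frames long.
#' @param frame_len,hop Frame length and hop in seconds.
#' @param smooth Moving-average width in seconds.
#' @return A \code{ddk_envelope}: list with \code{times} (frame centers),
#'   \code{level_db} (smoothed), \code{raw_db}, \code{hop}.
#' @export
amplitude_envelope <- function(signal, frame_len = 0.020, hop = 0.005,
                               smooth = 0.050) {
  stopifnot(inherits(signal, "audio_signal"))
  if (audio_duration(signal) < frame_len + hop)
    stop("signal too short for envelope analysis")
  fr <- frame_signal(signal, frame_len, hop, "rect")
  raw_db <- db_level(sqrt(colMeans(fr$frames^2)))
  k <- max(1L, round(smooth / fr$hop))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L && length(raw_db) > k) {
    half <- k %/% 2L
    padded <- c(rep(raw_db[1L], half), raw_db,
                rep(raw_db[length(raw_db)], half))
    sm <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))
    sm <- sm[(half + 1L):(half + length(raw_db))]
  } else sm <- raw_db
  structure(list(times = fr$times, level_db = sm, raw_db = raw_db,
                 hop = fr$hop), class = "ddk_envelope")
}

# Index of the trough between envelope positions i0..i1 (inclusive).
# `side` picks the representative index when the minimum is a plateau:
# interior troughs take the plateau midpoint, edge troughs the end nearest
# the syllable train.
trough_index <- function(level, i0, i1, side = c("mid", "last", "first")) {
  side <- match.arg(side)
  seg <- level[i0:i1]
  cand <- which(seg <= min(seg) + 0.1)
  pick <- switch(side,
    mid = cand[ceiling(length(cand) / 2)],
    last = cand[length(cand)],
    first = cand[1L])
  i0 + pick - 1L
}

#' Detect syllable nuclei in a DDK envelope
#'
#' Local maxima of the smoothed envelope are accepted as syllable nuclei
#' when they (a) exceed the silence floor (5th percentile of levels) by
#' \code{floor_offset_db}, (b) rise at least \code{prominence_db} above the
#' higher of the two adjacent troughs, and (c) fall no closer than
#' \code{min_separation} to the previously accepted nucleus.  Boundaries are
#' the minimum-level troughs between accepted nuclei and toward the task
#' edges.
#'
#' @param env A \code{\link{amplitude_envelope}} result.
#' @param config A \code{\link{ddk_config}}.
#' @return A \code{syllable_segmentation}: list with \code{nucleus_times},
#'   \code{boundaries} (length \code{n_detected + 1}, interleaving the
#'   nuclei), \code{n_detected}, \code{floor_db}.  An empty segmentation
#'   (no nuclei) is a valid result, not an error.
#' @export
detect_syllable_nuclei <- function(env, config = ddk_config()) {
  stopifnot(inherits(env, "ddk_envelope"), inherits(config, "ddk_config"))
  lv <- env$level_db
  n <- length(lv)
  floor_db <- as.numeric(stats::quantile(lv, 0.05, names = FALSE))
  empty <- structure(list(nucleus_times = numeric(0),
                          boundaries = numeric(0), n_detected = 0L,
                          floor_db = floor_db),
                     class = "syllable_segmentation")
  if (n < 3L) return(empty)

  # Candidate peaks: strict rise, non-strict fall (plateau-tolerant).
  cand <- which(lv[2:(n - 1L)] > lv[1:(n - 2L)] &
                lv[2:(n - 1L)] >= lv[3:n]) + 1L
  if (length(cand) == 0L) return(empty)

  # Topographic prominence: walk out to the nearest strictly higher sample
  # on each side and take the minimum level in between; ripple maxima on a
  # burst plateau get near-zero prominence, true nuclei the full burst rise.
  accepted <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    if (lv[i] < floor_db + config$floor_offset_db) next
    left <- i; while (left > 1L && lv[left] <= lv[i]) left <- left - 1L
    right <- i; while (right < n && lv[right] <= lv[i]) right <- right + 1L
    left_min <- min(lv[left:i])
    right_min <- min(lv[i:right])
    if (lv[i] - max(left_min, right_min) < config$prominence_db) next
    if (env$times[i] - last_t < config$min_separation) next
    accepted <- c(accepted, i)
    last_t <- env$times[i]
  }
  if (length(accepted) == 0L) return(empty)

  m <- length(accepted)
  bounds <- numeric(m + 1L)
  bounds[1L] <- env$times[trough_index(lv, 1L, accepted[1L], "last")]
  if (m > 1L) for (j in seq_len(m - 1L))
    bounds[j + 1L] <- env$times[trough_index(lv, accepted[j],
                                             accepted[j + 1L], "mid")]
  bounds[m + 1L] <- env$times[trough_index(lv, accepted[m], n, "first")]
  structure(list(nucleus_times = env$times[accepted], boundaries = bounds,
                 n_detected = m, floor_db = floor_db),
            class = "syllable_segmentation")
}

#' @export
print.syllable_segmentation <- function(x, ...) {
  cat(sprintf("<syllable_segmentation: %d nuclei, floor %.1f dB>\n",
              x$n_detected, x$floor_db))
  invisible(x)
}

#' Articulation rate from a syllable segmentation
#'
#' Selects the first \code{n} consecutive detected nuclei whose times lie
#' beyond the initiation transient (\code{skip_initial}), and divides
#' \code{n} by the elapsed time between the trough boundary before the first
#' and the trough boundary after the last selected syllable.  The reported
#' rate is rounded half-away-from-zero to one decimal; the full-precision
#' rate is retained for statistics.
#'
#' @param seg A \code{\link{detect_syllable_nuclei}} result.
#' @param n Number of syllables used (default 9).
#' @param task Optional task label (\code{"pa"}, \code{"ta"}, \code{"ka"},
#'   \code{"pataka"}), carried through to the result.
#' @param config A \code{\link{ddk_config}} (supplies \code{skip_initial}).
#' @return An \code{articulation_rate}: list with \code{task},
#'   \code{n_syllables}, \code{span} (s), \code{rate} (syllables/s) and
#'   \code{rate_reported} (1 decimal).
#' @export
articulation_rate <- function(seg, n = 9L, task = NA_character_,
                              config = ddk_config()) {
  stopifnot(inherits(seg, "syllable_segmentation"))
  eligible <- which(seg$nucleus_times >= config$skip_initial)
  if (length(eligible) < n) {
    cnd <- structure(class = c("insufficient_syllables", "error", "condition"),
                     list(message = sprintf(
                       "only %d usable syllables detected (need %d; %d total)",
                       length(eligible), n, seg$n_detected),
                       call = sys.call(), n_detected = seg$n_detected))
    stop(cnd)
  }
  k <- eligible[1L]
  span <- seg$boundaries[k + n] - seg$boundaries[k]
  rate <- n / span
  structure(list(task = task, n_syllables = as.integer(n), span = span,
                 rate = rate, rate_reported = round_half_away(rate, 1L)),
            class = "articulation_rate")
}

#' @export
print.articulation_rate <- function(x, ...) {
  cat(sprintf("<articulation_rate%s: %.1f syll/s (%d syllables / %.2f s)>\n",
              if (is.na(x$task)) "" else paste0(" /", x$task, "/"),
              x$rate_reported, x$n_syllables, x$span))
  invisible(x)
}
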