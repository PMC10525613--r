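# Envelope computation, syllable nucleus detection, articulation rates.

test_that("envelope level is 0 dBFS for full-scale signals and floored for silence", {
  full <- audio_signal(rep(c(1, -1), 8000), 16000)
  env <- amplitude_envelope(full)
  expect_true(all(abs(env$level_db) < 1e-9))
  sil <- amplitude_envelope(audio_signal(rep(0, 16000), 16000))
  expect_true(all(abs(sil$level_db + 80) < 1e-9))
  expect_error(amplitude_envelope(audio_signal(rep(0, 10), 16000)), "short")
})

test_that("envelope peaks of an amplitude-modulated tone follow the modulation rate", {
  rate <- 16000
  t <- (0:(4 * rate - 1)) / rate
  x <- (0.55 + 0.45 * cos(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  env <- amplitude_envelope(audio_signal(x * 0.9, rate))
  seg <- detect_syllable_nuclei(env, ddk_config(floor_offset_db = 3,
                                                prominence_db = 2))
  spacing <- diff(seg$nucleus_times)
  expect_true(all(abs(1 / spacing - 4) < 0.5))
})

test_that("nucleus detection recovers count and timing on clean trains", {
  d <- ddk_spec("pa", rate = 4, n_syllables = 10,
                vowel = vowel_spec(duration = 1), gap_fraction = 0.4,
                rate_jitter = 0)
  out <- synth_ddk_train(d, 16000)
  seg <- detect_syllable_nuclei(amplitude_envelope(out$signal))
  expect_equal(seg$n_detected, 10)
  expect_true(all(abs(seg$nucleus_times - out$truth$nucleus_times) < 0.025))
  expect_equal(length(seg$boundaries), 11)
  expect_true(all(seg$boundaries[-11] < seg$nucleus_times))
  expect_true(all(seg$boundaries[-1] > seg$nucleus_times))
})

test_that("silence and single bursts segment as expected", {
  sil <- detect_syllable_nuclei(
    amplitude_envelope(audio_signal(rep(0, 16000), 16000)))
  expect_equal(sil$n_detected, 0)
  rate <- 16000
  burst <- synth_vowel(vowel_spec(f0 = 120,
                                  formants = rbind(c(700, 80), c(1200, 90)),
                                  duration = 0.15), rate, seed = 1)
  one <- audio_signal(c(rep(0, rate %/% 2), burst$samples,
                        rep(0, rate %/% 2)), rate)
  seg <- detect_syllable_nuclei(amplitude_envelope(one))
  expect_equal(seg$n_detected, 1)
})

test_that("articulation rate implements nine-divided-by-span with half-away rounding", {
  seg <- structure(list(
    nucleus_times = 0.4 + (0:9) * 0.2,
    boundaries = c(0.3 + (0:9) * 0.2, 2.3), n_detected = 10L,
    floor_db = -80), class = "syllable_segmentation")
  ar <- articulation_rate(seg, 9, task = "pa")
  expect_equal(ar$span, 1.8)
  expect_equal(ar$rate, 5.0)
  expect_equal(ar$rate_reported, 5.0)

  seg2 <- seg
  seg2$boundaries[10] <- seg2$boundaries[1] + 1.75  # 9 syllables in 1.75 s
  ar2 <- articulation_rate(seg2, 9)
  expect_equal(ar2$rate, 9 / 1.75)
  expect_equal(ar2$rate_reported, 5.1)  # 5.142... rounds to 5.1

  err <- tryCatch(articulation_rate(seg, 11), error = identity)
  expect_s3_class(err, "insufficient_syllables")
  expect_equal(err$n_detected, 10L)
})

test_that("initial transient nuclei are excluded from the measured span", {
  # first nucleus at 0.1 s must be skipped; rate measured from the second
  seg <- structure(list(
    nucleus_times = c(0.1, 0.4 + (0:9) * 0.2),
    boundaries = c(0.05, 0.3 + (0:9) * 0.2, 2.5), n_detected = 11L,
    floor_db = -80), class = "syllable_segmentation")
  ar <- articulation_rate(seg, 9)
  expect_equal(ar$span, 9 * 0.2)
  expect_equal(ar$rate, 5.0)
})

test_that("rates are recovered within 0.2 syll/s across the clinical range", {
  for (r in c(2, 3, 5, 7)) {
    d <- ddk_spec("pa", rate = r, n_syllables = 13,
                  vowel = vowel_spec(duration = 1),
                  gap_fraction = 0.35, rate_jitter = 0)
    out <- synth_ddk_train(d, 16000)
    seg <- detect_syllable_nuclei(amplitude_envelope(out$signal))
    expect_equal(seg$n_detected, 13, info = sprintf("rate %g", r))
    ar <- articulation_rate(seg, 9, task = "pa")
    expect_lt(abs(ar$rate - r), 0.2)
  }
})

test_that("time-stretching a train scales the estimated rate inversely", {
  d <- ddk_spec("pa", rate = 5, n_syllables = 13,
                vowel = vowel_spec(duration = 1), gap_fraction = 0.35)
  out <- synth_ddk_train(d, 16000)
  est <- function(sig) {
    seg <- detect_syllable_nuclei(amplitude_envelope(sig))
    articulation_rate(seg, 9)$rate
  }
  base <- est(out$signal)
  # relabeling the rate stretches time by exactly k = 2
  stretched <- audio_signal(out$signal$samples, 8000)
  expect_equal(est(stretched), base / 2, tolerance = 0.02)
})
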