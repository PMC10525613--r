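# Source-filter synthesizer: glottal source, vowels, DDK trains, cohorts.

test_that("glottal source has one pulse per period and a peak at f0", {
  src <- synth_glottal_source(100, 1, 10000)
  expect_equal(audio_duration(src), 1.0)
  expect_equal(sum(src$samples > 0.5), 100)  # one dominant sample per pulse
  expect_lt(abs(fft_peak_hz(src) - 100), 1)
  expect_error(synth_glottal_source(0, 1, 10000), "positive")
  expect_error(synth_glottal_source(6000, 1, 10000), "Nyquist")
})

test_that("synthesized vowels place spectral envelope maxima at the formants", {
  spec <- vowel_spec(f0 = 120, formants = rbind(c(700, 80), c(1200, 90)),
                     duration = 2, amplitude = 0.9)
  sig <- synth_vowel(spec, 10000)
  peaks <- envelope_peaks_hz(sig, 120, max_hz = 2000, n_peaks = 2)
  expect_lt(abs(peaks[1] - 700), 20)
  expect_lt(abs(peaks[2] - 1200), 20)
  expect_equal(max(abs(sig$samples)), 0.9)
})

test_that("vowel synthesis respects amplitude and is seed-deterministic", {
  spec <- vowel_spec(f0 = 110, formants = rbind(c(800, 80), c(1300, 90)),
                     duration = 0.5, amplitude = 0.5, noise_db = -30)
  a <- synth_vowel(spec, 16000, seed = 9)
  b <- synth_vowel(spec, 16000, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_equal(max(abs(a$samples)), 0.5)
  expect_error(synth_vowel(vowel_spec(formants = rbind(c(700, 80), c(9000, 90)),
                                      duration = 0.2), 16000), "Nyquist")
})

test_that("DDK trains have the constructed nucleus spacing and true rate", {
  d <- ddk_spec("pa", rate = 4, n_syllables = 10,
                vowel = vowel_spec(duration = 1), gap_fraction = 0.4,
                rate_jitter = 0)
  out <- synth_ddk_train(d, 16000)
  expect_equal(length(out$truth$nucleus_times), 10)
  expect_equal(diff(out$truth$nucleus_times), rep(0.25, 9), tolerance = 1e-9)
  expect_equal(out$truth$rate, 4.0, tolerance = 0.01)
  jit <- ddk_spec("pa", rate = 4, n_syllables = 10,
                  vowel = vowel_spec(duration = 1), rate_jitter = 0.05)
  o1 <- synth_ddk_train(jit, 16000, seed = 3)
  o2 <- synth_ddk_train(jit, 16000, seed = 3)
  expect_identical(o1$truth$nucleus_times, o2$truth$nucleus_times)
  expect_identical(o1$signal$samples, o2$signal$samples)
  expect_error(ddk_spec("pa", rate = 12), "rate")
  expect_error(synth_ddk_train(ddk_spec("pa", rate = 10, gap_fraction = 0.9),
                               16000), "20 ms")
})

test_that("centralization shrinks ground-truth vowel space area by c squared", {
  fx <- small_cohort()
  truth <- fx$gen$truth
  canon_area <- NULL
  for (tr in truth) {
    # reconstruct the pre-shrink area from the stored vertices and factor
    v <- tr$formants
    ctr <- colMeans(v)
    v0 <- sweep(sweep(v, 2, ctr) / tr$centralization, 2, ctr, `+`)
    expect_equal(tr$tvsa, cross_area(v) , tolerance = 1e-9)
    expect_equal(tr$tvsa / cross_area(v0), tr$centralization^2,
                 tolerance = 1e-9)
  }
})

test_that("planted onset rate factors order the ground-truth group medians", {
  fx <- small_cohort()
  truth <- fx$gen$truth
  onset <- vapply(truth, `[[`, character(1), "onset_type")
  med_rate <- function(o) {
    rs <- unlist(lapply(truth[onset == o], function(t)
      unlist(t$rates[c("pa", "ta", "ka")])))
    stats::median(rs)
  }
  expect_lt(med_rate("bulbar"), med_rate("spinal_bulbar"))
  expect_lt(med_rate("spinal_bulbar"), med_rate("spinal_only"))
  expect_lt(med_rate("spinal_bulbar"), med_rate("none"))
})

test_that("generated cohorts have the requested composition and files", {
  fx <- small_cohort()
  coh <- fx$gen$cohort
  expect_equal(nrow(coh), 10)
  expect_equal(sum(coh$group == "ALS"), 7)
  expect_equal(as.vector(table(coh$onset_type)[c("bulbar", "spinal_bulbar",
                                                 "spinal_only")]),
               c(2L, 3L, 2L))
  wavs <- unlist(coh[grep("^wav_", names(coh))])
  expect_length(wavs, 70)
  expect_true(all(file.exists(file.path(fx$dir, wavs))))
  # every WAV has a ground-truth entry
  expect_setequal(names(fx$gen$truth), coh$subject_id)
  # clinical ranges
  als <- coh[coh$group == "ALS", ]
  expect_true(all(als$pumns >= 0 & als$pumns <= 32))
  expect_true(all(als$alsfrs_r_b >= 0 & als$alsfrs_r_b <= 12))
  expect_true(all(als$alsfrs_r <= 48 & als$doss >= 1 & als$doss <= 7))
  expect_true(all(coh$onset_type[coh$group == "HC"] == "none"))
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- cohort_spec(n_hc = 1L, n_bulbar = 1L, n_spinal_bulbar = 1L,
                      n_spinal_only = 0L, n_pumn = 1L,
                      synth_rate = 16000, vowel_duration = 5.5, seed = 77L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("generated audio round-trips through WAV I/O unchanged", {
  fx <- small_cohort()
  coh <- fx$gen$cohort
  p <- file.path(fx$dir, coh$wav_a[1])
  s <- read_wav(p)
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, p2)
  expect_identical(readBin(p2, "raw", file.size(p2))[-(1:44)],
                   readBin(p, "raw", file.size(p))[-(1:44)])
})
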