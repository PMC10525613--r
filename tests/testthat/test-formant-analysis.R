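# LPC fitting, root conversion, formant tracking and phonation time.

test_that("Levinson-Durbin matches hand-computed recursions", {
  m1 <- lpc_from_autocorrelation(c(1.0, 0.5), 1)
  expect_equal(m1$coefficients, 0.5)
  expect_equal(m1$gain, 1 - 0.25)
  m2 <- lpc_from_autocorrelation(c(1.0, 0.5, 0.25), 2)
  expect_equal(m2$coefficients, c(0.5, 0))
  expect_equal(m2$gain, 0.75)
  expect_error(lpc_from_autocorrelation(c(0, 0, 0), 2), "degenerate")
})

test_that("white-noise frames give small reflection coefficients and gain near energy", {
  set.seed(4)
  ok <- replicate(20, {
    x <- stats::rnorm(512)
    m <- lpc_coefficients(x, 8)
    all(abs(m$reflection) < 0.2) && abs(m$gain / sum(x^2) - 1) < 0.2
  })
  expect_gte(mean(ok), 0.95)
  expect_error(lpc_coefficients(rep(0, 100), 8), "all-zero")
  expect_error(lpc_coefficients(rnorm(5), 8), "longer than")
})

test_that("pole pairs round-trip through the prediction polynomial exactly", {
  rate <- 10000
  pole_poly <- function(f, b) {
    r <- exp(-pi * b / rate); th <- 2 * pi * f / rate
    c(1, -2 * r * cos(th), r^2)  # coefficients of 1 - a1 z^-1 - a2 z^-2
  }
  p1 <- pole_poly(700, 80)
  m <- structure(list(order = 2L, coefficients = -p1[2:3], gain = 1),
                 class = "lpc_model")
  got <- formants_from_lpc(m, rate)
  expect_equal(unname(got[, "frequency"]), 700, tolerance = 1e-6)
  expect_equal(unname(got[, "bandwidth"]), 80, tolerance = 1e-6)

  # cascade of two known pairs via polynomial product
  p2 <- pole_poly(1200, 90)
  prod <- convolve(p1, rev(p2), type = "open")
  m2 <- structure(list(order = 4L, coefficients = -prod[2:5], gain = 1),
                  class = "lpc_model")
  got2 <- formants_from_lpc(m2, rate)
  expect_equal(got2[, "frequency"], c(700, 1200), tolerance = 1e-6)
  expect_equal(got2[, "bandwidth"], c(80, 90), tolerance = 1e-6)

  # real roots only -> no formants
  m3 <- structure(list(order = 2L, coefficients = c(1.3, -0.4), gain = 1),
                  class = "lpc_model")
  expect_equal(nrow(formants_from_lpc(m3, rate)), 0)
})

test_that("random pole-pair cascades round-trip within 1e-6 relative error", {
  rate <- 10000
  set.seed(11)
  for (i in 1:25) {
    f <- sort(stats::runif(2, 250, 2400))
    if (diff(f) < 200) next
    b <- stats::runif(2, 40, 200)
    polys <- lapply(1:2, function(j) {
      r <- exp(-pi * b[j] / rate); th <- 2 * pi * f[j] / rate
      c(1, -2 * r * cos(th), r^2)
    })
    prod <- convolve(polys[[1]], rev(polys[[2]]), type = "open")
    m <- structure(list(order = 4L, coefficients = -prod[-1], gain = 1),
                   class = "lpc_model")
    got <- formants_from_lpc(m, rate)
    expect_equal(got[, "frequency"], f, tolerance = 1e-6)
    expect_equal(got[, "bandwidth"], b, tolerance = 1e-6)
  }
})

test_that("formant tracking recovers planted formants of a clean vowel", {
  spec <- vowel_spec(f0 = 120, formants = rbind(c(700, 80), c(1200, 90)),
                     duration = 3)
  sig <- synth_vowel(spec, 44100, seed = 1)
  tr <- track_formants(sig)
  vt <- vowel_targets(tr, vowel = "a")
  expect_lt(abs(vt$F1 - 700), 21)   # 3 %
  expect_lt(abs(vt$F2 - 1200), 36)  # 3 %
  tr2 <- track_formants(sig)
  expect_identical(lapply(tr$formants, I), lapply(tr2$formants, I))
})

test_that("silence yields no voiced frames and vowel_targets refuses it", {
  sig <- audio_signal(rep(0, 20000), 10000)
  tr <- track_formants(sig)
  expect_false(any(tr$voiced))
  expect_true(all(vapply(tr$formants, nrow, integer(1)) == 0))
  expect_error(vowel_targets(tr), "insufficient")
})

test_that("vowel target medians resist single-frame outliers", {
  spec <- vowel_spec(f0 = 120, formants = rbind(c(700, 80), c(1200, 90)),
                     duration = 1.5)
  tr <- track_formants(synth_vowel(spec, 10000, seed = 2))
  base <- vowel_targets(tr)
  mid <- which(tr$voiced)[25]
  tr$formants[[mid]] <- rbind(c(1400, 50), c(2500, 60))
  pert <- vowel_targets(tr)
  expect_lt(abs(pert$F1 - base$F1), 5)
  expect_lt(abs(pert$F2 - base$F2), 5)
})

test_that("formant recovery degrades monotonically with added noise", {
  noise_err <- vapply(c(-Inf, -30, -20), function(nd) {
    errs <- vapply(1:8, function(i) {
      set.seed(100 + i)
      f1 <- stats::runif(1, 300, 800); f2 <- f1 + stats::runif(1, 400, 1200)
      spec <- vowel_spec(f0 = 115, formants = rbind(c(f1, 80), c(f2, 100)),
                         duration = 1, noise_db = nd)
      vt <- vowel_targets(track_formants(synth_vowel(spec, 10000, seed = i)))
      abs(vt$F1 - f1) / f1 + abs(vt$F2 - f2) / f2
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(noise_err) >= -1e-9))
})

test_that("maximum phonation time measures the longest voiced stretch", {
  rate <- 16000
  burst <- synth_vowel(vowel_spec(f0 = 120,
                                  formants = rbind(c(700, 80), c(1200, 90)),
                                  duration = 6), rate, seed = 1)
  pad <- audio_signal(c(rep(0, rate * 0.5), burst$samples, rep(0, rate * 0.5)),
                      rate)
  res <- maximum_phonation_time(pad)
  expect_equal(res$mpt, 6, tolerance = 0.1)
  expect_true(res$eligible)

  short <- audio_signal(c(rep(0, rate), burst$samples[1:(3 * rate)],
                          rep(0, rate)), rate)
  res3 <- maximum_phonation_time(short)
  expect_equal(res3$mpt, 3, tolerance = 0.1)
  expect_false(res3$eligible)

  expect_equal(maximum_phonation_time(audio_signal(rep(0, rate), rate))$mpt, 0)
})
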