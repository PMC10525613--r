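# Source-filter voice synthesis: sustained vowels, DDK syllable trains and
# whole cohorts with stored ground truth.  This is the package's test bed:
# every analysis stage is validated against signals whose formants, nucleus
# times, rates and group structure are known exactly.

#' Specify a synthetic vowel
#'
#' @param f0 Glottal fundamental in Hz (50-400).
#' @param formants Matrix or list of \code{c(frequency, bandwidth)} rows in
#'   Hz, frequencies strictly increasing, bandwidths in (0, 500).  At least
#'   F1 and F2 must be given.
#' @param duration Seconds, positive.
#' @param amplitude Peak target in (0, 1].
#' @param noise_db Additive white-noise level in dB relative to peak
#'   (\code{-Inf} = none).
#' @param glottal_tilt One-pole low-pass coefficient shaping the glottal
#'   pulse train toward the natural voice source spectrum (about -6 dB/oct);
#'   0 leaves the source spectrally flat.
#' @return A \code{vowel_spec} object.
#' @export
vowel_spec <- function(f0 = 120, formants = rbind(c(800, 80), c(1300, 90)),
                       duration = 1, amplitude = 0.9, noise_db = -Inf,
                       glottal_tilt = 0.97) {
  if (is.list(formants)) formants <- do.call(rbind, formants)
  formants <- matrix(as.numeric(formants), ncol = 2L,
                     dimnames = list(NULL, c("frequency", "bandwidth")))
  if (!is.numeric(f0) || f0 < 50 || f0 > 400)
    stop("`f0` must lie in [50, 400] Hz")
  if (nrow(formants) < 2L) stop("at least two formants (F1, F2) are required")
  if (any(diff(formants[, 1L]) <= 0))
    stop("formant frequencies must be strictly increasing")
  if (any(formants[, 2L] <= 0 | formants[, 2L] >= 500))
    stop("formant bandwidths must lie in (0, 500) Hz")
  if (duration <= 0) stop("`duration` must be positive")
  if (amplitude <= 0 || amplitude > 1) stop("`amplitude` must lie in (0, 1]")
  if (glottal_tilt < 0 || glottal_tilt >= 1)
    stop("`glottal_tilt` must lie in [0, 1)")
  structure(list(f0 = f0, formants = formants, duration = duration,
                 amplitude = amplitude, noise_db = noise_db,
                 glottal_tilt = glottal_tilt),
            class = "vowel_spec")
}

#' Specify a DDK syllable train
#'
#' @param syllable Task label: \code{"pa"}, \code{"ta"}, \code{"ka"} or
#'   \code{"pataka"} (for the sequential task each CV unit is one syllable).
#' @param rate Target syllable rate in syllables/second (1-10).
#' @param n_syllables Number of syllables, at least 1.
#' @param vowel A \code{\link{vowel_spec}} for the syllable nucleus (its
#'   \code{duration} field is ignored; burst length follows the rate).
#' @param gap_fraction Fraction of each syllable period that is silent
#'   occlusion, in (0, 1).
#' @param rate_jitter Relative standard deviation of the per-syllable period.
#' @return A \code{ddk_spec} object.
#' @export
ddk_spec <- function(syllable = c("pa", "ta", "ka", "pataka"), rate = 5,
                     n_syllables = 12L, vowel = vowel_spec(),
                     gap_fraction = 0.35, rate_jitter = 0) {
  syllable <- match.arg(syllable)
  if (rate < 1 || rate > 10) stop("`rate` must lie in [1, 10] syllables/s")
  if (n_syllables < 1L) stop("`n_syllables` must be >= 1")
  if (gap_fraction <= 0 || gap_fraction >= 1)
    stop("`gap_fraction` must lie in (0, 1)")
  if (rate_jitter < 0) stop("`rate_jitter` must be >= 0")
  stopifnot(inherits(vowel, "vowel_spec"))
  structure(list(syllable = syllable, rate = rate,
                 n_syllables = as.integer(n_syllables), vowel = vowel,
                 gap_fraction = gap_fraction, rate_jitter = rate_jitter),
            class = "ddk_spec")
}

#' Glottal source: band-limited pulse train
#'
#' Places one pulse per fundamental period at \eqn{t_k = k / f_0}, splitting
#' each pulse linearly across the two neighbouring samples so the train's
#' spectral peaks fall at exact multiples of \code{f0}.
#'
#' @param f0 Fundamental frequency in Hz, \code{0 < f0 < rate / 2}.
#' @param duration Seconds.
#' @param rate Sampling rate in Hz.
#' @return An \code{\link{audio_signal}}.
#' @export
synth_glottal_source <- function(f0, duration, rate) {
  if (!is.numeric(f0) || f0 <= 0) stop("`f0` must be positive")
  if (f0 >= rate / 2) stop("`f0` must be below the Nyquist frequency")
  n <- round(duration * rate)
  s <- numeric(n + 1L)
  k <- 0:ceiling(f0 * duration)
  t <- k / f0
  t <- t[t < duration]
  pos <- t * rate
  i <- floor(pos)
  frac <- pos - i
  lo <- i + 1L
  keep <- lo <= n
  s[lo[keep]] <- s[lo[keep]] + (1 - frac[keep])
  hi <- lo + 1L
  keep <- hi <= n + 1L
  s[hi[keep]] <- s[hi[keep]] + frac[keep]
  audio_signal(s[seq_len(n)], rate)
}

# Cascade of second-order resonators, one per formant row.
# Pole radius r = exp(-pi * B / rate), pole angle 2 * pi * f / rate.
apply_formant_filter <- function(x, formants, rate) {
  for (j in seq_len(nrow(formants))) {
    f <- formants[j, 1L]; b <- formants[j, 2L]
    if (f >= rate / 2) stop(sprintf("formant %g Hz at/above Nyquist", f))
    r <- exp(-pi * b / rate)
    th <- 2 * pi * f / rate
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r * r),
                                  method = "recursive"))
  }
  x
}

# One-pole low-pass giving the pulse train the natural glottal spectral
# slope (about -6 dB/oct); the inverse of the analyzer's pre-emphasis.
shape_glottal <- function(x, tilt) {
  if (tilt <= 0) return(x)
  y <- as.numeric(stats::filter(x, tilt, method = "recursive"))
  y * (1 - tilt)  # keep peak amplitude of order 1
}

raised_cosine_ramp <- function(n_total, n_ramp) {
  env <- rep(1, n_total)
  n_ramp <- min(n_ramp, n_total %/% 2)
  if (n_ramp > 0L) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(n_ramp) / n_ramp)
    env[seq_len(n_ramp)] <- up
    env[n_total + 1L - seq_len(n_ramp)] <- up
  }
  env
}

#' Synthesize a sustained vowel
#'
#' Source-filter synthesis: glottal pulse train filtered through a cascade of
#' second-order resonators (one per formant), peak-normalized to the target
#' amplitude, with optional additive white noise.
#'
#' @param spec A \code{\link{vowel_spec}}.
#' @param rate Sampling rate in Hz; all formant frequencies must be below
#'   \code{rate / 2}.
#' @param seed Optional integer seed making the noise reproducible; the
#'   caller's RNG stream is left untouched.
#' @return An \code{\link{audio_signal}} with peak exactly
#'   \code{spec$amplitude}.
#' @export
synth_vowel <- function(spec, rate = 44100, seed = NULL) {
  stopifnot(inherits(spec, "vowel_spec"))
  with_seed_local(seed, {
    src <- synth_glottal_source(spec$f0, spec$duration, rate)
    y <- shape_glottal(src$samples, spec$glottal_tilt)
    y <- apply_formant_filter(y, spec$formants, rate)
    y <- y * raised_cosine_ramp(length(y), round(0.010 * rate))
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak * spec$amplitude
    if (is.finite(spec$noise_db)) {
      y <- y + stats::rnorm(length(y), 0,
                            spec$amplitude * 10^(spec$noise_db / 20))
      y <- y / max(abs(y)) * spec$amplitude
    }
    audio_signal(y, rate)
  })
}

#' Synthesize a DDK syllable train with ground truth
#'
#' Concatenates \code{n_syllables} units, each a silent occlusion gap of
#' \code{gap_fraction} of the (possibly jittered) period followed by a
#' ramped vowel burst.  The excitation is gated, filtered once through the
#' formant cascade, then re-gated so occlusion gaps are truly silent.
#'
#' @param spec A \code{\link{ddk_spec}}.
#' @param rate Sampling rate in Hz.
#' @param seed Optional integer seed (period jitter and additive noise).
#' @return A list with \code{signal} (an \code{\link{audio_signal}}) and
#'   \code{truth}: \code{nucleus_times} (burst energy centers, s),
#'   \code{onsets}, \code{offsets}, \code{periods}, \code{n} and
#'   \code{rate} (syllables divided by the summed periods; equals
#'   \code{spec$rate} exactly when \code{rate_jitter = 0}).
#' @export
synth_ddk_train <- function(spec, rate = 44100, seed = NULL) {
  stopifnot(inherits(spec, "ddk_spec"))
  period <- 1 / spec$rate
  if ((1 - spec$gap_fraction) * period < 0.020)
    stop("burst would be shorter than 20 ms; lower `rate` or `gap_fraction`")
  with_seed_local(seed, {
    n <- spec$n_syllables
    periods <- period * (1 + spec$rate_jitter * stats::rnorm(n))
    periods <- pmax(periods, 0.5 * period)
    starts <- c(0, cumsum(periods))[seq_len(n)]
    onsets <- starts + spec$gap_fraction * periods
    offsets <- starts + periods
    total <- sum(periods) + 0.05  # small tail
    n_samp <- round(total * rate)

    src <- shape_glottal(synth_glottal_source(spec$vowel$f0, total, rate)$samples,
                         spec$vowel$glottal_tilt)
    gate <- numeric(n_samp)
    for (k in seq_len(n)) {
      i0 <- max(1L, floor(onsets[k] * rate) + 1L)
      i1 <- min(n_samp, floor(offsets[k] * rate))
      nb <- i1 - i0 + 1L
      if (nb > 0L)
        gate[i0:i1] <- raised_cosine_ramp(nb, round(0.15 * nb))
    }
    y <- apply_formant_filter(src * gate, spec$vowel$formants, rate)
    y <- y * gate
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak * spec$vowel$amplitude
    if (is.finite(spec$vowel$noise_db)) {
      y <- y + stats::rnorm(length(y), 0,
                            spec$vowel$amplitude * 10^(spec$vowel$noise_db / 20))
      y <- y / max(abs(y)) * spec$vowel$amplitude
    }
    truth <- list(nucleus_times = (onsets + offsets) / 2,
                  onsets = onsets, offsets = offsets, periods = periods,
                  n = n, rate = n / sum(periods), syllable = spec$syllable)
    list(signal = audio_signal(y, rate), truth = truth)
  })
}

# sample() that never falls into the scalar 1:x trap.
resample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

# Canonical corner-vowel targets (adult male baseline), Hz.
canonical_vowel_targets <- function() {
  rbind(a = c(F1 = 800, F2 = 1300),
        i = c(F1 = 300, F2 = 2300),
        u = c(F1 = 350, F2 = 800))
}

#' Specify a synthetic cohort
#'
#' Defines the composition and planted effect structure of a synthetic
#' case-control cohort: healthy controls plus patients stratified by site of
#' onset (bulbar, spinal with bulbar symptoms, spinal only) and by prevalent
#' upper vs lower motor-neuron impairment (pUMN/pLMN).  Vowel formants are
#' drawn from canonical corner-vowel targets with inter-speaker noise, then
#' shrunk toward their centroid by the group's \code{centralization} factor
#' (a factor \eqn{c} scales the true vowel-space area by exactly
#' \eqn{c^2}).  DDK rates are a healthy base rate times the onset group's
#' \code{rate_factor}, further slowed in proportion to the UMN burden score,
#' plus noise.  Clinical scores are generated by a linear monotone link from
#' the planted bulbar deficit with additive Gaussian noise, clipped and
#' rounded to each scale's range.
#'
#' @param n_hc,n_bulbar,n_spinal_bulbar,n_spinal_only Group sizes.
#' @param n_pumn Number of patients planted as prevalent-UMN; the rest are
#'   prevalent-LMN.  UMN-burden scores are generated so that a median split
#'   (ties to the high group) recovers the planted classes.
#' @param centralization Named factors in (0, 1] for \code{HC}, \code{pUMN},
#'   \code{pLMN}: multiplicative shrink of formant deviations toward the
#'   per-speaker centroid.
#' @param rate_factor Named factors in (0, 1] for \code{HC}, \code{bulbar},
#'   \code{spinal_bulbar}, \code{spinal_only}: multiplicative DDK rate
#'   reduction.
#' @param umn_rate_slowing Additional fractional rate slowing per unit of
#'   normalized UMN burden (score/32).
#' @param base_amr,base_smr Healthy base rates, syllables/s.
#' @param vowel_duration Sustained-vowel duration in seconds.
#' @param n_syll_amr Syllables per single-syllable DDK train.
#' @param n_units_smr /pataka/ repetitions (each contributes 3 syllables).
#' @param gap_fraction,rate_jitter,noise_db Passed to the synthesizer.
#' @param speaker_sd Inter-speaker formant SD in Hz.
#' @param rate_noise_sd Per-subject rate noise SD, syllables/s.
#' @param clinical_noise_sd Noise SD of the clinical-score link, scale points.
#' @param synth_rate Sampling rate of the generated WAV files, Hz.
#' @param seed Integer RNG seed; a fixed seed makes outputs byte-identical.
#' @return A \code{cohort_spec} object.
#' @export
cohort_spec <- function(n_hc = 20L, n_bulbar = 8L, n_spinal_bulbar = 21L,
                        n_spinal_only = 7L, n_pumn = 23L,
                        centralization = c(HC = 1, pUMN = 0.75, pLMN = 0.95),
                        rate_factor = c(HC = 1, bulbar = 0.65,
                                        spinal_bulbar = 0.80,
                                        spinal_only = 0.95),
                        umn_rate_slowing = 0.45,
                        base_amr = 6.0, base_smr = 6.5,
                        vowel_duration = 5.5,
                        n_syll_amr = 13L, n_units_smr = 5L,
                        gap_fraction = 0.35, rate_jitter = 0.04,
                        noise_db = -40,
                        speaker_sd = 40, rate_noise_sd = 0.25,
                        clinical_noise_sd = 1.0,
                        synth_rate = 44100, seed = 1L) {
  n_als <- n_bulbar + n_spinal_bulbar + n_spinal_only
  if (any(c(n_hc, n_bulbar, n_spinal_bulbar, n_spinal_only) < 0))
    stop("group sizes must be >= 0")
  if (n_pumn > n_als) stop("`n_pumn` cannot exceed the number of patients")
  stopifnot(all(centralization > 0 & centralization <= 1),
            all(rate_factor > 0 & rate_factor <= 1))
  need_c <- c("HC", "pUMN", "pLMN"); need_r <- c("HC", "bulbar",
              "spinal_bulbar", "spinal_only")
  if (!all(need_c %in% names(centralization)))
    stop("`centralization` must name HC, pUMN, pLMN")
  if (!all(need_r %in% names(rate_factor)))
    stop("`rate_factor` must name HC, bulbar, spinal_bulbar, spinal_only")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with audio and ground truth
#'
#' Writes, per subject, WAV recordings of the sustained vowels /a:/, /i:/,
#' /u:/ and the DDK tasks /pa/, /ta/, /ka/, /pataka/, plus a cohort CSV with
#' clinical covariates and a ground-truth JSON.  All randomness derives from
#' \code{spec$seed}: the same spec yields byte-identical files.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with \code{cohort} (data frame, one row per
#'   subject), \code{truth} (per-subject ground truth) and \code{dir}.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))

  with_seed_local(spec$seed, {
    n_als <- spec$n_bulbar + spec$n_spinal_bulbar + spec$n_spinal_only
    n_all <- n_als + spec$n_hc
    onset <- c(rep("bulbar", spec$n_bulbar),
               rep("spinal_bulbar", spec$n_spinal_bulbar),
               rep("spinal_only", spec$n_spinal_only))
    onset <- sample(onset)
    ids <- c(sprintf("ALS%02d", seq_len(n_als)),
             sprintf("HC%02d", seq_len(spec$n_hc)))
    group <- c(rep("ALS", n_als), rep("HC", spec$n_hc))
    onset_all <- c(onset, rep("none", spec$n_hc))

    # Planted pUMN/pLMN classes, stratified across onset strata so the two
    # UMN classes carry the same onset mix (UMN burden and onset site are
    # modeled as independent).  Enough pUMN scores are tied at the cut
    # value that the downstream median split (ties to high) recovers the
    # planted classes exactly.
    is_pumn <- rep(FALSE, n_als)
    if (n_als > 0 && spec$n_pumn > 0) {
      frac <- spec$n_pumn / n_als
      chosen <- integer(0)
      for (o in unique(onset)) {
        idx <- which(onset == o)
        k <- round(length(idx) * frac)
        if (k > 0) chosen <- c(chosen, resample_vec(idx, min(k, length(idx))))
      }
      while (length(chosen) > spec$n_pumn)
        chosen <- chosen[-sample.int(length(chosen), 1L)]
      remaining <- setdiff(seq_len(n_als), chosen)
      if (length(chosen) < spec$n_pumn)
        chosen <- c(chosen, resample_vec(remaining, spec$n_pumn - length(chosen)))
      is_pumn[chosen] <- TRUE
    }
    n_plmn <- n_als - spec$n_pumn
    pumns <- integer(n_als)
    if (n_plmn > 0)
      pumns[!is_pumn] <- sample(4:12, n_plmn, replace = TRUE)
    if (spec$n_pumn > 0) {
      k_tie <- min(spec$n_pumn, max(1L, n_als %/% 2L + 1L - n_plmn))
      hi_scores <- c(rep(13L, k_tie),
                     sample(14:20, spec$n_pumn - k_tie, replace = TRUE))
      pumns[is_pumn] <- resample_vec(hi_scores)
    }

    sex <- sample(c("M", "F"), n_all, replace = TRUE, prob = c(2, 1) / 3)
    age <- round(clamp(stats::rnorm(n_all, 62, 8), 35, 85))
    dis_dur <- c(round(clamp(stats::rlnorm(n_als, log(30), 1.0), 2, 200)),
                 rep(NA_real_, spec$n_hc))

    umn_class <- c(ifelse(is_pumn, "pUMN", "pLMN"), rep("HC", spec$n_hc))
    cfac <- ifelse(group == "HC", spec$centralization[["HC"]],
                   ifelse(umn_class == "pUMN", spec$centralization[["pUMN"]],
                          spec$centralization[["pLMN"]]))
    rfac <- ifelse(group == "HC", spec$rate_factor[["HC"]],
                   spec$rate_factor[onset_all])
    pumns_all <- c(pumns, rep(0L, spec$n_hc))
    slow <- 1 - spec$umn_rate_slowing * pumns_all / 32

    # Planted bulbar deficit drives the clinical scores (patients only).
    deficit <- 1 - rfac * slow
    alsfrs_b <- clamp(round(12 - 8 * deficit[seq_len(n_als)] +
                              stats::rnorm(n_als, 0, spec$clinical_noise_sd)),
                      0, 12)
    alsfrs_rest <- clamp(round(stats::rnorm(n_als, 25, 4)), 0, 36)
    alsfrs_r <- alsfrs_b + alsfrs_rest
    doss <- clamp(round(7 - 6 * deficit[seq_len(n_als)] +
                          stats::rnorm(n_als, 0, 0.7)), 1, 7)
    dras <- clamp(round(6 + 28 * deficit[seq_len(n_als)] +
                          stats::rnorm(n_als, 0, 2)), 0, 34)

    canon <- canonical_vowel_targets()
    tasks <- c("a", "i", "u", "pa", "ta", "ka", "pataka")
    wav_cols <- stats::setNames(vector("list", length(tasks)),
                                paste0("wav_", tasks))
    for (nm in names(wav_cols)) wav_cols[[nm]] <- character(n_all)
    truth <- vector("list", n_all)
    names(truth) <- ids
    task_mult <- c(pa = 1.0, ta = 0.98, ka = 0.93)

    for (s in seq_len(n_all)) {
      f0 <- if (sex[s] == "M") stats::runif(1, 100, 140) else
        stats::runif(1, 180, 220)
      fshift <- if (sex[s] == "M") 1 else 1.12
      base <- canon * fshift +
        matrix(stats::rnorm(6, 0, spec$speaker_sd), nrow = 3)
      centroid <- colMeans(base)
      verts <- sweep(sweep(base, 2, centroid) * cfac[s], 2, centroid, `+`)
      dimnames(verts) <- dimnames(canon)

      sub_truth <- list(subject_id = ids[s], group = group[s],
                        onset_type = onset_all[s], umn_class = umn_class[s],
                        centralization = cfac[s],
                        formants = verts,
                        tvsa = triangle_area(verts),
                        rates = list(), nuclei = list())

      for (v in c("a", "i", "u")) {
        bw1 <- stats::runif(1, 60, 110); bw2 <- stats::runif(1, 70, 130)
        vs <- vowel_spec(f0 = f0,
                         formants = rbind(c(verts[v, 1L], bw1),
                                          c(verts[v, 2L], bw2)),
                         duration = spec$vowel_duration,
                         amplitude = 0.9, noise_db = spec$noise_db)
        sig <- synth_vowel(vs, spec$synth_rate)
        p <- file.path(out_dir, sprintf("%s_%s.wav", ids[s], v))
        write_wav(sig, p)
        wav_cols[[paste0("wav_", v)]][s] <- basename(p)
      }

      bwn1 <- stats::runif(1, 60, 110); bwn2 <- stats::runif(1, 70, 130)
      nucleus <- vowel_spec(f0 = f0,
                            formants = rbind(c(verts["a", 1L], bwn1),
                                             c(verts["a", 2L], bwn2)),
                            duration = 1, amplitude = 0.9,
                            noise_db = spec$noise_db)
      for (task in c("pa", "ta", "ka", "pataka")) {
        base_rate <- if (task == "pataka") spec$base_smr else
          spec$base_amr * task_mult[[task]]
        true_rate <- clamp(base_rate * rfac[s] * slow[s] +
                             stats::rnorm(1, 0, spec$rate_noise_sd),
                           1.5, 9)
        n_syll <- if (task == "pataka") 3L * spec$n_units_smr else
          spec$n_syll_amr
        ds <- ddk_spec(syllable = if (task == "pataka") "pataka" else task,
                       rate = true_rate, n_syllables = n_syll,
                       vowel = nucleus, gap_fraction = spec$gap_fraction,
                       rate_jitter = spec$rate_jitter)
        out <- synth_ddk_train(ds, spec$synth_rate)
        p <- file.path(out_dir, sprintf("%s_%s.wav", ids[s], task))
        write_wav(out$signal, p)
        wav_cols[[paste0("wav_", task)]][s] <- basename(p)
        sub_truth$rates[[task]] <- out$truth$rate
        sub_truth$nuclei[[task]] <- out$truth$nucleus_times
      }
      truth[[s]] <- sub_truth
    }

    cohort <- data.frame(
      subject_id = ids, group = group, onset_type = onset_all,
      sex = sex, age = age, disease_duration = dis_dur,
      pumns = c(pumns, rep(NA_integer_, spec$n_hc)),
      alsfrs_r = c(alsfrs_r, rep(NA_real_, spec$n_hc)),
      alsfrs_r_b = c(alsfrs_b, rep(NA_real_, spec$n_hc)),
      doss = c(doss, rep(NA_real_, spec$n_hc)),
      dras = c(dras, rep(NA_real_, spec$n_hc)),
      stringsAsFactors = FALSE)
    for (nm in names(wav_cols)) cohort[[nm]] <- wav_cols[[nm]]

    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(cohort = cohort, truth = truth, dir = out_dir))
  })
}

# Shoelace area of a 3 x 2 vertex matrix (used for ground truth).
triangle_area <- function(v) {
  abs(v[1, 1] * (v[2, 2] - v[3, 2]) +
      v[2, 1] * (v[3, 2] - v[1, 2]) +
      v[3, 1] * (v[1, 2] - v[2, 2])) / 2
}
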