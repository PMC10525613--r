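# motorspeech

Acoustic voice biomarkers for motor speech phenotyping in R.

Clinicians assessing dysarthria — for example distinguishing the spastic
(upper motor-neuron) from the flaccid (lower motor-neuron) speech phenotype
in ALS — increasingly rely on two objective acoustic measures:

* **tVSA**, the triangular vowel space area: the area (Hz²) of the triangle
  spanned by the first two formants (F1, F2) of the corner vowels /a/, /i/,
  /u/,

  `tVSA = |F1_i (F2_a − F2_u) + F1_a (F2_u − F2_i) + F1_u (F2_i − F2_a)| / 2`.

  Formant centralization in dysarthria compresses the area.
* **AMR/SMR**, the alternating and sequential motion rates of oral
  diadochokinesis: the maximum repetition rate of /pa/, /ta/, /ka/ (AMR)
  and of the sequence /pataka/ (SMR), measured as nine consecutive
  syllables divided by their elapsed duration, in syllables/second.

`motorspeech` turns raw mono WAV recordings into these biomarkers and runs
the cohort-level statistics used in phenotype studies:

* LPC formant estimation (autocorrelation method, Levinson–Durbin, pole
  root-solving) with maximum-phonation-time gating (> 5 s) of the vowel
  protocol;
* envelope-based syllable nucleus detection for DDK recordings;
* Mann–Whitney contrasts (exact for small tie-free samples), Spearman
  correlations with clinical scales (UMN burden, ALSFRS-r and its bulbar
  subscore, DOSS, DRAS), median-split pUMN/pLMN grouping, and ROC/AUC with
  class-stratified bootstrap confidence intervals;
* a source-filter voice synthesizer that generates entire cohorts — vowels
  with group-dependent formant centralization, DDK trains with
  group-dependent slowing, clinical scores linked to the planted deficits —
  with exact ground truth, so the whole pipeline is validated end to end.

## Worked example

Synthesize the three corner vowels of a healthy speaker, estimate their
formant targets, and compute the vowel space area:

```r
library(motorspeech)

targets <- lapply(list(a = c(800, 1300), i = c(300, 2300), u = c(350, 800)),
  function(fv) {
    spec <- vowel_spec(f0 = 120, formants = rbind(c(fv[1], 80), c(fv[2], 95)),
                       duration = 5.5, noise_db = -40)
    sig <- synth_vowel(spec, 44100, seed = 1)       # 44.1 kHz mono audio
    vowel_targets(track_formants(sig))              # LPC formant targets
  })
targets$a
#> <vowel_formants: F1 = 812 Hz, F2 = 1320 Hz (274 frames)>

tvsa(targets$a, targets$i, targets$u)
#> <tvsa_result: 345222 Hz^2>
```

The planted triangle has area 350,000 Hz²; the full analysis chain
(synthesis → WAV-grade audio → LPC → area) recovers it within 1.4%.

A DDK train at a planted 4.2 syllables/s:

```r
train <- synth_ddk_train(ddk_spec("pa", rate = 4.2, n_syllables = 13,
                                  rate_jitter = 0.04,
                                  vowel = vowel_spec(noise_db = -40)),
                         44100, seed = 2)
seg <- detect_syllable_nuclei(amplitude_envelope(train$signal))
articulation_rate(seg, 9, task = "pa")
#> <articulation_rate /pa/: 4.1 syll/s (9 syllables / 2.17 s)>
round(train$truth$rate, 2)   # jittered realized rate
#> [1] 4.16
```

Group contrasts use the same conventions as the clinical literature:

```r
mann_whitney_u(c(1.9, 2.4, 2.8, 3.1), c(3.6, 3.9, 4.4, 4.8, 5.2))
#> <Mann-Whitney U = 0 (n = 4 vs 5), p = 0.01587 [exact]>
```

## Whole-cohort pipeline

The CLI chains synthesis, extraction and analysis:

```sh
Rscript inst/scripts/motorspeech.R all --seed 7 --out-dir out/
```

`out/` then contains the per-subject WAVs, `cohort.csv` (clinical
covariates), `features.csv` (tVSA, AMR /pa/ /ta/ /ka/, SMR /pataka/, MPT),
`report.json` / `results.csv` (all contrasts, correlations and ROC
results) and per-feature ROC curve CSVs.  Identical seeds give
byte-identical outputs.  The same steps are available programmatically via
`generate_cohort()`, `extract_cohort_features()` and `run_analysis()`.

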