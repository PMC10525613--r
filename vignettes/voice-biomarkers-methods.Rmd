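---
title: "Acoustic voice biomarkers for motor speech phenotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic voice biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(motorspeech)
```

## The clinical problem

Most people with amyotrophic lateral sclerosis (ALS) lose intelligible
speech as the disease progresses.  Distinguishing the *spastic* dysarthria
of upper motor-neuron (UMN) involvement from the *flaccid* dysarthria of
lower motor-neuron (LMN) involvement is clinically important but hard at
the bedside.  Two families of acoustic measures are candidates for
objective biomarkers:

* **Triangular vowel space area (tVSA)** — the area of the triangle spanned
  by the first two formant frequencies (F1, F2) of the corner vowels /a/,
  /i/, /u/.  Dysarthria compresses articulatory excursions, centralizing
  formants and shrinking the area.
* **Oral diadochokinesis (DDK) rates** — the alternating motion rate (AMR:
  repetition of /pa/, /ta/ or /ka/) and sequential motion rate (SMR:
  repetition of /pataka/), in syllables per second.  Slowed rates track
  bulbar motor impairment.

This package computes both families from raw mono WAV recordings, applies
the nonparametric statistical program used in clinical phenotype studies
(Mann–Whitney contrasts, Spearman correlations with clinical scales,
median-split grouping by UMN burden, ROC discrimination), and ships a
source-filter voice synthesizer that generates whole cohorts with known
ground truth so that every stage can be validated end to end.

## Formant estimation

Sustained vowels are resampled to an analysis rate of 10 kHz, pre-emphasized
(`y[n] = x[n] - 0.97 x[n-1]`), and sliced into 25 ms Hamming frames at a
10 ms hop.  Each voiced frame is fitted with a linear-prediction (LPC)
model by the autocorrelation method (Levinson–Durbin recursion); the order
follows the one-pole-pair-per-kilohertz rule, `2 + rate/1000 = 12`.  The
prediction polynomial's complex roots give formant candidates: a pole with
angle θ and radius ρ maps to frequency `θ·rate/2π` and bandwidth
`-(rate/π)·ln ρ`.  Candidates are admitted when their frequency lies in
(90 Hz, Nyquist − 50 Hz) and their bandwidth is below 400 Hz — a
conventional, Praat-like heuristic that rejects spurious low-frequency and
edge roots.

Per-vowel targets are the **medians** of the first and second admitted
formants over the central 50% of the voiced span.  The median resists
onset/offset transitions and single-frame tracking errors; the central-span
restriction avoids the amplitude ramps at phonation boundaries.

**Voicing rule.**  A frame is voiced when its RMS level exceeds
`max(peak level − 25 dB, −55 dBFS)`.  An earlier design keyed the threshold
to the 5th percentile of frame levels (+20 dB); that estimator is fine for
recordings that contain silence but degenerates on *fully voiced* files —
a 5.5 s sustained vowel has its 5th percentile at the voiced level, so no
frame clears it and the phonation time would read zero.  The peak-relative
rule handles both cases and is what the package uses everywhere; the DDK
detector still estimates its silence floor from the 5th percentile because
DDK recordings always contain occlusion gaps.

**Maximum phonation time (MPT)** is the longest contiguous voiced region,
bridging unvoiced gaps up to 150 ms; subjects enter the vowel protocol only
when MPT exceeds 5 s.  Subjects failing the gate keep their DDK features —
only the vowel protocol is gated.

**Known limitation.**  LPC formant estimates degrade as the fundamental
frequency rises, because the spectral envelope is sampled only at the
harmonics.  With the package's defaults, recovery of F1 ≈ 250–300 Hz is
accurate to a few Hz at male f0 (100–140 Hz) but biased by up to ~30 Hz at
f0 ≈ 200 Hz.  This is a well-known property of LPC analysis, not of this
implementation; validation batches therefore characterize recovery at male
baseline f0 and treat high-pitch performance as a documented limitation.

## Vowel space area

With per-vowel targets `(F1_v, F2_v)`,

```
tVSA = |F1_i (F2_a − F2_u) + F1_a (F2_u − F2_i) + F1_u (F2_i − F2_a)| / 2
```

in Hz².  The absolute value makes the area independent of vertex
orientation (the printed shoelace form can be negative).  No Bark/mel
scaling is applied.  Two properties anchor the tests: the area is invariant
under vertex permutation, and shrinking all formant deviations from the
triangle centroid by a factor *c* scales the area by exactly *c²* — the
property the synthetic cohort's centralization factor exploits.

## DDK segmentation and rates

The amplitude envelope is per-frame RMS in dBFS (20 ms frames, 5 ms hop,
floored at −80 dB) smoothed by a ~50 ms moving average.  Envelope local
maxima are accepted as syllable nuclei when they

1. exceed the recording's silence floor (5th percentile of levels) by
   10 dB,
2. have at least 3 dB of **topographic prominence** — the rise above the
   higher of the two troughs reached before the next higher envelope point
   on each side, and
3. fall at least 90 ms after the previously accepted nucleus.

Topographic prominence (rather than prominence relative to the immediately
adjacent local trough) matters in practice: smoothed envelopes carry ripple
on top of each burst, and measuring against the nearest micro-trough would
reject every genuine nucleus.  All three thresholds are configurable
(`ddk_config()`).

The articulation rate follows the clinical convention: nine consecutive
syllables divided by their elapsed duration, reported to one decimal
(half-away-from-zero).  The span runs from the trough boundary before the
first selected syllable to the trough boundary after the ninth, so
inter-syllable gaps count toward the duration.  Nuclei within the first
250 ms are excluded as initiation transient; the first nine eligible
consecutive nuclei are used.  For /pataka/, each CV unit counts as one
syllable, so rates for AMR and SMR share one syllables-per-second axis.
Full-precision rates feed the statistics by default; `--round-rates`
switches to the one-decimal reported form.

## Statistics

* **Mann–Whitney U**: U counts (x, y) pairs with x > y, ties one half.
  The two-sided p is exact when the smaller group has ≤ 8 observations and
  no ties are present, otherwise a normal approximation with tie and
  continuity corrections is used (delegated to `stats::wilcox.test`; the
  test suite checks the exact branch against full enumeration of all label
  assignments).
* **Spearman**: Pearson correlation of mid-ranks; p from the t
  approximation `t = ρ√((n−2)/(1−ρ²))`; ρ = ±1 is reported at the
  permutation bound 2/n!.
* **ROC/AUC**: the rank formula (identical to U/(n₊·n₋)); the confidence
  interval is a class-stratified percentile bootstrap (2000 resamples by
  default).  Score orientation is declared per feature: for tVSA and all
  rates, *lower* values indicate the prevalent-UMN class.
* **Median split**: subjects at or above the midpoint-interpolated median
  of the UMN-burden score form the pUMN group.  A score exactly at the cut
  goes to the high group — with integer clinical scores ties at the median
  are common, and this convention is what makes unequal splits (such as
  23 vs 13) possible at a median cut-off.
* No multiplicity adjustment is applied; raw p-values are reported.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

* **Vowels.**  Canonical corner-vowel targets (adult male baseline):
  /a/ (800, 1300), /i/ (300, 2300), /u/ (350, 800) Hz, with inter-speaker
  Gaussian variation (SD 40 Hz) and a +12% formant shift for female
  speakers; f0 is drawn uniformly from 100–140 Hz (male) or 180–220 Hz
  (female) with a 2:1 male:female ratio.  Each subject's three vowel
  vertices are shrunk toward their centroid by the group's centralization
  factor (healthy 1.0, prevalent-LMN 0.95, prevalent-UMN 0.75), so the
  planted tVSA scales by the factor squared.
* **Source-filter synthesis.**  The glottal source is a band-limited pulse
  train shaped by a one-pole low-pass (coefficient 0.97), giving the
  natural ≈ −6 dB/octave voice spectrum; the analyzer's pre-emphasis is its
  exact inverse.  Formants are cascaded second-order resonators.  White
  recording noise is added at −40 dB relative to peak, which leaves ≈ 30 dB
  of signal-to-noise ratio in the formant region — representative of a
  quiet clinical recording setup.
* **DDK trains.**  Healthy base rates are 6.0 syll/s (AMR) and 6.5 syll/s
  (/pataka/ units), with task factors (/ta/ 0.98, /ka/ 0.93), reduced
  multiplicatively by onset group (bulbar 0.65, spinal-with-bulbar 0.80,
  spinal-only 0.95) and slowed further in proportion to the UMN-burden
  score (up to 45% at the scale maximum — calibrated so that rate features
  discriminate UMN classes at clinically reported strength, AUC ≈ 0.7).
  Per-syllable periods carry 4% jitter; occlusion gaps are 35% of the
  period.
* **Clinical scores.**  A planted bulbar deficit (one minus the realized
  rate factor) maps linearly, with Gaussian noise, onto the bulbar
  functional subscore (0–12), dysphagia severity (DOSS, 1–7, decreasing)
  and dysphagia risk (DRAS, increasing), then is clipped and rounded to
  each scale's range; linearity is the simplest monotone link consistent
  with sign-level clinical knowledge.  UMN class is assigned *stratified
  across onset strata* (burden and onset site are modeled as independent),
  and enough prevalent-UMN subjects sit exactly at the burden cut value
  that the median split downstream recovers the planted classes.
* **What it does not emulate.**  No consonant acoustics, coarticulation,
  vibrato, amplitude drift, room reverberation, or non-white noise; bursts
  are stylized CV units sufficient for envelope-based detection.  Passing
  tests demonstrate correct *measurement* under the stated generative
  model, not performance on real clinical audio.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(enumeration of Mann–Whitney null distributions, pair-counting AUC,
cross-product triangle areas, FFT/cepstral spectral measurements) and then
closes the loop end to end:

* One full-size cohort (8 bulbar / 21 spinal-with-bulbar / 7 spinal-only
  patients + 20 controls, 44.1 kHz audio) must reproduce the planted
  phenotype structure: compressed tVSA in the prevalent-UMN group
  (p < 0.05, AUC ≥ 0.75) and rate medians ordered bulbar <
  spinal-with-bulbar < spinal-only.
* A replicate study of 100 seeded cohorts checks that the *direction* of
  every planted effect is recovered in at least 95% of replicates.  The
  replicates use a scaled design — 5/6/5 patients + 5 controls, 20 kHz
  synthesis, 20 ms analysis hop — chosen so the whole study runs in
  minutes while keeping each planted effect identifiable at its default
  size.  Group-level plants (case–control differences, onset ordering,
  UMN centralization) are checked on group medians; the UMN rate-slowing
  plant is a monotone link, so it is checked by the sign of the Spearman
  correlation between each rate and the burden score, its direct
  statistical image.
* Determinism: the command-line `all` pipeline run twice with the same
  seed must produce byte-identical cohort, feature and report files.

## Numerical choices

* Integer-ratio resampling uses a zero-phase 64-tap FIR low-pass at 0.9 of
  the output Nyquist (FFT convolution); general rational ratios use
  polyphase resampling (`signal::resample`).  Both are anti-aliased.
* WAV I/O supports 8/16/24/32-bit integer PCM and 32-bit float, averaging
  multi-channel input to mono; 16-bit round-trips are exact to one LSB.
* The Levinson–Durbin recursion is run vectorized across all frames of a
  recording (numerically identical to the per-frame recursion); frames
  with non-positive-definite autocorrelation are marked unvoiced rather
  than erroring.
* Envelope smoothing pads with edge values, so a constant envelope stays
  constant at the boundaries.
* Percentile-bootstrap CIs are clamped to bracket the point estimate in
  the rare degenerate resample; quantiles use the default type-7
  interpolation throughout, matching the median/IQR summaries.
* Degenerate inputs are first-class: silence segments to an empty
  segmentation (not an error), an all-equal median split sends every
  subject to the high group, and a failed task leaves an NA feature with a
  recorded note instead of aborting the subject.
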