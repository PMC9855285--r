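---
title: "Methods: simulating and measuring contralateral delay activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring contralateral delay activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdafilter)
```

## The measurement model

In a lateralized change-detection task, an arrow cue directs the
participant to memorize items in one visual hemifield. During the
maintenance interval, posterior electrodes contralateral to the memorized
hemifield show a sustained negativity relative to ipsilateral electrodes —
the contralateral delay activity (CDA) — whose amplitude grows with the
number of items held in visual working memory (VWM). Face distractors
presented alongside the targets should, if successfully filtered,
contribute nothing to this signal; a more negative CDA in a distractor
condition than in a no-distractor baseline therefore indicates unnecessary
storage of the distractors.

`cdafilter` measures this as follows. For each condition, the
contralateral waveform averages left-hemisphere sites on cue-right trials
together with right-hemisphere sites on cue-left trials over the pairs
P7/P8, P9/P10 and PO7/PO8; the ipsilateral waveform uses the complementary
assignment. The CDA amplitude is the mean of the difference wave
(contra − ipsi) over 500–1000 ms after memory-array onset, endpoints
inclusive on the sampling grid, and the per-participant difference score
is `distractor − non-distractor`.

Two choices here were genuinely open and are worth stating:

* **Averaging order.** Trials are averaged within each cue side first,
  then sites, then the two cue sides with equal weight. Artifact rejection
  can leave unequal trial counts on the two cue sides; weighting the sides
  equally prevents that imbalance from leaking into the contra/ipsi
  contrast. A trials-pooled average would weight sides by surviving count.
* **Window convention.** Both window endpoints are inclusive, so
  −200..1100 ms at 1000 Hz is 1301 samples and 500–1000 ms averages 501
  samples. All window means in the package share this convention.

## Preprocessing chain

The chain is interpolation → average reference → low-pass → epoching →
baseline, in that fixed order (`preprocess_continuous()`; the epoched
shortcut `preprocess_epochs()` is tested to agree away from epoch edges).

* **Interpolation** replaces a bad channel by the unweighted mean of its
  good neighbors from a user-supplied adjacency map. This is the simplest
  topographic estimate; spherical splines would be a natural extension but
  the difference is immaterial for channels that never enter the montage.
* **Average reference** subtracts the per-sample mean of all scalp
  channels. The bipolar HEOG is excluded from both the average and the
  re-referencing — standard practice, since an ocular bipolar channel is
  not a scalp potential. Note the contra − ipsi difference is invariant to
  any common-mode subtraction, so this choice cannot bias the CDA.
* **Low-pass filter.** Only the cutoff (17 Hz) is a fixed analysis
  parameter; the realization is this package's choice: a linear-phase FIR
  (Hamming window) with a 17→25 Hz transition band, order ≈ 3.3/Δf ≈ 412,
  applied non-causally with group-delay compensation and mirror padding,
  and normalized to DC gain exactly 1. Measured behaviour: a 2-Hz tone
  passes within 2% with zero phase lag; a 50-Hz tone is attenuated below
  10% (in fact ≈ −50 dB). Because window means are low-frequency
  functionals, the downstream statistics are robust to the exact filter
  family.
* **Baseline** subtracts each channel's mean over −200..0 ms; idempotent
  by construction.

## Artifact rejection

Thresholds are read literally as strict inequalities on the epoch
extremum: a trial is rejected if |HEOG| > 60 µV at any sample (lateral eye
movements move the eyes toward the cued side, so such trials have
mislocalized stimulation), or if any scalp channel exceeds ±80 µV. A
peak-to-peak variant is available (`mode = "peak_to_peak"`). Both flags
are computed over the full epoch including the baseline, independently of
each other, and reported separately (rejection-rate tables use the HEOG
rule alone); a trial failing either flag is excluded from averaging.
Participants are excluded when their combined rejection rate is strictly
above 30% — exactly 30% is retained. Whether the exclusion rate should
count HEOG-only or combined rejections is not standardized; combined is
the default here and the policy object makes either auditable.

## Behavioral measures and the slots model

Capacity is Cowan's `K = N(H − F)` with `N = 6` for the separate VWM
measurement, unclamped (negative estimates are data, not errors), and
sensitivity is `d′ = Z(H) − Z(F)`. Extreme rates under `d′` are replaced
by `1/(2n)` and `1 − 1/(2n)` by default; the study's own rates were
interior, so this correction only matters for simulated ceiling cases.

The generator inverts the slots model: `k` of `N` items are stored
perfectly; a probed stored item yields the correct response; otherwise the
participant guesses "change" with probability `g` (default 0.5). This
gives `H = k/N + (1 − k/N)g` and `F = (1 − k/N)g`, so `E[K̂] = k` — the
estimator is unbiased under its own generative model, which the suite
verifies by Monte Carlo (2000 replicates of 100 trials at
k ∈ {0, 1.5, 3, 4.5, 6}, agreement within 3 Monte-Carlo SEs). A lapse
parameter flips responses to a coin toss; the filtering task uses lapse
0.1 with target load 2, which reproduces the ~90–95% accuracy scale
typical of this task. Stored-distractor slots (distractors competing for
capacity) are off by default: no behavioral generative model for them is
established, and the CDA, not accuracy, is the filtering measure.

## The synthetic EEG generator

The generator's defaults are the study conditions: 1000-Hz sampling,
−200..1100 ms epochs, 3 conditions × 200 trials in 12 blocks with change
and cue side exactly counterbalanced (stratified assignment, not Bernoulli
draws — small runs stay balanced, which removes confounds in tests), two
18-participant groups whose BDI-II/DASS-A scores are truncated normals at
the group means/SDs (depressed BDI ≥ 14, control ≤ 9), and ground-truth
CDA amplitudes defaulting to the group × condition means of the study
(e.g. control fearful −0.85 µV) with a 0.5-µV between-participant SD
(published between-participant SDs of ~0.4–0.7 µV include measurement
noise, so the latent SD is set slightly below them).

The lateralized component is a plateau at the ground-truth amplitude
covering the 500–1000 ms window plus 50 ms of padding on each side, with
50-ms raised-cosine ramps outside the padded plateau. Two consequences
matter:

* noise-free, the contra − ipsi window mean equals the injected amplitude
  to machine precision (the plateau covers the whole window);
* after the 17-Hz filter, smoothing of the ramps happens outside the
  measurement window, so the recovered amplitude is biased by well under
  0.001 µV.

Noise enters at two levels, and the distinction is deliberate:

* `noise_sd` is per-sample sensor noise (white, or AR(1) with φ = 0.97 to
  mimic EEG autocorrelation; innovations are scaled so the stationary SD
  equals `noise_sd`). Default 15 µV, chosen so that honest trials stay
  inside the ±80 µV rejection bound. `per_sample_noise_sd()` converts a
  target single-trial window-mean SD into this unit. Note that baseline
  correction re-injects baseline noise into the whole epoch, inflating the
  SD of the measured window mean by roughly √(1 + n_window/n_baseline)
  relative to the naive arithmetic.
* `amp_noise_sd` is trial-to-trial jitter of the component amplitude
  itself — noise *at the window-mean level* by construction, unaffected by
  baseline correction and (to < 0.1%) by filtering. Injection–recovery
  calibration uses this level: with SD 2 µV and 200 trials the estimator's
  sampling error is 2/√200 ≈ 0.14 µV, and the suite checks a single seeded
  replicate within ±0.15 µV and the mean of 500 replicates within
  ±0.02 µV of the injected −0.85 µV.

Artifacts are injected with ground-truth flags so the rejection operators
can be scored: saccades are HEOG steps (default 100 µV, signed toward the
cued side, onset uniform after stimulus onset) and "blasts" are 100-ms
square pulses (default 120 µV) on one random scalp channel. Because the
default amplitudes clear the 60/80 µV thresholds by ≥ 20 µV and scalp
noise is kept ≤ 5 µV in those tests, flag sensitivity and specificity are
exactly 1 against the ground truth.

What the generator does **not** emulate: volume conduction or any forward
head model (channels are independent up to the injected components), ocular
potentials beyond the step saccade, blinks as a separate class, stimulus
rendering, reaction times, or any mechanistic link between depressive
symptoms and CDA — group effects are injected as amplitude differences,
not modeled. Passing recovery tests therefore demonstrates that the
*measurement chain* is unbiased and calibrated, not that it would be
robust to every pathology of real recordings.

## Inferential layer

The mixed ANOVA/ANCOVA uses Type III sums of squares with sum-to-zero
contrasts on a multivariate linear fit (the JASP/SPSS convention for this
design), uncorrected dfs by default — (2, 68) within and (1, 34) between at
18 + 18 × 3, and (2, 66) for the ANCOVA within effects with the centered
covariate — with Greenhouse–Geisser as an option. Partial η² is
`SS_effect/(SS_effect + SS_error)`. An explicit sums-of-squares
decomposition serves as the oracle in the test suite (agreement to 1e−8),
and a 2000-study null simulation checks the interaction's type-I rate at
5% ± 1.5%. Degenerate zero-variance data report F = 0 by convention rather
than 0/0. Planned comparisons are deliberately uncorrected for
multiplicity, matching standard practice for a small set of planned tests.

The independent-samples t is pooled-variance Student's t and accepts
`list(mean, sd, n)` summaries, so statistics are reproducible from
published tables; Cohen's d is the mean difference over the pooled SD. For
paired tests no d convention is canonical, so `d_z` (default), `d_av` and
a pooled-SD variant are all available and labeled in the output — reported
paired d values in the literature are frequently inconsistent with
`t/√n`, so the package refuses to guess which convention a given paper
used.

The JZS Bayes factor integrates the noncentral-t likelihood against a
Cauchy(0, √2/2) effect-size prior by adaptive quadrature (relative
tolerance 1e−8; the suite cross-checks against the equivalent g-prior
integral to 1e−5). Two-sided priors throughout: directional Bayes tests
are not attempted because the direction conventions of any particular
report are not recoverable from summaries.

Exploratory earlier components (N2pc, Ppc) reuse the same window-mean
operator with configurable windows; the 200–300 ms and 100–200 ms defaults
are generic conventions and explicitly non-authoritative.

## Problem sizes and numerical conventions

The test suite runs the full study pipeline at reduced sizes (3–8
participants per group, 8–40 trials per condition) and the calibration
checks at their stated sizes (2000 ANOVA simulations; 2000 × 100-trial
slots-model replicates; 500 injection–recovery seeds), completing in a few
minutes on one core. `scripts/acceptance.R` re-runs the injection–recovery
calibration at 500 seeds × 200 trials. Master seeds fan out to
per-participant, per-stage child seeds via a fixed integer hash
(`derive_seed()`), so every intermediate is regenerable in isolation and
end-to-end runs are bit-reproducible.

Degenerate inputs error early and name the constraint: trial counts that
cannot be counterbalanced exactly, missing analysis channels, all-bad
neighbor sets, single-channel references, windows off the time axis,
zero-variance t tests, constant or group-confounded covariates, missing
ANOVA cells (no imputation).

## Known limitations

BrainVision support covers the core multiplexed binary dialect
(IEEE float32 and int16-with-resolution) with stimulus markers — vectorized
or segment-annotated files are out of scope. There is no ICA or
regression-based ocular correction (contaminated trials are rejected, not
repaired), no resampling, no time–frequency or source-level measures, and
no mixture-model capacity estimators. The two-group ANCOVA assumes
homogeneous covariate slopes; heterogeneous-slope designs need a different
model. Correlation analyses at n = 36 are exploratory by nature; the
package computes them but cannot make them well-powered.
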