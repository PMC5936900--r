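---
title: "A generative model of sung and whistled pitch imitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative model of sung and whistled pitch imitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchmimic)
```

## The scientific problem

When people imitate a short melody they can do so with different motor
systems: by singing, where pitch is set by the laryngeal muscles, or by
whistling, where pitch is set by the lips and tongue. Comparing the two
on matched material separates properties of the shared auditory and
memory stages from properties of the effector-specific motor stages.
Two robust empirical signatures in this paradigm are that singing is
systematically *less precise* than whistling, and that sung notes are
systematically pulled toward each singer's *habitual pitch* — high
targets come out flat, low targets sharp — a pattern consistent with a
conservation-of-effort ("vocal laziness") account of laryngeal control.

This package provides the full computational apparatus for such a
study: stimulus composition and synthesis, a generative simulator of
imitation performances with known ground truth, the standard scoring
statistics, and the inferential stage. Because the generative
parameters are known, the whole pipeline can be validated by parameter
recovery rather than by eye.

## Pitch units

All scoring is in **cents** relative to the lowest scale degree (the
root) of the stimulus range: `cents = 1200 * log2(f / root)`, so 100
cents is one equal-temperament semitone and 1200 cents one octave.
Stimulus ranges are one octave each: roots at 110 Hz (male sung),
220 Hz (female sung) and 880 Hz (whistled). Working in cents puts all
three registers on a common task scale.

## Stimulus model

Melodies are five notes on the chromatic grid, composed by a
constrained random walk: the first note uniform on the twelve
chromatic degrees, every subsequent interval uniform on the integers
−4..+4 semitones (a repeated note is allowed), and the whole melody
rejection-sampled until every note lies within one octave
(`[0, 12]` semitones). Resampling the *entire* melody — rather than
redrawing a single offending note — gives a well-defined stationary
distribution; the conditional interval distribution remains exactly
uniform wherever the octave constraint cannot bind, which the tests
exploit as an oracle.

Whistle-timbre stimuli are sine tones (750 ms notes, 50 ms gaps,
44.1 kHz / 16-bit) shaped by a parametric onset envelope: raised-cosine
attack (default 40 ms), sustained body, raised-cosine release (20 ms).
The original whistle onset envelope was estimated empirically from
pilot recordings and is not recoverable; a parametric attack is
acoustically immaterial to scoring, which reads only the steady centre
of each note. "Convolved with an onset envelope" is implemented as
multiplicative amplitude shaping — literal convolution is not a
meaningful onset operation.

## The generative performer

One produced note in modality $m$ (sing or whistle) is

$$p = t + b_m + \gamma_m (h_m - t) + \varepsilon_{perc}
      + \varepsilon_{prod} + \varepsilon_{motor,m}$$

with $t$ the target (cents), $b_m$ a constant flat/sharp bias, $h_m$
the habitual pitch, $\gamma_m \in [0, 1)$ a linear compression of
errors toward the habitual pitch, and three independent Gaussian noise
stages:

* $\varepsilon_{perc} \sim N(0, \sigma_{perc}^2)$ — perceptual/memory
  noise, one SD per participant shared by both modalities;
* $\varepsilon_{prod} \sim N(0, \sigma_{prod}^2)$ — production noise
  common to both effectors (chiefly respiratory drive), also a shared
  per-participant SD;
* $\varepsilon_{motor,m} \sim N(0, \sigma_{motor,m}^2)$ —
  effector-specific motor noise.

Two shared stages are needed, not one. A single shared perceptual
stage does produce correlated imprecision across modalities, but the
study's partial correlations *control for perceptual ability* (the
melodic-discrimination score), and that control removes essentially
all of the perceptual contribution. The surviving correlation requires
shared variance that perception does not index; respiration is the
natural candidate, since expiratory flow drives both phonation and
whistling. With only the perceptual stage shared, simulation shows the
partial correlations collapse to zero.

Three discrete error processes complete the model, so that the
exclusion and verification rules have real work to do: per note, an
omission (probability 0.0037), a duplication (0.0037) or an octave
jump of ±1200 cents (0.001). The two count-altering probabilities sum
to 0.0074 per note, which makes the expected fraction of five-note
trials with a wrong note count $1-(1-0.0074)^5 \approx 3.6\%$.

Linear compression with a single $\gamma_m$ per modality is the
simplest mechanism that produces the observed monotone error-by-target
profile; it also implies, correctly, that a *constant* per-trial shift
cancels in adjacent-note intervals, so interval-level inaccuracy is
nearly unaffected by bias or transposition.

### Population defaults

Each participant's parameters are drawn from clipped-normal population
distributions. The defaults emulate the qualitative geometry of human
cohorts in this paradigm and are stipulations, not estimates:

| parameter | sing | whistle | units |
|---|---|---|---|
| habitual pitch $h_m$ | N(150, 150) | N(1050, 150) | cents |
| motor SD $\sigma_{motor,m}$ | N(60, 12) | N(20, 6) | cents |
| bias $b_m$ | N(−20, 25) | N(+20, 25) | cents |
| compression $\gamma_m$ | N(0.15, 0.05) | N(0.06, 0.03) | — |
| producible range | N(−250,150) .. N(1450,150) | same | cents |
| perceptual SD $\sigma_{perc}$ | N(45, 20), shared | | cents |
| production SD $\sigma_{prod}$ | N(35, 18), shared | | cents |

Habitual sung pitches sit low in the stimulus octave and habitual
whistled pitches high in it, which is what converts compression into
the observed "sing flat, whistle sharp" asymmetry. The $\gamma$ means
are chosen so that the implied error-by-target slopes (roughly −0.15
and −0.06 cents per cent) reproduce the size relations of the reported
standardized slope and interaction over a ~640-cent (2 SD) spread of
targets. Cohort size defaults to 28 participants, each imitating 45
melodies per modality.

The perceptual-ability covariate is simulated as percent correct over
90 same/different trials in three sets of descending transposition
size (300, 200, 100 cents), with success probability
$\mathrm{logit}^{-1}(d')$, $d' = \text{transposition} /
(2\sigma_{perc})$: chance when noise overwhelms the transposition,
ceiling when it vanishes. The factor 2 is a response-criterion scaling
chosen so the default cohort spans roughly 70–100% with a mean near
the high 80s.

What the simulator does **not** emulate: real voice acoustics
(formants, vibrato, jitter), attention lapses and serial-position
effects, respiratory dynamics within a trial, and any nonlinearity of
compression. Passing recovery tests therefore show that the *pipeline*
is correct and well calibrated, not that human data obey this model.

## Scoring

Produced fundamental frequencies (from the trial table, or extracted
from audio by the autocorrelation estimator over the central 250 ms of
each note window) are converted to cents. Two exclusion rules apply
before scoring: trials with the wrong number of produced notes (the
positions of omissions/duplications are indeterminate) and trials
whose *target* melody leaves the participant's producible range.
Alignment is then strictly positional, which the count filter makes
valid.

* **Inaccuracy** = mean signed error (cents), at the note and the
  interval level.
* **Imprecision** = the sample SD (n−1) of errors within each class,
  averaged unweighted across classes. For notes the class is the
  target's chromatic degree (0–12, up to 13 classes — stimuli span at
  most one octave, so octave-collapsing is a no-op); for intervals it
  is the target interval in semitones. Classes with fewer than two
  observations are dropped (their SD is undefined).

Notes whose absolute error exceeds 1000 cents are flagged as candidate
octave/measurement errors and annotated with the nearest-octave
residual. The default policy retains them, since in a real data set
flagging is a review step; `octave_correct = TRUE` snaps flagged notes
to the nearest target octave and is the appropriate mode when scoring
simulator output, where every flagged note really is an injected
octave jump. The recovery harness and the replicated sign-pattern
checks use that mode; leaving the ±1200 outliers in adds heavy
independent noise to imprecision scores and visibly degrades the
cross-modality partial correlations.

## Inference

The inferential stage mirrors the standard analysis for this design:

* four nested random-intercept LMMs (`lme4`), predicting each score
  type from modality and perceptual ability with a per-participant
  intercept; effects tested by nested model comparison with
  Kenward–Roger degrees of freedom (`pbkrtest`). If a fit degenerates
  (zero variance), the implementation falls back to a fixed-effects
  least-squares comparison and labels the rows accordingly.
* standardized estimates by refitting with inputs centred and scaled
  by 2 SD; binary predictors are coded ±0.5, making their coefficient
  exactly the between-condition difference (whistle minus sing).
* percentile bootstrap CIs (default 1000 iterations) resampling
  *participants* with replacement — resampling rows would break the
  within-participant correlation that the random intercept encodes.
* partial correlations of sing vs whistle scores controlling for
  perceptual ability, by residualizing both on the control and
  correlating residuals; the implementation is verified in tests
  against the closed-form recursion formula.
* a post-hoc model of mean note error per participant × modality ×
  target degree: `error ~ modality * target + (1 | participant)`,
  whose negative target slope and positive interaction are the
  compression signatures.

## Numerical choices and degenerate inputs

* F0 estimation uses the unbiased (lag-normalized) autocorrelation
  with parabolic peak interpolation; the shortest peak within 5% of
  the global maximum is taken, which guards against period-multiple
  errors. Segments with peak correlation below 0.5, or negligible
  energy, are flagged unvoiced rather than guessed.
* All randomness flows from one root seed through named sub-streams
  (`derive_seed`), so any stage can be re-run in isolation and
  per-unit draws are order-independent.
* Composition uses whole-melody rejection with a large iteration cap
  that raises a diagnostic error rather than looping forever under a
  misconfiguration.
* Zero-variance outcomes (e.g. noiseless simulations) are legitimate
  inputs everywhere: model fitting falls back to `lm`, the bootstrap
  returns a zero-width interval at the point estimate, and imprecision
  of constant errors is exactly 0.

## Problem sizes used in validation

The packaged validation suite runs the composer constraints over
10,000 seeded melodies; the exclusion-rate check over a 112-participant
study (10,080 trials); parameter recovery over two independent
28-participant studies; the directional sign pattern over 200
replicated cohorts; and the type-I calibration of the modality test
over 1000 null-cohort replicates (a cohort whose sing and whistle
populations are identical). These sizes give Monte-Carlo standard
errors small enough for 3-SE acceptance bands while keeping the suite
comfortably runnable on a laptop.

One caveat from the model's own structure deserves emphasis: because
constant shifts cancel in intervals, the *interval-level inaccuracy*
contrast between modalities has expectation near zero under this
generator, and its sign is not a stable prediction — unlike the note
inaccuracy contrast, both imprecision contrasts, the target-pitch
slope, the interaction, and the imprecision partial correlations,
which the replicated checks require to come out in the modeled
direction in at least 95% of cohorts.

## A worked example

```{r, eval = FALSE}
library(pitchmimic)

run <- run_end_to_end(run_config(n_boot = 200, seed = 1))
run$analysis$effects
run$analysis$partial_correlations
run$analysis$posthoc

rec <- recover_parameters(run_config(seed = 1), n_replicates = 2)
rec$summary
```

## Known limitations

* The whistle onset envelope is parametric, not the empirical pilot
  envelope; WAV output is mono integer PCM only.
* The F0 estimator is designed for clean, near-sinusoidal material; it
  is not a substitute for a full voice pitch tracker on real
  recordings (no octave-cost dynamic programming, no formant handling).
* The simulator's noise is Gaussian on the cents scale and
  homoscedastic across targets within a participant; real performers
  may be noisier far from their habitual pitch.
* MBEA simulation is a one-parameter logistic link on transposition
  detectability; it ignores contour and memory-load structure of the
  real battery.
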