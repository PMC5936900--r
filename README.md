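# pitchmimic

Tools for studying **pitch imitation across motor systems** — singing
(pitch from the larynx) versus whistling (pitch from the lips and
tongue). The package is aimed at researchers in vocal-motor control and
behavioural bioacoustics who want a fully simulatable, fully testable
version of the melody-imitation paradigm: composed stimuli, synthetic
performers with known ground truth, the standard accuracy/precision
scoring, and the mixed-model inferential stage.

## What it implements

**Stimuli.** Five-note melodies composed by a constrained random walk
(first note uniform on the chromatic scale, intervals uniform on ±4
semitones, whole melody rejection-sampled into a single octave), and
whistle-timbre sine stimuli (750 ms notes, 50 ms gaps, 44.1 kHz/16-bit
WAV) in the task octaves A2–A3 (110 Hz root), A3–A4 (220 Hz) and A5–A6
(880 Hz).

**A generative performer.** One produced note in modality *m* is

```
produced = target + bias_m + gamma_m * (habitual_m - target)
           + e_perc + e_prod + e_motor_m
```

— constant bias, linear compression (`gamma`) of errors toward the
performer's habitual pitch, and three Gaussian noise stages: perceptual
and production noise with participant-level SDs shared across
modalities, plus effector-specific motor noise. Rare omissions,
duplications and ±1200-cent octave jumps exercise the exclusion and
verification rules. Ground-truth parameters make the whole pipeline
checkable by parameter recovery.

**Scoring.** Frequencies are converted to cents
(`1200 * log2(f / root)`); trials with the wrong note count or with
targets outside a participant's producible range are excluded with
machine-readable reasons; then per participant × modality:

* *inaccuracy* — mean signed error (flat < 0 < sharp), notes and
  intervals;
* *imprecision* — sample SD of errors within each target pitch class,
  averaged across classes.

**Inference.** Nested random-intercept LMMs (lme4) with Kenward–Roger
tests, 2-SD standardized estimates, participant-cluster percentile
bootstrap CIs, partial correlations of sing vs whistle scores
controlling for perceptual ability, and a post-hoc model of error by
target pitch whose negative slope and positive modality interaction
are the compression signatures. A simulated melodic-discrimination
(MBEA-style) score provides the perceptual covariate.

## A worked example

```r
library(pitchmimic)

run <- run_end_to_end(run_config(n_boot = 200, seed = 1))
run$analysis$effects
```

```
               outcome       effect       F df1 df2        p std_estimate ci_low ci_high
1      note_inaccuracy     modality 278.576   1  27 9.44e-16       136.98 121.93  153.75
...
5     note_imprecision     modality  29.551   1  27 9.46e-06       -18.55 -25.52  -12.46
7 interval_imprecision     modality  14.951   1  27 6.29e-04       -23.35 -32.94  -10.33
```

The modality estimates are whistle-minus-sing differences in cents:
this simulated cohort whistles ~137 cents sharper than it sings
(habitual-pitch compression pulling sung notes down and whistled notes
up) and is 19–23 cents *more precise* when whistling. Partial
correlations keep the shared-stage signal after controlling for
perceptual ability:

```r
run$analysis$partial_correlations
#>                  score r_squared       p  n
#> 3     note_imprecision  0.284824 0.00414 28
#> 4 interval_imprecision  0.204092 0.01800 28
```

and the post-hoc target-pitch model shows the compression signature
(error falls with target height, more steeply for singing):

```
                 effect    F df2         p std_estimate
2          target_cents  641 686 2.01e-100        -79.1
3 modality:target_cents  169 685  1.22e-34         71.7
```

Parameter recovery against the generator's ground truth:

```r
recover_parameters(run_config(seed = 1), n_replicates = 2)$summary
#>   parameter modality     bias    rmse se_bias
#> 1      bias     sing  2.06642 12.8183 1.70581
#> 3     gamma     sing  0.00449  0.0237 0.00313
#> 5  noise_sd     sing  1.60239  6.1820 0.80509
#> ...
```

Estimator biases are statistically indistinguishable from zero; RMSEs
are the single-study estimation error at 45 trials per modality.

A thin command-line wrapper with `compose`, `synth`, `simulate`,
`score`, `run` and `recover` subcommands lives at
`inst/scripts/pitchmimic.R`.

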