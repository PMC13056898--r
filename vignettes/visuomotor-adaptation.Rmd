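---
title: "Modelling within- and between-trial visuomotor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within- and between-trial visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(vmadapt)
```

## The scientific problem

When cursor feedback is rotated by a fixed angle relative to the hand,
people adapt through two distinguishable processes. *Between-trial*
learning updates the motor plan for the next movement from the previous
movement's error. *Within-trial* learning corrects the ongoing movement
online, using the continuous stream of visual feedback. A pair of joystick
tasks separates them: a **reaching** task in which the cursor is steered
continuously to the target (both processes available), and a **curling**
task in which the cursor is released ballistically once it crosses a small
radius (8 mm) around the start, so only the planned initial direction
matters and online correction is impossible.

`vmadapt` implements the analysis pipeline for such experiments —
trajectory-level angular errors, outlier-robust preprocessing, block-wise
state-space model fitting and adaptation summaries — together with a fully
seeded synthetic-cohort generator, so that every stage is testable end to
end without access to human data.

## The single-rate state-space model

The core estimator is the single-rate state-space model of trial-by-trial
adaptation. The learner's internal state $z_n$ estimates the applied
rotation $r_n$ (degrees, counterclockwise positive); the angular hand
direction relative to the target is $y_n = -z_n$ and the state evolves as

$$z_{n+1} = A\,z_n + B\,(r_n - z_n),$$

where $B \in [0,1]$ (the *learning rate*) is the fraction of the current
error $r_n - z_n$ corrected on the next trial and $A \in [0,1]$ (the
*retention factor*) is the fraction of the learned state carried from one
trial to the next. Under a constant rotation $r$ the error converges to
$e^* = r\,(1-A)/(1-A+B)$ (exactly 0 when $A = 1$); `fixed_point()` exposes
this closed form and the forward recurrence is available as
`predict_series()`.

`fit_statespace()` estimates $(A, B)$ by bounded least squares on the
observed error series: `optim(method = "L-BFGS-B")` within $[0,1]^2$, from
the three starting points $(0.9, 0.1)$, $(0.99, 0.3)$, $(0.5, 0.5)$, keeping
the best solution (multi-start guards against local minima of the
non-convex objective). Convergence tolerance is $10^{-9}$ on the objective;
boundary solutions are reported as such, and a zero-variance series is
flagged *degenerate* ($B$ unidentifiable) rather than rejected. The fit is
a classed object with the usual `coef()`, `predict()`, `residuals()`,
`plot()` and `simulate()` methods:

```{r fit-example}
r <- rep(40, 40)
y <- predict_series(A = 0.95, B = 0.2, r)$error + rnorm(40, 0, 2)
fit <- fit_statespace(y, r)
fit
```

### Fitting scale

Cohort analyses fit each adaptation block after log-standardisation
(`standardise_to_baseline()`): $s_n = \log_{10}|e_n| - \log_{10} m$ with
$m$ the subject's median absolute baseline error, the rotation transformed
consistently, and a floor of $\epsilon = 0.5^\circ$ inside the logarithm
guarding zero errors. This removes between-subject differences in error
range. A raw-degrees mode exists because parameter-recovery studies are
cleaner there; the two scales order block-wise learning rates identically
on noise-free series (a tested invariant). The log transform uses the
error magnitude: adaptation errors to a 40° rotation are overwhelmingly
one-signed, and the magnitude reading extends the transform to occasional
over-corrections.

Each adaptation block is fitted from $z_0 = 0$: blocks are separated by
de-adaptation blocks that return the state close to zero, and block-wise
fitting with a free initial state would confound retention with the
starting condition.

## Preprocessing

Trial series are cleaned in the order: extreme removal, then Hampel
filtering.

* `remove_extreme_outliers()` flags trials with $|e| > 60^\circ$ (the rule
  is applied to the magnitude) and excludes them from all later stages;
  gaps are closed by concatenation, not imputed.
* `hampel_filter()` slides a window of the 6 nearest neighbours (3 per
  side, truncated at the block ends, centre excluded) and replaces a point
  by the window median when it deviates by more than 3 scaled MADs
  ($1.4826 \times \mathrm{MAD}$ — the standard Hampel identifier). When
  the window MAD is zero, any deviation from the median is replaced. The
  first 5 trials of each block are never replaced (they carry the genuine
  large errors of early adaptation) but do serve as neighbours. The filter
  makes a single pass over the original values — replacements never feed
  back into later windows — which makes it exactly checkable against a
  brute-force per-window oracle, a property the test suite exercises on
  1,000 random series.

## Trajectory metrics

Angular error is the signed angle between the start→target and
start→cursor vectors at a reference point: the sample of **peak tangential
speed** for reaching, the first crossing of the **8 mm release radius**
(linearly interpolated between the bracketing samples) for curling — and
the same 8 mm reference applied to reaching gives the matched early
comparison between tasks. Speed is computed by centred finite differences
after a 21-sample moving average (shrinking at the ends): at 1 kHz this
suppresses quantisation noise without biasing the peak location, and the
smoothed estimate is tested against a raw-sample brute-force oracle within
0.5°. Movement onset is the conventional 5%-of-peak-speed criterion;
`control_time()` runs from onset to the trial end (reaching) or the
release-radius crossing (curling). `count_direction_changes()` counts
successive-sample direction differences above 5°, skipping
zero-displacement samples whose direction is undefined.

## The synthetic cohort

`simulate_cohort()` emulates the study design: 22 subjects per
reinforcement condition (neutral, reward, punishment), each performing
both tasks through the default `make_schedule()` — a 400-trial Learning
period (baseline block, then adaptation/de-adaptation alternating, ending
on the fifth adaptation block) and a 160-trial Retention period
(adaptation, de-adaptation, adaptation, washout), all blocks of 40 trials,
with a 40° counterclockwise rotation in adaptation blocks.

Per trial, the generative model draws planning noise
$\xi^{plan} \sim N(0, \sigma_{plan})$ and execution noise
$\xi^{exec} \sim N(0, \sigma_{exec})$; the planned error is
$e^{plan}_n = r_n - z_n + \xi^{plan}_n$, the measured error
$(1-g)\,e^{plan}_n + \xi^{exec}_n$ in reaching (online-correction gain
$g$) and $e^{plan}_n + \xi^{exec}_n$ in curling ($g \equiv 0$). The
between-trial update consumes the *pre-correction* planned error —
including its planning noise — so exploration of the motor plan is
informative for learning while execution noise is not, the mechanistic
asymmetry the analysis is designed to detect. The state resets to zero at
each adaptation-block start (mirroring the block-wise fit) and carries
over into de-adaptation and washout blocks, which therefore show rebound
aftereffects. Savings are modelled minimally as a multiplicative gain on
the effective learning rate per successive adaptation block
($B_{eff} = \min(1, B \cdot 1.15^{\,k-1})$ by default): the device that
makes the savings metric exercisable without committing to a specific
memory mechanism.

### Population defaults and why

Subject-level parameters are drawn once per subject ($A \sim N(0.95,
0.02)$, $\sigma_{plan} \sim N(3, 1.2)$, $\sigma_{exec} \sim N(2, 0.5)$
degrees, savings gain $\sim N(1.15, 0.05)$, all truncated to their valid
ranges) and shared across tasks. Two structures are task-specific by
design:

* **Learning rate.** $B$ is drawn per task around task means of 0.25
  (reaching) and 0.15 (curling) with SD 0.05; in curling it is drawn
  jointly with $\sigma_{plan}$ at correlation $\rho = 0.6$ (planning noise
  as informative exploration), in reaching independently (online
  correction dampens the informational value of plan variability).
* **Online correction.** $g \sim N(0.35, 0.08)$ in reaching, elevated by
  0.2 for reward and punishment subjects equally (the two reinforcement
  signs did not differ empirically); $g \equiv 0$ in curling, so the
  reinforcement manipulation cannot affect curling by construction.

These values were chosen once so that the designed effects are of a size a
study with 22 subjects per condition is powered to detect — a mean
reaching error advantage of a few degrees for reinforced groups against a
between-subject SD of roughly 2° — and so that early curling variability
(SD over $\sigma_{plan}$ of ~40%) remains resolvable from five-trial
windows averaged over five blocks.

The payoff rule maps each learning-period trial's error magnitude to 0–10
points, linear down to zero at 30°: reward subjects gain the scored
points, punishment subjects start from a 4,000-point endowment and lose
the unscored remainder; neutral subjects and all retention-period trials
get no points.

### What the generator does and does not emulate

The simulator reproduces the statistical structure the analysis assumes:
blocked schedules, two-process task asymmetry, reinforcement confined to
the online-correction pathway, higher early variability without online
correction, a planning-noise–learning-rate coupling in curling only, and
Gaussian trial noise (the noise model of human errors is not documented;
Gaussian is assumed). It does **not** emulate biomechanics, joystick
dynamics, explicit re-aiming strategies, fatigue or attentional drift, and
its synthetic trajectories are smooth idealisations — they carry the exact
reference-point errors of the trial table, but not the jittery
sub-movements that give human reaching paths their multiple direction
changes. Passing tests therefore demonstrate that the pipeline recovers
the structure it targets when that structure is present, not that real
data satisfy the generator's assumptions.

## Behavioural summaries

`block_summaries()` computes per-block mean error, the first-five-trials
mean and SD (early window), the last-five mean, and early improvement
(error trial 1 − trial 5). Early/late windows are fixed at 5 trials *by
original trial index* even when interior trials were removed (windows with
removals are flagged partial); values are post-Hampel, which for the early
window means raw values, consistent with the protected prefix. Savings
(`savings_curve()`), retention (`retention_contrast()`: last learning
adaptation block vs first retention block, paired t), washout aftereffects
(`washout_change()`: change in mean error magnitude from baseline to
washout) and reinforcement contrasts (`condition_contrasts()`: equal-
variance one-way F plus BH-corrected pairwise t tests) follow. All tests
are two-sided; pairwise t tests are plain (not Welch-corrected).
`variability_learning_association()` correlates early variability with
early improvement and with the fitted learning rate, and computes the
first-order partial correlation controlling early improvement, with
p-values from the t transform on $n-2$ (or $n-3$) degrees of freedom.

```{r cohort-example}
cfg <- cohort_config(n_per_condition = 4)
tab <- simulate_cohort(cfg, make_schedule(), seed = 42)
pre <- preprocess_trials(tab)
pre$report
fits <- fit_blocks(pre$table)
metrics <- add_learning_rates(block_summaries(pre$table), fits)
head(subject_summaries(metrics, tab))
```

## Numerical choices and degenerate inputs

* Angles are degrees throughout, counterclockwise positive, wrapped to
  $(-180, 180]$; a rotation of $+40$ means the cursor is rotated
  counterclockwise relative to the hand.
* Radius crossings interpolate linearly in $x,y$ between bracketing
  samples (sub-millimetre accuracy at 1 kHz); the interpolated crossing
  always lies within one sample of the brute-force first-crossing index.
* Zero-displacement samples are skipped when directions are computed; an
  all-stationary trajectory, a path that never reaches the reference
  radius, and a series shorter than 4 trials are errors, not silent
  results.
* Series with zero variance give flagged/`NA` correlation and $R^2$
  results rather than `NaN` surprises.
* The problem sizes used by the test suite and the acceptance script —
  500-trial fixed-point runs, 200 recovery replicates per learning-rate
  value, 1,000 Hampel oracle series, 100 geometry round trips, 20
  full-cohort seeds — were chosen as the smallest scales at which the
  corresponding Monte-Carlo statements are stable.

## Known limitations

* The savings mechanism is a phenomenological one-parameter device; it
  reproduces the savings *metric*, not a theory of savings.
* The trajectory synthesiser treats online-correction latency only as the
  correction-onset delay (150 ms); latency variability is not modelled.
* Direction-change counts discriminate the tasks only for paths with
  genuine sub-movements; on the smooth synthetic paths both tasks yield
  counts near zero.
* Linear mixed-effects modelling and generalised effect sizes are outside
  the package's scope; practitioners can pass the per-trial tables to
  `lme4`/`lmerTest` directly.
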