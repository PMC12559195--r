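---
title: "Analyzing and modeling multimodal courtship signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing and modeling multimodal courtship signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtsig)
library(dplyr)
```

Male *Drosophila* court with two pulsatile signal modes: air-borne pulse
song (inter-pulse intervals of roughly 30–45 ms, plus sustained sine song)
and substrate-borne vibrations produced by abdominal quivering
(inter-vibration intervals of roughly 140–180 ms). The two modes occur in
largely distinct behavioral contexts — vibrations require a stationary
pair so the signal can reach the female through the substrate — and
rarely overlap in time. `courtsig` implements the quantitative toolchain
for studying how the choice between song, vibration and silence is made:
interval-based signal classification and train statistics, a
delay-embedded multinomial choice model over kinematic cues, and a
rate-based model of the underlying brain circuit. Because the package is
validated entirely on synthetic data, a seeded generator for two-fly
trajectories, ground-truth-driven labels and pulse trains is a first-class
component.

## Signal classification and train statistics

Pulses are typed by the intervals to their neighbors: an interval inside
the song band (30–45 ms by default) marks song, one inside the vibration
band (140–180 ms) marks vibration; a pulse whose two neighbor intervals
disagree takes the type of the tighter interval, which resolves ambiguity
toward song, and isolated pulses stay unclassified. Trains are maximal
runs of same-type events with gaps below 2–2.5 times the modal interval —
80 ms for song, 400 ms for vibration. From rasterized trains the package
computes per-type signal fractions over courtship frames, pairwise
overlap fractions, and transition matrices between train types; in
sequence mode, pauses longer than 0.5 s become an explicit no-signal
state and self-transitions are excluded. Group comparisons use Wilcoxon
signed-rank (paired) and Mann–Whitney U (unpaired) tests — exact up to
n = 25 without ties, normal approximation beyond — with Bonferroni
adjustment of the 0.05 familywise level.

```{r classify}
ev <- classify_pulses(c(seq(0, 0.16, by = 0.04), seq(1, 2, by = 0.16)))
segment_trains(ev)
```

## Kinematic cues and the courtship mask

`extract_cues()` turns two-fly pose tracks (head, thorax, abdomen, wings
at 100 Hz) into the 19 cues used for choice modeling: per fly the
rotational speed and acceleration, speed, forward and lateral velocity,
and the corresponding accelerations; plus male–female distance, the
male's angular position in the female's body frame (`relative_angle`,
0° = in front of her) and his heading relative to her position
(`relative_orientation`). Conventions the tracking literature leaves
open were fixed as: heading from the thorax→head vector; velocities by
central differences of the thorax before any smoothing; rotational
acceleration as the first difference of rotational speed; angles in
degrees wrapped to (−180, 180], reported as absolute values by default
(a `signed_angles` switch keeps the sign). Tracks are anti-alias smoothed
and decimated from 100 to 50 Hz for analysis.

Courtship frames are those with the male within 8 mm of the female (6 mm
for modeling) and within ±60° of her rear axis. Frames are invalidated
when the thorax distance drops below 1 mm or any head/thorax confidence
falls below 50%, and from copulation onward. Cues are z-scored per pair —
over valid courtship frames, since only those enter the model; the
`frames` argument of `zscore_cues()` exposes this choice — and pairs are
pooled after scaling.

## The choice model

The per-frame choice between song, vibration and no signal is modeled as
a multinomial logistic regression on the cues' trailing 1 s history. The
history is compressed onto four raised cosines with log-spaced peaks
(fine resolution at short lags, coarse near 1 s), so each cue contributes
4 coefficients. The warp offset and peak placement are free in the
standard construction; defaults put the first peak near 40 ms and the
last one sample short of 1 s, both exposed in `cosine_basis()`. Because
no-signal frames dominate, the data are balanced before fitting by
subsampling an equal number of frames per class. Each fit repeat draws an
independent balance and 90/10 train/test split, selects the L2 penalty by
10-fold cross-validation over 10 log-spaced strengths, and scores a
true-class-normalized confusion matrix on the held-out split; accuracy is
the diagonal mean. Temporal filters are recovered by back-projecting the
basis onto the weights — an exact linear identity — and a filter's
integral (its sum over lags) tells whether high cue values promote
(positive) or suppress (negative) that signal. Per-cue information is
assessed either by fitting on a single cue's columns (`restrict`, the
default) or by shuffling all other cues before embedding
(`shuffle_others`); both readings are implemented because either is a
defensible operationalization of "a model per cue".

The ridge fit is computed by `glmnet`; its multinomial solution is
symmetric (per-feature coefficients sum to zero across classes), so the
synthetic ground-truth model specifies class-centred filters per cue,
making recovery well-posed. Ground-truth filters are specified directly
on the lag grid rather than in basis coefficients so recovery tests do
not presuppose the basis.

```{r glm, eval = FALSE}
cm <- synth_cue_matrix(75000, rate_hz = 50, seed = 1)
gt <- default_ground_truth()
lab <- sample_signals(cm, gt, seed = 2)
design <- delay_embed(cm, cosine_basis(), labels = lab$label)
fit <- fit_choice_model(design, n_repeats = 10, seed = 3)
glance(fit)
autoplot(fit, cues = c("male_velocity", "female_velocity", "distance"))
```

## The circuit model

The rate model has seven threshold-linear units: the social-cue
integrators pC2l and P1a, a recurrent persistence unit (RNN), the
descending neurons pIP10 (song) and DNvib (vibration), and two inhibitory
interneurons that implement mutual inhibition between the descending
pathways. Wiring follows the circuit's structural description: pC2l
drives pIP10 strongly and P1a weakly; P1a drives DNvib and the RNN; the
RNN drives DNvib strongly and pIP10 weakly; each descending neuron drives
an interneuron that inhibits the other descending neuron. Each unit obeys

    tau dr/dt = -r + g f(W r + I - beta a),

with `f` threshold-linear saturating at `r_max` and `a` a low-passed copy
of the unit's own rate (subtractive adaptation). Distinctive dynamical
elements, each tied to an observed behavior:

* **P1a** rises fast (0.5 s) but decays slowly (8 s, inside the
  reported 5–10 s range). The asymmetry is needed because activation
  effects appear with little delay while offset vibrations persist for
  5–10 s; a single symmetric time constant cannot do both.
* **The RNN** self-excites with slope > 1 above a threshold, so it
  latches only under strong direct P1a drive — the weak pC2l→P1a relay
  never reaches threshold — and slow adaptation (40 s) limits the
  persistence to tens of seconds.
* **Both descending neurons adapt**, and the DNvib→pIP10 interneuron
  adapts strongly, acting as a high-pass filter that makes song
  suppression fast at vibration onset.
* **Ornstein–Uhlenbeck noise** (50 ms correlation, SD 0.015) is added to
  the descending neurons' outputs and propagates to the interneurons;
  descending output maps linearly onto signal probability (gain 0.9,
  clipped to [0, 1], no floor — the small noise-driven baseline plays
  that role).

The circuit is known structurally — which cell types connect, which
connections inhibit, which dynamics are slow — but that description does
not pin down equations or parameter values. The implementation is
therefore a structural reconstruction: threshold-linear units with
subtractive adaptation are the minimal dynamics consistent with every
stated behavior, and the parameter set ships as a versioned default
tuned only against the qualitative behavioral contract (vibration
dominance and persistence under P1a drive, song-then-offset-vibration
under pC2l drive, collapse of persistence under RNN ablation with
preserved offset vibrations, increased song/vibration co-activity
without mutual inhibition, reduced signaling under satiation). It should
be read as a sufficiency argument, not a measurement of biophysical
constants.

Integration uses an exponential-Euler step (dt = 1 ms): the leak is
integrated exactly between steps, so an isolated unit reproduces its
closed-form step response to machine precision and the scheme is stable
for any dt below the smallest time constant; halving dt moves epoch means
by well under 1%. A divergence guard aborts if any rate leaves its
physical range. Epoch statistics use the stimulus-aligned windows
before (−10–0 s), during (0–5 s), offset (5–15 s) and after (15–35 s),
and trial averages pool 100 independently seeded simulations.

```{r circuit, eval = FALSE}
pars <- circuit_params()
sim <- run_circuit_trials(pars, stimulus_protocol("P1a"), seed = 1)
autoplot(sim)
sim$epoch_summary
```

## What the synthetic generator does and does not emulate

`generate_tracks()` produces a female alternating Ornstein–Uhlenbeck
walking with exponentially distributed stationary bouts, and a male whose
position relaxes toward a point behind her — the minimal process that
reproduces the two locomotor statistics the analyses rely on: positively
correlated male/female speeds and stationary episodes. Labels come from a
known choice model applied to the cues (so downstream fits have a ground
truth), and pulse events are placed in labeled spans at intervals drawn
uniformly from the configured bands; uniform interval distributions were
chosen over empirical-quantile matching for analytic tractability, and
sine song is represented as labeled segments only, since every downstream
computation is event- or segment-level. The generator's defaults are the
study conditions (100 Hz tracks analyzed at 50 Hz, 30–45 ms song and
140–180 ms vibration intervals, 8/6 mm courtship thresholds).

What the generator does *not* emulate — wing kinematics, audio waveforms,
pose-estimation error structure beyond uniform confidence drops, and the
behavioral autocorrelation of real signal choice — bounds what passing
tests show: they validate the estimators and the model machinery, not
claims about real flies. Filter recovery on white-noise cues, in
particular, is easier than on autocorrelated natural cues, where
collinearity across lags would widen the recovery error.

## Problem sizes and numerical choices

Validation runs use 75,000 frames (25 minutes at 50 Hz) subsampled to
60,000 balanced rows for model recovery, 20 fit repeats for sign-recovery
rates, 10 for the chance-level control, 1,000 random event sets for the
segmentation oracle, and 100-trial circuit averages — sizes at which
every estimate is stable yet a full run stays comfortable on a laptop.
glmnet is run with a coordinate-descent tolerance of 1e-4 and the
500-iteration cap of the fitting recipe; convergence is recorded per
repeat in the fit metadata. Degenerate inputs are flagged rather than
silently dropped: empty masks, single trains, all-zero paired
differences and empty designs each carry an explicit flag or typed error.

## Known limitations

The RNN is a single effective unit, not a multi-unit network; mutual
inhibition sits between the descending neurons (the simplest of the
anatomically possible placements); circuit parameters are qualitative,
not fitted to trial-average traces, which are not numerically available.
The per-pulse classification rule (tighter neighbor wins) is one of
several defensible conventions for pulses whose two intervals disagree;
with disjoint interval bands the choice only affects boundary pulses.
Whether the relative angle and orientation enter the choice model signed
or absolute is not settled by convention; absolute is the default and the
signed variant is a switch.
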