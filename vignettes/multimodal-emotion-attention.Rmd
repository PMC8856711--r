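---
title: "Methods: multimodal psychophysiology of emotion-attention interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal psychophysiology of emotion-attention interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

A briefly flashed affective picture (80 ms) can change how well a person
performs an immediately following, unrelated attention task — and the
*direction* of that change differs across people: some are faster after an
emotional picture (facilitated), others slower (impeded). `emoattn`
implements the full analysis chain for paradigms of this kind, in which
three streams are recorded simultaneously during a cued flanker task
preceded by affective pictures:

* **EEG**, from which event-related potentials time-locked to picture
  onset are extracted — the P300 (mean voltage 250–350 ms, indexing
  perceived emotional significance) and the late positive potential
  (LPP, 500–800 ms, indexing arousal/regulation), at midline channels
  Fz, Cz, Pz;
* **skin conductance** (SCR), scored per trial as the baseline-to-window
  maximum change of the high-pass-filtered signal;
* **reaction time** on the flanker target, log-transformed.

Every response measure is referenced to the neutral-picture condition
through the difference score

$$E_{\mathrm{modality},\ \mathrm{emotion}} =
  R_{\mathrm{modality},\ \mathrm{emotion}} - R_{\mathrm{modality},\ \mathrm{neutral}},$$

with modality ∈ {RT, SCR, P300, LPP} and emotion ∈ {positive, erotic,
mutilation, horror}. The sign of $E_{RT}$ defines the participant's group
in each emotion condition — facilitated ($E_{RT}<0$), impeded
($E_{RT}>0$) — and the physiological E scores are used to *predict* that
group with a cross-validated linear support-vector machine, unimodally
(P300 + LPP) or multimodally (P300 + LPP + SCR).

Because no raw data are distributed with studies of this kind, the
package ships a first-class synthetic-cohort generator that emulates the
full recording session, so every stage of the pipeline is testable
end-to-end and its statistical calibration can be demonstrated by
simulation.

# The synthetic cohort

## Session structure

A session is 10 blocks × 24 trials; each of the five picture categories
(neutral, positive, erotic, mutilation, horror) occupies exactly two
blocks, one in each half of the session, and no category occupies two
consecutive blocks (in particular blocks 5 and 6 differ). Within a block
the three cue types (spatial, center, none) and two flanker congruency
levels are fully crossed and balanced. Trial timing: picture 80 ms,
fixation drawn uniformly from 900–1300 ms, cue 100 ms, 400 ms fixation,
then the target with a 1700 ms response deadline.

Two timing conventions are defensible for the randomized fixation —
anchored at picture *offset* or at picture *onset* (the two differ by the
80 ms picture duration). The generator exposes both
(`timing$fixation_anchor`); the default anchors at offset, so the cue
never arrives earlier than 980 ms after picture onset.

The interval from target onset to the next picture is a fixed nominal
1.2 s (`timing$post_target_s`): observed response times do not feed back
into the schedule. This keeps schedules independent of the simulated
behavior; the SCR scoring window ("picture onset to 500 ms before the
next trial") uses these scheduled onsets, as it would with a real event
log.

Blocks are separated by 120 s breaks (`timing$block_gap_s`), during
which the participant's fingers are out of the conductance sensor: those
samples are masked invalid and never interpolated. The EEG recording is
modelled as *paused* during breaks — its timeline compresses each break
to `timing$eeg_gap_s` (default 4 s). Epochs never span a break, so no
downstream quantity depends on this; it keeps simulation affordable.

## Latent responder traits

Each participant carries one latent scalar $z$ per non-neutral emotion,
$z \sim N(0, \sigma_z^2)$, loading simultaneously on

* the ERP bump amplitudes of that emotion (`load_erp_uv`, default 1.5 µV
  per SD),
* the SCR phasic driver (`load_scr`, default 0.05 units per SD), and
* the signed RT effect (`load_rt`, default 0.08 log-units per SD), plus
  a per-emotion mean shift (`rt_shift`, default 0, giving an even
  facilitated/impeded split in expectation).

The intended group label is the sign of the planted RT effect and is
stored with the ground truth. This single-trait structure is the minimal
model under which neutral-referenced physiological features carry
information about the direction of the attentional effect, which is what
makes the classification result reproducible in principle. The default
loadings and noise levels were chosen once so that the simulated effect
sizes sit in the range reported for this paradigm (emotion effects on
P300/LPP of ~2 µV with standardized effects up to ~1.3; multimodal
classification accuracy in the 70–80% band at n = 26).

## Signal forward models

**EEG.** Each trial adds two Gaussian-in-time bumps to the background:
a P300-like bump (peak 300 ms, SD 40 ms, spatial weights largest at
Fz/Cz) and an LPP-like bump (peak 650 ms, SD 120 ms, largest at Cz/Pz).
Two normalisation conventions make planted amplitudes directly
interpretable:

* temporal kernels are scaled to unit *mean over the component's
  analysis window*, so a planted amplitude of $a$ µV yields a window
  mean of $a$ µV;
* spatial patterns have zero mean across the montage (the forward model
  lives in average-reference space, as real average-referenced
  topographies do) and unit mean weight over the channels entering the
  component's analysis average.

Consequently the planted condition difference δ is, up to filtering and
noise, exactly the expected downstream $E$ value — parameter recovery is
an identity, which the test suite exploits. Background noise is
spectrally shaped white noise with a $1/f$ trend plus a 10 Hz alpha
peak (RMS `eeg_rms_uv`, default 6 µV). Ocular-like artifacts (300 ms
half-sine, 150 µV on Fz) are injected per trial with probability
`artifact_rate` (default 0.05) to exercise rejection. The default
montage is a six-channel subset (Fz, Cz, Pz, F3, F4, Oz) — only
Fz/Cz/Pz enter any statistic — and the default rate is 128 Hz,
typical of consumer-grade headsets; any rate ≥ 100 Hz works (the
analysis windows must contain at least 10 samples).

**SCR.** Phasic responses use the Bateman kernel (difference of
exponentials, rise 0.75 s, decay 2.0 s, unit peak) at 1 s latency after
picture onset, scaled by condition driver × trait; tonic drift is slow
spectrally-shaped noise plus white measurement noise, all removed or
handled by the 0.05 Hz high-pass downstream. Conductance units are
arbitrary (device-specific); the pipeline is unit-agnostic.

**RT.** Log reaction time is additive: baseline (log 560 ms), cue effect
(spatial −0.08 < center −0.04 < none 0), congruency effect (congruent 0 <
incongruent +0.05), planted emotion effect, and Gaussian residual (SD
0.12). Times above 1700 ms become timeouts (no response recorded).

## What the generator does *not* emulate

No eye movements or EOG, no real stimulus content, no non-stationarity
in noise levels, no electrode drift or impedance artifacts, no
correlation structure between channels beyond the event-related
patterns, and no relationship between awareness and response (the
awareness/recognition side experiment is out of scope). Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated
under the stated statistical structure — not that real data satisfy that
structure.

# Preprocessing and feature extraction

The EEG chain is fixed: band-pass 0.1–30 Hz → average re-reference →
epoch \[−100, 1000) ms around picture onset → baseline-correct on
\[−100, 0) → reject epochs whose absolute amplitude strictly exceeds
100 µV. Ordering notes:

* Filtering is zero-phase forward–backward Butterworth, realised as a
  2nd-order high-pass cascaded with a 4th-order low-pass (each applied
  twice, squaring the magnitude response). A single band-pass section
  with a 0.1 Hz edge at a 128 Hz rate is numerically fragile; the
  cascade is stable and meets the documented transfer contract (gain
  within 5% at 10 Hz; ≥ 20 dB down at 60 Hz; DC removed), which the
  tests verify.
* Screening-after-baseline is the documented order; the amplitude rule
  is evaluated on the analysis channels Fz/Cz/Pz by default (a flag
  screens the whole montage), since those are the only channels entering
  statistics. Ocular-artifact removal by ICA is intentionally out of
  scope; the amplitude rule is the rejection mechanism.
* All windows are half-open \[start, end) with sample index
  `floor(t × rate)` relative to onset, everywhere — window arithmetic is
  exact bookkeeping at any rate, and an epoch at 1000 Hz has exactly
  1100 samples.

ERP features are plain window means (P300: \[250, 350); LPP:
\[500, 800)) per retained trial and channel. Condition-level aggregation
pools trials (trial-weighted); a `block_equal_weight` flag averages
block means instead. For classification, P300 is averaged over Fz/Cz/Pz
and LPP over Cz/Pz.

The SCR chain high-passes the whole series at 0.05 Hz with a zero-phase
linear-phase FIR (window design, order ≈ 3.3·rate/0.1 giving a ~0.1 Hz
transition at 60 Hz). At so low a cutoff the textbook window design has
appreciable DC leakage, so the filter is built as the exact spectral
complement of a unity-DC low-pass — DC gain is identically zero. The
per-trial score is max over \[onset, next onset − 500 ms) of conductance
minus the mean over \[onset − 500 ms, onset), floored at 0 (a trial that
never rises above baseline is a zero-magnitude response; the floor also
keeps the log transform finite). Scores are transformed `log(1 + s)` and
averaged per cell.

RT cells are means of natural-log RT; timeouts are always excluded and
counted; incorrect responses are retained by default (the direction keys
make every response usable) with an `exclude_errors` flag. The log base
is irrelevant to sign-based grouping and scale-equivariant statistics.

"Block-averaged" classification rows are per session *half*: each
condition occupies exactly one block per half, so the half is the
natural pairing unit, and the half-wise E score subtracts the same-half
neutral block. Ties $E_{RT}=0$ are labelled `undefined` and excluded
from classification rather than assigned arbitrarily (measure-zero with
continuous RT).

# Statistics

The inferential toolkit mirrors the field's standard repertoire:

* one-sample and paired t tests with $d = t/\sqrt{n}$;
* Wilcoxon signed-rank with normal approximation, tie-corrected
  variance, and $r = Z/\sqrt{n}$ ($n$ = non-zero differences entering
  the test). **No continuity correction by default**: the printed Z
  values this toolkit reproduces (e.g. $Z = 2.803$ for ten all-positive
  differences) are exactly $\mu_W/\sigma_W$, the convention of the
  common commercial packages; a `correct` flag enables the correction.
* Friedman's rank test;
* repeated-measures ANOVA (up to three within factors, complete
  balanced designs) through the multivariate-model route, with
  Mauchly's test per multi-df effect and the Greenhouse–Geisser
  ε-adjusted dfs and p reported when Mauchly rejects at 0.05 (the
  threshold is configurable); $\eta_p^2 = F\,df_1/(F\,df_1+df_2)$ from
  the *uncorrected* dfs, algebraically identical to
  $SS_{\mathrm{eff}}/(SS_{\mathrm{eff}}+SS_{\mathrm{err}})$;
* Bonferroni correction $\min(1, m\,p)$ with $m$ defaulting to the
  four-emotion family.

Degenerate inputs fail loudly rather than silently: zero-variance t
tests, all-zero signed-rank differences, and incomplete ANOVA cells are
errors; an all-constant within-subject design reports $F = 0$.

# Classification

Linear-kernel SVM, regularisation constant 1 (both configurable; with
two or three features and ≤ 52 rows a linear margin is the defensible
default — no hyperparameter search). Ten-fold cross-validation with
folds *grouped by participant* (both halves of a participant share a
fold) and stratified by label: participants are shuffled within class
and dealt onto a cyclic fold counter that continues across classes, so
every fold is non-empty and classes spread as evenly as possible.
Within each training fold, features are standardised by training
statistics only and the same affine map is applied to the test rows.
Per-fold accuracy and AUC (from decision scores) are averaged with
fold-level standard errors, and fold accuracies are compared against the
50% chance level with a one-sample t test — its df of 9 matches a
ten-fold design.

When the group split is unbalanced (a binomial draw at n = 26 often
leaves one class with fewer participants than folds) some test folds
contain a single class; their AUC is undefined and excluded from the
AUC mean, while accuracy uses all folds. A training fold with a single
class triggers a re-draw of the folds under an incremented seed, and an
error after ten attempts. Multimodal analysis uses the intersection of
participants with usable EEG and SCR features; dropped rows are logged.

# Numerical and design choices

* Sample-index convention: `floor(t × rate)`, half-open windows,
  everywhere (generator, epoching, feature windows, SCR windows).
* Zero-phase filtering throughout; filter transients are absorbed by
  reflection padding sized to the high-pass time constant.
* Determinism: every stochastic stage derives its own stream seed from
  `(seed, participant, stage)`; identical configuration and seed give
  bit-identical schedules, signals, features and reports.
* E scores compose exactly with balanced aggregation (condition-level E
  equals the mean of half-level E when trial counts balance), and the
  sign rule is antisymmetric (negating every deviation from neutral
  flips every label); both are asserted as properties.
* Simulation sizes in the test suite: the classification calibration
  uses 20 replicate cohorts of n = 26 (the study's EEG sample size);
  parameter recovery uses 200 replicates of reduced cohorts (n = 3,
  6-trial blocks), which keeps the Monte-Carlo standard error near 4%
  of the planted effect; null calibration uses one 200-participant
  zero-effect cohort. These sizes were chosen as the smallest that
  make the checks statistically meaningful.

# Known limitations

* The ICA-based ocular-artifact route of real-data practice is not
  implemented; the amplitude threshold plus optional whole-montage
  screening stands in for it, and an EOG-regression hook would be the
  natural extension.
* No EDF reader/writer: EEG interchange uses a delimited channel×time
  matrix with a JSON sidecar. The delimited path is lossless and
  round-trip tested.
* The RM-ANOVA supports complete balanced within-subject designs only —
  the designs this analysis produces; missing cells are a hard error by
  design, not imputed.
* Real-data effect sizes, channel covariance, and artifact structure are
  richer than the generator's; calibration results transfer to real data
  only insofar as the latent-trait model approximates it.
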