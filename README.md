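# emoattn

Multimodal psychophysiological analysis of how rapidly presented
affective pictures change subsequent attention — and for whom.

A flashed emotional scene (80 ms), followed immediately by a cued
flanker trial, speeds some people up and slows others down. `emoattn` is
an R pipeline for paradigms that record EEG, skin conductance (SCR) and
reaction time (RT) simultaneously in such tasks. It is written for
cognitive-neuroscience and psychophysiology researchers who want a
tested, reproducible implementation of the full chain:

1. **Synthetic cohort generator** — ground-truth-annotated multimodal
   sessions (10 blocks × 24 trials, five picture categories, event-locked
   P300/LPP bumps on 1/f + alpha EEG noise, Bateman-kernel phasic SCR,
   additive log-RT model, latent responder traits), so every stage is
   testable without any data download.
2. **EEG preprocessing** — zero-phase 0.1–30 Hz band-pass, average
   re-reference, epoching on [−100, 1000) ms, baseline correction,
   100 µV artifact screening.
3. **Feature extraction** — P300 (mean voltage 250–350 ms) and LPP
   (500–800 ms) at Fz/Cz/Pz; per-trial SCR max-change scores
   (baseline = 500 ms pre-picture mean), log(1+s)-transformed; per-cell
   mean log RT with timeout handling.
4. **E difference scores and stratification** — for every modality and
   emotion,

   `E(modality, emotion) = R(modality, emotion) − R(modality, neutral)`,

   and the sign rule *facilitated* (`E_RT < 0`) vs *impeded*
   (`E_RT > 0`).
5. **Group statistics** — one-sample/paired *t* with Cohen's
   *d* = *t*/√n, Wilcoxon signed-rank with *r* = *Z*/√n, Friedman test,
   repeated-measures ANOVA with Mauchly check, Greenhouse–Geisser
   correction and partial η², Bonferroni correction.
6. **Classification** — participant-grouped, stratified 10-fold
   cross-validated linear SVM predicting facilitated vs impeded from
   physiological E scores, unimodal (P300 + LPP) or multimodal
   (P300 + LPP + SCR), with fold-level accuracy/AUC and a *t* test
   against the 50% chance level.

## Worked example

Simulate a 16-participant cohort (12-trial blocks to keep it quick) and
run the whole pipeline:

```r
library(emoattn)
library(dplyr)

cfg <- cohort_config(n_participants = 16, trials_per_block = 12,
                     timing = list(block_gap_s = 30), seed = 2028)
run <- run_pipeline(cfg, classify_emotions = "horror")

run$stats$one_sample |>
  filter(modality == "SCR") |>
  select(emotion, statistic, p, p_corrected, effect)
#>      emotion statistic     p p_corrected  effect
#> 1   positive    -0.240 0.813       1.000 -0.0601
#> 2     erotic     0.970 0.347       1.000  0.2425
#> 3 mutilation    -0.386 0.705       1.000 -0.0966
#> 4     horror     1.248 0.231       0.925  0.3119
```

One-sample *t* tests of each `E_SCR` against 0, Bonferroni-corrected
over the four emotions; `effect` is Cohen's *d*. (At n = 16 with the
generator's default moderate effects, SCR alone is not significant —
the planted horror elevation shows as the largest *d*.)

```r
run$stats$erp_anova |>
  filter(modality == "P300") |>
  select(effect_name, statistic, df1, df2, p_adj, effect)
#>       effect_name statistic df1 df2   p_adj effect
#> 1         channel      1.09   2  30 0.35005 0.0676
#> 2         emotion      4.78   3  45 0.00563 0.2417
#> 3 channel:emotion      1.83   6  90 0.10167 0.1088
```

The channel × emotion repeated-measures ANOVA on `E_P300`: a clear
emotion main effect (partial η² = 0.24), no channel effect — the planted
structure. `p_adj` is Greenhouse–Geisser-corrected wherever Mauchly's
test rejected.

```r
run$reports$horror_unimodal
#> <classifier_report> unimodal / horror: accuracy 72.5% (SE 7.86),
#>   AUC 0.958 (SE 0.042), t vs 50% = 2.86 (p = 0.0187)
run$reports$horror_multimodal
#> <classifier_report> multimodal / horror: accuracy 77.5% (SE 10.17),
#>   AUC 0.917 (SE 0.083), t vs 50% = 2.70 (p = 0.0243)
run$comparisons$horror$mean_d_accuracy
#> [1] 5
```

Cross-validated prediction of each participant's attentional direction
(facilitated vs impeded in the horror condition) from their
physiological E scores: both feature sets beat chance, and adding SCR
raises mean fold accuracy by 5 percentage points here.

`glance()` and `tidy()` methods give tibble summaries of every report;
`plot_erp()`, `plot_escores()` and `autoplot()` provide the standard
figures.

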