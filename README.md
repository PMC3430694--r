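# voxtune

Voxel tuning functions for a cued artificial-grammar fMRI paradigm.

`voxtune` is a complete, tested reimplementation of the analysis pipeline of a
task-switching experiment that crosses **cognitive control** (CUE: a
contextual cue maps directly to a task, an episodic cue says *repeat* or
*switch* relative to the previous trial) with **sequence processing** (TASK:
judge a center-embedded A^n^B^n^ syllable sequence, or count and match its
/e/- and /o/-final syllables). Crossing the factors gives the four conditions
CG, CC, EG, EC. The original subject data are not available, so the package
ships a first-class synthetic-data generator and validates the *procedure*:
exact reproduction of the session's printed design counts, exhaustive
correctness of the grammar checkers, and parameter recovery plus statistical
calibration of the tuning pipeline on synthetic ground truth.

It is intended for cognitive neuroscientists who want to reuse, scrutinize, or
extend the voxel-tuning-function methodology on their own ROI data
(columnar beta tables or NIfTI timeseries + mask) or on simulations.

## The core procedure

* **Stimuli.** Syllables are plosive+vowel units; the vowel carries the
  category (A: /e,i/; B: /o,u/). A length-2n sequence is grammatical iff it
  is A^n^B^n^ with mirrored consonant pairing b–p, d–t, g–k
  (A1A2A3B3B2B1, e.g. */be di ge ko tu pu/*). The count judgment asks whether
  #/e/-final = #/o/-final.
* **Design.** 192 trials (48 per condition), 96 contextual / 96 episodic
  cues, 50/50 stimulus labels within each task, counterbalanced task
  transitions, jitter 0–1500 ms, 48 interleaved null events, TR = 2 s.
* **Betas.** Correct trials are randomly split into 6 runs (8 per condition
  per run); a GLM per run models the four conditions as HRF-convolved
  impulses at cue onset plus one pooled nuisance regressor, DCT high-pass
  (128 s) and intercept; betas are z-normalized per voxel.
* **Voxel tuning (leave-one-run-out).** On 5 classification runs a voxel's
  preference is the condition with the largest mean beta; it is kept only if
  that preference wins in ≥ 3 of the 5 runs; its 4-point tuning curve is
  read from the held-out analysis run. Tuned-voxel counts (fold-averaged)
  enter a within-subject 2×2 ANOVA, and tuning success is a paired t of each
  condition's curve peak against the mean of the other three conditions.

## Worked example

```r
library(voxtune)
set.seed(7)

generate_sequence(n = 3, grammatical = TRUE, countmatch = FALSE)
#> di bi ge ko pu to [grammatical: TRUE, count-match: FALSE]
is_grammatical("be di ge ko tu pu")
#> [1] TRUE

schedule <- generate_schedule()
schedule
#> Session schedule: 192 trials + 48 null events; TR = 2 s
#> CC CG EC EG
#> 48 48 48 48

pop <- make_voxel_population(120,
  c(CG = .15, CC = .10, EG = .30, EC = .10, untuned = .35),
  tuning_gain = 0.5, noise_sd = 1)
amplitudes <- simulate_trial_amplitudes(pop, schedule)
bold <- simulate_bold(amplitudes, schedule, noise_sd = 1)
behavior <- simulate_behavior(schedule)
assignment <- assign_trials_to_runs(schedule, behavior, n_runs = 6)
betas <- extract_beta_array(schedule, assignment, bold)
summarize_tuning(loocv_tuning(znormalize(betas)))
#> Tuned-voxel counts (mean over 6 folds, 120 voxels):
#>    CG    CC    EG    EC
#> 15.67 12.83 28.17 11.00
#> untuned fraction: 0.436
```

The counts say: of 120 voxels (36 of them truly tuned to EG, 18 to CG, 12
each to CC and EC, 42 untuned), the winner-take-all classifier with the
3-of-5 reliability filter keeps on average 28.2 voxels as EG-tuned per fold,
15.7 as CG, and so on. Untuned voxels are not all rejected — under pure
noise a voxel still passes the filter with probability ≈ 0.34 (see the
methods vignette) — which is why counts exceed the true tuned numbers and
why the group-level ANOVA on counts, not a per-voxel threshold, carries the
inference.

## The analysis workflow

Numbered drivers under `analysis/` run the full study-scale analysis and
write their tables under `results/`:

1. `01_simulate_session.R` — one session schedule + stimulus examples
   (`session_events.tsv`, `stimulus_examples.tsv`).
2. `02_simulate_cohort.R` — 21 simulated subjects: behavior and run-wise
   GLM betas (`behavior/`, `betas/`).
3. `03_voxel_tuning.R` — leave-one-run-out tuning per subject
   (`tuning_counts.tsv`, `tuning_curves.tsv`).
4. `04_group_stats.R` — 2×2 ANOVAs on errors, RTs and tuned counts,
   tuning-success t tests, speed–accuracy correlations
   (`group_stats.json`).

`run_pipeline(run_config(...))` performs the same end-to-end run as a single
call with one master seed and writes a reproducible report bundle.

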