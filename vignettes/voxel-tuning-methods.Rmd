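---
title: "Voxel tuning functions for a cued artificial-grammar paradigm: models and methods"
author: "voxtune"
output: rmarkdown::html_vignette
---

# Overview

`voxtune` reimplements, as a tested pipeline over synthetic data, the analysis
of a task-switching fMRI experiment in which cognitive control (which rule to
apply, signalled by a cue) is crossed with sequence processing (which rule is
applied to a syllable sequence). The package covers five stages:

1. **Stimuli** (`generate_sequence`, `is_grammatical`, `count_match`) —
   center-embedded A^n^B^n^ syllable sequences and the two judgments made on
   them.
2. **Session design** (`generate_schedule`) — the counterbalanced 2×2
   (CUE × TASK) event-related schedule with jitter and null events.
3. **Synthetic data** (`make_voxel_population`, `simulate_trial_amplitudes`,
   `simulate_bold`, `simulate_behavior`) — condition-tuned voxels, trial
   amplitudes, HRF-convolved BOLD, and trial-level behavior.
4. **Beta estimation** (`assign_trials_to_runs`, `extract_beta_array`,
   `znormalize`) — run-wise condition betas by ordinary least squares.
5. **Voxel tuning and group statistics** (`loocv_tuning`, `summarize_tuning`,
   `tuning_success`, `rm_anova_2x2`, `paired_t`, `pearson_r`).

The original subject data are not publicly available, so the package's claims
are about the *procedure*: the generators reproduce the session's printed
count structure exactly, the checkers agree with exhaustive enumeration, and
the tuning pipeline recovers known synthetic ground truth with calibrated
error rates.

# The artificial grammar

A syllable is a plosive consonant (b, d, g, p, t, k) plus a vowel. The vowel
carries the category: A syllables end in /e/ or /i/, B syllables in /o/ or
/u/. A sequence of length $2n$ is grammatical iff the first $n$ syllables are
category A, the last $n$ category B, and the consonants obey the mirrored
pairing $A_1 A_2 \dots A_n B_n \dots B_2 B_1$ under the voiced/voiceless
involution b↔p, d↔t, g↔k. The count judgment asks instead whether the number
of /e/-final syllables equals the number of /o/-final syllables; since only A
syllables can end in /e/ and only B syllables in /o/, both counts range over
$0..n$.

Generator conventions, where the design was open:

* A syllables take the voiced plosives (b, d, g) and B syllables the
  voiceless partners, following the one worked stimulus layout; the *checker*
  is deliberately more general and accepts any consonant assignment that
  satisfies the mirrored pairing.
* Ungrammatical sequences are a grammatical sequence with the B consonants
  permuted (leaving at least one mirrored pair broken), never a broken
  A-block/B-block shape — the violation is purely in the concatenation
  matching. At $n = 1$ no such permutation exists and the request errors.
* Vowels are drawn uniformly over all assignments consistent with the
  requested count/match label, weighting the (number of /e/, number of /o/)
  pair by its multiplicity, so the two labels are generated independently.
* $n \le 3$: the generator insists on distinct A consonants (only three
  voiced plosives exist), which also guarantees that any B permutation breaks
  a pair.

# Session design

The session has $4 \times 48 = 192$ trials: 96 contextual cues (48 squares →
grammar task, 48 diamonds → count task) and 96 episodic cues (48 upward
triangles = repeat the previous task, 48 downward = switch). Trial order is
found by seeded local search (pairwise swaps that never increase a penalty,
with restarts) over four constraints: the session-initial trial is contextual
(an episodic cue has no predecessor to resolve against — the original procedure
leaves this undefined, so the package forbids it); exactly half of the
episodic cues are repeats, which makes the episodic-grammar and
episodic-count cells come out at 48 each after resolution; and the four task
transitions (grammar→grammar, …) are counterbalanced to within one. Each
trial spans jitter (0/500/1000/1500 ms, balanced within condition) + 1000 ms
cue + 6 × 1000 ms syllables + 2000 ms response + 500 ms feedback + 3000 ms
fixation = 12.5 s + jitter. 48 null events of trial-equivalent duration are
interleaved uniformly at random. Whether the original randomization also
constrained cue-kind transitions is unknown; the package constrains only task
transitions, the only counterbalancing the original procedure states.

# Synthetic data model

Each voxel $v$ has a mean-response 4-vector $\mu_v$ over the conditions CG,
CC, EG, EC. A tuned voxel has its preferred entry elevated by `tuning_gain`
(default 0.5 signal units) over the others (at 0); an untuned voxel is flat.
Trial amplitudes are $a_{tv} = \text{baseline} + \mu_v[c(t)] +
\varepsilon_{tv}$ with i.i.d. Gaussian trial noise (`trial_noise_sd`, default
1) — the simplest model consistent with the GLM's assumptions. BOLD is the
linear superposition of a canonical double-gamma HRF impulse (response gamma
shape 6, undershoot shape 16, ratio 6:1, 32 s support, unit peak) placed at
each cue onset, sampled on the TR = 2 s grid, plus Gaussian scanner noise
(optionally AR(1); coefficient default 0) and an optional slow sinusoidal
drift. Behavior is Bernoulli errors and truncated-Gaussian RTs per condition;
the default error cells (CG 4.15, CC 1.65, EG 6.85, EC 4.35 %) are the
additive decomposition of the study-scale margins (grammar 5.5 vs count
3.0 %, episodic 5.6 vs contextual 2.9 %), and RT means follow the task
margins (798 vs 812 ms) with a typical 150 ms single-trial spread. These are
generator defaults that reproduce the reported means in expectation, not
fitted values.

The generator deliberately omits: spatial correlation and smoothness, motion
and physiological noise, slice timing, non-linear HRF effects, and
between-voxel noise correlations. Passing tests therefore show that the
*analysis* is correct and calibrated under its own assumptions, not that it
is robust to everything real data do.

# Beta estimation

Correct trials are randomly partitioned, per condition, into 6 runs of 8 (at
study scale); the assignment differs across subjects. Erroneous trials are
flagged and never enter a condition regressor; correct trials in excess of
the divisible count are dropped at random, keeping run sizes equal for the
classifier. The default GLM follows the literal description: one GLM per run
partition, with four condition regressors (duration-0 events at cue onset,
HRF-convolved), a single pooled nuisance regressor (all other trials,
erroneous trials, and null events), discrete-cosine drift regressors with a
128 s cutoff, and an intercept. The source leaves open whether a single
24-regressor (run × condition) GLM was used instead; `variant = "single"`
selects it. The two differ slightly under noise, and only the single-GLM
variant matches the simulator's generative model exactly — with the per-run
variant the pooled nuisance column cannot represent condition-heterogeneous
amplitudes, so even noiseless betas carry a small bias; the package's exact
recovery checks therefore use `"single"`, while `"per-run"` remains the
default analysis setting.

Betas are z-normalized per voxel across the 24 run × condition cells (the
normalization axis is not stated in the original description; per-voxel matches the stated
purpose of removing mean-intensity differences). Constant or non-finite
voxels cannot be standardized; they are NaN-flagged, excluded from the tuned
count accounting, and reported separately.

# Voxel tuning

For each of six folds, one run is the analysis run and the other five the
classification runs. A voxel's preference is the condition with the largest
mean beta across classification runs; an exact tie leaves the voxel untuned
for the fold (ties have measure zero under continuous noise, so this rule is
unbiased and almost never fires). The reliability filter requires the
preference to also be the within-run winner in at least half of the
classification runs — read as $\lceil 5/2 \rceil = 3$ of 5, the only integer
reading. The 4-point tuning curve is taken exclusively from the held-out
analysis run, so voxel selection and curve measurement use disjoint data;
the tests verify this by mutating classification runs and observing
unchanged curves. Tuned-voxel counts are averaged (not summed) over the six
folds, keeping per-subject quantities on the voxel-count scale of a single
session; `aggregate = "sum"` is available. Whether the original per-subject
count was a fold average, a fold sum, or required cross-fold consistency is
not stated; the fold average is the package's choice.

## Null behavior of the reliability filter

Under exchangeable conditions (no tuning), each classification run's winner
is uniform over the four conditions, approximately independently across
runs. Enumerating all $4^5 = 1024$ per-run winner patterns, some condition
achieves a 3-of-5 majority in $424/1024 \approx 0.414$ of them
(`null_reliability_rate()`). That enumeration is an *upper bound* on the
fraction of voxels the pipeline actually keeps under the null: a voxel is
kept only if the across-run *mean* winner — the preference rule — coincides
with the vote majority, which happens in roughly 82 % of majority patterns.
The pipeline's empirical null tuned fraction is therefore ≈ 0.34 (about
0.085 per condition), as both the package's test-suite oracle simulations
and the acceptance script's `null_tuned_fraction` output show. Analyses
comparing tuned counts against chance should use the empirical/simulated
rate, not the vote-enumeration bound.

## Tuning success

For condition $c$, each subject contributes the mean analysis-run beta of
its $c$-tuned voxels at $c$, paired with the mean of those voxels' betas
over the other three conditions; a paired t across subjects tests
selectivity. Because the curve comes from the held-out run, this statistic
is calibrated under the null (selection bias would otherwise make it
anti-conservative); the test suite verifies a ≈ 5 % type-I rate. Subjects
without any $c$-tuned voxel are excluded with a warning and the degrees of
freedom reduced.

# Group statistics

`rm_anova_2x2` fits the within-subject CUE × TASK decomposition through
`stats::aov` error strata; every effect has one numerator degree of freedom,
so each $F(1, n-1)$ equals the squared paired t on the corresponding
within-subject contrast (verified to 1e-10), p values are two-tailed, and
sphericity correction is moot. Effects whose contrast is identically zero
(e.g. the interaction on exactly additive data) are reported as $F = 0$,
$p = 1$ rather than 0/0. `paired_t` flags zero-variance differences instead
of returning NaN — near-ceiling accuracy makes this a real case, as some
simulated (and real) subjects commit no errors.

# Numerical choices and problem sizes

* OLS is solved by QR; rank deficiency is an error naming the collinear
  columns.
* The HRF is evaluated as a continuous function shared by the simulator and
  the design-matrix builder, so noiseless simulation lies exactly in the
  design span and recovery checks can demand 1e-6 (achieved ≈ 1e-15).
* z-normalization is idempotent to 1e-12.
* Counterbalancing search: penalty-guided random swaps, 40,000 swaps × 25
  restarts bound; at study scale it converges in well under a second.
* Test-suite problem sizes are chosen to keep the full suite around half a
  minute while leaving Monte-Carlo error well inside the asserted bands:
  calibration runs use 1000 replicates; null-calibration checks use
  1000-voxel ROIs over tens of seeds with the fast cell-mean beta estimator
  (`betas_from_cell_means`, the orthogonal-design limit of the GLM);
  exact-recovery checks run the full BOLD + GLM path at study scale.

# Known limitations

* The per-run GLM variant's noiseless bias (above) is inherent to pooling
  heterogeneous conditions in one nuisance regressor; it is small relative
  to typical noise but visible in exact checks.
* ROI definition (orthogonal F-test selection, cluster thresholds) is out of
  scope: ROIs are inputs, either synthetic populations or user-supplied
  masks (`read_roi_timeseries`).
* The behavioral generator draws error and RT independently per trial; it
  reproduces condition means, not RT distributions or sequential effects.
* Group F and t values from the original subjects are not reproducible and
  are not targets; only design counts, worked examples, and
  recovery/calibration properties are.
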