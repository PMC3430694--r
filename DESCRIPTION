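Package: voxtune
Title: Voxel Tuning Functions for a Cued Artificial-Grammar fMRI Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, end to end and on synthetic data, the analysis pipeline of a
    task-switching artificial-grammar fMRI study: generation and verification of
    center-embedded AnBn consonant-vowel syllable sequences with a count/match control
    task, construction of the counterbalanced 2x2 (cue x task) event-related session
    schedule with jittered timing and null events, simulation of condition-tuned voxel
    populations, trial amplitudes, HRF-convolved BOLD timeseries and trial-level
    behavior, run-wise GLM beta estimation with discrete-cosine high-pass drift terms
    and z-normalization, leave-one-run-out voxel tuning functions with a majority-vote
    reliability filter, and the group-level statistics (within-subject 2x2 ANOVA,
    paired t tests, Pearson correlation) applied to behavior and tuned-voxel counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
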