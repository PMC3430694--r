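# Shared fixtures, all generated in code.

# Wrap a plain array as an (unnormalized) beta array.
as_beta_array <- function(arr) {
  structure(arr, class = "beta_array", normalized = FALSE)
}

# Runs x conditions x voxels array holding each voxel's true means, the
# noiseless beta target.
mu_beta_array <- function(pop, n_runs = 6L) {
  arr <- array(NA_real_, c(n_runs, 4L, pop$n_voxels))
  for (r in seq_len(n_runs)) arr[r, , ] <- t(pop$mu)
  as_beta_array(arr)
}

# Assert every count invariant of a generated session schedule.
check_schedule_invariants <- function(sch) {
  tr <- sch$trials
  npc <- sch$n_per_condition
  n <- nrow(tr)
  expect_equal(n, 4L * npc)
  expect_equal(unname(table(tr$condition)[c("CG", "CC", "EG", "EC")]),
               rep(npc, 4L), ignore_attr = TRUE)
  expect_equal(sum(tr$cue_kind == "contextual"), 2L * npc)
  expect_equal(sum(tr$cue_kind == "episodic"), 2L * npc)
  sym <- table(factor(tr$cue_symbol, levels = c("square", "diamond",
                                                "triangle_up", "triangle_down")))
  expect_equal(unname(sym), rep(npc, 4L), ignore_attr = TRUE)
  expect_equal(sum(tr$resolved_task == "grammar"), 2L * npc)
  expect_equal(sum(tr$resolved_task == "count"), 2L * npc)
  # 50/50 stimulus labels within each task
  g <- tr$resolved_task == "grammar"
  expect_equal(sum(tr$is_grammatical[g]), npc)
  expect_equal(sum(tr$count_match[!g]), npc)
  # session starts contextual; episodic replay consistent
  expect_equal(tr$cue_kind[1L], "contextual")
  expect_true(verify_episodic_resolution(sch))
  # task transitions counterbalanced within 1
  trans <- table(factor(paste(tr$resolved_task[-n], tr$resolved_task[-1L]),
                        levels = c("grammar grammar", "grammar count",
                                   "count grammar", "count count")))
  expect_lte(max(trans) - min(trans), 1L)
  # jitter levels each cover a quarter of every condition
  for (cc in c("CG", "CC", "EG", "EC")) {
    jt <- table(factor(tr$jitter_ms[tr$condition == cc],
                       levels = c(0, 500, 1000, 1500)))
    expect_lte(max(jt) - min(jt), 1L)
  }
  # stimulus labels verified by the checkers
  expect_true(all(vapply(seq_len(n), function(i) {
    is_grammatical(tr$sequence[i]) == tr$is_grammatical[i] &&
      count_match(tr$sequence[i]) == tr$count_match[i]
  }, logical(1L))))
  expect_equal(sum(sch$stream$type == "null"), sch$n_null)
  invisible(TRUE)
}
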