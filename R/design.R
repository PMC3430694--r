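# The four experimental conditions cross cue kind (Contextual/Episodic) with
# resolved task (Grammar/Count).
CONDITIONS <- c("CG", "CC", "EG", "EC")

#' The four experimental conditions
#' @return Character vector `c("CG", "CC", "EG", "EC")`.
#' @export
conditions <- function() CONDITIONS

# Default per-trial stage durations (ms): cue, six syllables, response window,
# feedback, fixation.  A trial without jitter spans 12,500 ms.
default_timing <- function() {
  list(cue_ms = 1000, syllable_ms = 1000, n_syllables = 6L,
       response_ms = 2000, feedback_ms = 500, fixation_ms = 3000)
}

trial_span_ms <- function(timing = default_timing()) {
  timing$cue_ms + timing$n_syllables * timing$syllable_ms +
    timing$response_ms + timing$feedback_ms + timing$fixation_ms
}

#' Resolve an episodic cue to a task
#'
#' An upward triangle repeats the previously performed task; a downward
#' triangle switches to the other task.
#'
#' @param previous_task `"grammar"` or `"count"`; the task performed on the
#'   previous trial.  An episodic cue on the session-initial trial has no
#'   predecessor and is an error.
#' @param symbol `"triangle_up"` or `"triangle_down"`.
#' @return `"grammar"` or `"count"`.
#' @export
resolve_episodic <- function(previous_task, symbol) {
  if (is.null(previous_task) || length(previous_task) == 0L || is.na(previous_task)) {
    stop("episodic cue has no previous task to resolve against ",
         "(session-initial trial must be contextual)")
  }
  previous_task <- match.arg(previous_task, c("grammar", "count"))
  symbol <- match.arg(symbol, c("triangle_up", "triangle_down"))
  if (symbol == "triangle_up") previous_task
  else if (previous_task == "grammar") "count" else "grammar"
}

# Penalty for a candidate ordering of (cue_kind, task) labels:
#  - session-initial trial must be contextual,
#  - exactly half of the episodic trials must be repeats (balancing the
#    up/down triangle symbols and hence EG/EC after resolution),
#  - the four task-transition counts must each lie in {floor, ceil} of
#    (N-1)/4 (counterbalanced transitions).
.order_penalty <- function(kind, task) {
  n <- length(task)
  pen <- if (kind[1L] != "contextual") 10L else 0L
  prev <- task[-n]
  cur <- task[-1L]
  trans <- table(factor(paste(prev, cur), levels = c(
    "grammar grammar", "grammar count", "count grammar", "count count")))
  lo <- (n - 1L) %/% 4L
  hi <- as.integer(ceiling((n - 1L) / 4))
  pen <- pen + sum(pmax(0L, lo - trans) + pmax(0L, trans - hi))
  ep <- which(kind == "episodic")
  ep <- ep[ep > 1L]
  repeats <- sum(task[ep] == task[ep - 1L])
  pen + abs(repeats - sum(kind == "episodic") %/% 2L)
}

# Seeded local search over orderings: random swaps accepted when the penalty
# does not increase, with restarts.  The constraint set is loose at study
# scale, so this converges quickly.
.arrange_trials <- function(kind, task, max_iter = 40000L, max_restarts = 25L) {
  n <- length(task)
  for (restart in seq_len(max_restarts)) {
    ord <- sample.int(n)
    # force a contextual trial first
    ctx <- which(kind[ord] == "contextual")[1L]
    if (ctx != 1L) ord[c(1L, ctx)] <- ord[c(ctx, 1L)]
    k <- kind[ord]; t <- task[ord]
    pen <- .order_penalty(k, t)
    iter <- 0L
    while (pen > 0L && iter < max_iter) {
      iter <- iter + 1L
      ij <- sample.int(n, 2L)
      k2 <- k; t2 <- t
      k2[ij] <- k[rev(ij)]; t2[ij] <- t[rev(ij)]
      pen2 <- .order_penalty(k2, t2)
      if (pen2 <= pen) {
        k <- k2; t <- t2; pen <- pen2
        ord[ij] <- ord[rev(ij)]
      }
    }
    if (pen == 0L) return(ord)
  }
  stop("counterbalancing unsatisfiable within ", max_restarts, " restarts x ",
       max_iter, " swaps (n = ", n, " trials); relax the trial counts")
}

# Balanced assignment of a set of levels within each condition (used for
# jitter: each of the four levels covers 1/4 of each condition's trials).
.balanced_within <- function(condition, levels) {
  out <- numeric(length(condition))
  for (cc in unique(condition)) {
    idx <- which(condition == cc)
    reps <- rep(levels, length.out = length(idx))
    out[idx] <- sample(reps)
  }
  out
}

#' Generate a counterbalanced 2x2 cue-by-task session schedule
#'
#' Builds the event-related session: `4 * n_per_condition` trials split evenly
#' over the four conditions (CG, CC, EG, EC), with squares/diamonds as
#' contextual cues, up/down triangles as episodic cues resolved against the
#' previous task, task transitions counterbalanced, per-task 50/50 splits of
#' the relevant stimulus label, jitter balanced within condition, and
#' `n_null` null events (fixation only, trial-equivalent duration) interleaved
#' uniformly at random.
#'
#' @param n_per_condition Trials per condition (study value 48; must be even).
#' @param n_null Number of null events (study value 48).
#' @param jitters_ms Jitter levels in ms (study values 0, 500, 1000, 1500).
#' @param timing Stage timing list, see `default_timing()`.
#' @param tr Repetition time in seconds (study value 2).
#' @param max_iter,max_restarts Bounds for the counterbalancing search.
#' @return An object of class `ag_schedule`: list with `trials` (data frame),
#'   `stream` (interleaving of trials and null events), `timing`, `tr`,
#'   `n_per_condition`, `n_null`.
#' @export
generate_schedule <- function(n_per_condition = 48L, n_null = 48L,
                              jitters_ms = c(0, 500, 1000, 1500),
                              timing = default_timing(), tr = 2,
                              max_iter = 40000L, max_restarts = 25L) {
  n_per_condition <- as.integer(n_per_condition)
  if (n_per_condition < 2L || n_per_condition %% 2L != 0L) {
    stop("n_per_condition must be an even integer >= 2")
  }
  kind <- rep(c("contextual", "contextual", "episodic", "episodic"),
              each = n_per_condition)
  task <- rep(c("grammar", "count", "grammar", "count"),
              each = n_per_condition)
  ord <- .arrange_trials(kind, task, max_iter = max_iter,
                         max_restarts = max_restarts)
  kind <- kind[ord]; task <- task[ord]
  n_trials <- length(task)

  # cue symbols follow from kind, task, and the previous task
  symbol <- character(n_trials)
  for (i in seq_len(n_trials)) {
    if (kind[i] == "contextual") {
      symbol[i] <- if (task[i] == "grammar") "square" else "diamond"
    } else {
      symbol[i] <- if (task[i] == task[i - 1L]) "triangle_up" else "triangle_down"
    }
  }
  condition <- paste0(ifelse(kind == "contextual", "C", "E"),
                      ifelse(task == "grammar", "G", "C"))

  # stimulus labels: within each task, the task-relevant label is split 50/50;
  # the task-irrelevant label is balanced as well, independently shuffled
  is_gram <- logical(n_trials); is_match <- logical(n_trials)
  for (tk in c("grammar", "count")) {
    idx <- which(task == tk)
    half <- length(idx) %/% 2L
    is_gram[idx] <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
    is_match[idx] <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
  }
  seqs <- vapply(seq_len(n_trials), function(i) {
    format(generate_sequence(3L, is_gram[i], is_match[i]))
  }, character(1L))

  correct <- ifelse(task == "grammar",
                    ifelse(is_gram, "yes", "no"),
                    ifelse(is_match, "yes", "no"))
  jitter <- .balanced_within(condition, jitters_ms)

  trials <- data.frame(
    index = seq_len(n_trials),
    cue_kind = kind, cue_symbol = symbol, resolved_task = task,
    condition = condition, sequence = seqs,
    is_grammatical = is_gram, count_match = is_match,
    correct_response = correct, jitter_ms = jitter,
    stringsAsFactors = FALSE
  )

  # interleave null events uniformly at random among the stream positions
  n_stream <- n_trials + n_null
  null_pos <- sort(sample.int(n_stream, n_null))
  stream <- data.frame(stream_index = seq_len(n_stream),
                       type = "trial", trial = NA_integer_,
                       jitter_ms = NA_real_, stringsAsFactors = FALSE)
  stream$type[null_pos] <- "null"
  stream$trial[stream$type == "trial"] <- seq_len(n_trials)
  stream$jitter_ms[stream$type == "trial"] <- jitter
  stream$jitter_ms[stream$type == "null"] <-
    sample(rep(jitters_ms, length.out = n_null))

  out <- list(trials = trials, stream = stream, timing = timing, tr = tr,
              n_per_condition = n_per_condition, n_null = n_null)
  class(out) <- "ag_schedule"
  out
}

#' @export
print.ag_schedule <- function(x, ...) {
  cat("Session schedule:", nrow(x$trials), "trials +", x$n_null,
      "null events; TR =", x$tr, "s\n")
  print(table(x$trials$condition))
  invisible(x)
}

#' Compute stage-level onsets for a schedule
#'
#' Events are laid out back to back in stream order; each trial (and each
#' null event) occupies `jitter + cue + 6 syllables + response + feedback +
#' fixation`.  The cue onset (used as the GLM event onset) follows the jitter.
#'
#' @param schedule An `ag_schedule`.
#' @return Data frame with one row per stream element: `stream_index`, `type`,
#'   `trial`, `onset_ms` (element start), `cue_onset_ms`, `duration_ms`,
#'   `jitter_ms`, plus stage onsets `syllables_on_ms`, `response_on_ms`,
#'   `feedback_on_ms`, `fixation_on_ms`.
#' @export
schedule_onsets <- function(schedule) {
  stopifnot(inherits(schedule, "ag_schedule"))
  st <- schedule$stream
  tm <- schedule$timing
  span <- trial_span_ms(tm)
  if (nrow(st) == 0L) {
    return(data.frame(stream_index = integer(), type = character(),
                      trial = integer(), onset_ms = numeric(),
                      cue_onset_ms = numeric(), duration_ms = numeric(),
                      jitter_ms = numeric()))
  }
  dur <- st$jitter_ms + span
  onset <- cumsum(c(0, dur[-length(dur)]))
  cue_on <- onset + st$jitter_ms
  out <- data.frame(
    stream_index = st$stream_index, type = st$type, trial = st$trial,
    onset_ms = onset, cue_onset_ms = cue_on, duration_ms = dur,
    jitter_ms = st$jitter_ms,
    syllables_on_ms = cue_on + tm$cue_ms,
    response_on_ms = cue_on + tm$cue_ms + tm$n_syllables * tm$syllable_ms,
    feedback_on_ms = cue_on + tm$cue_ms + tm$n_syllables * tm$syllable_ms +
      tm$response_ms,
    fixation_on_ms = cue_on + tm$cue_ms + tm$n_syllables * tm$syllable_ms +
      tm$response_ms + tm$feedback_ms
  )
  if (any(diff(out$onset_ms) <= 0)) stop("internal error: overlapping events")
  out
}

#' Replay episodic cues and check stored resolved tasks
#'
#' Walks the trial order, resolving each episodic cue against the previous
#' trial's task, and compares with the stored `resolved_task`.
#'
#' @param schedule An `ag_schedule`.
#' @return TRUE invisibly; stops on divergence.
#' @export
verify_episodic_resolution <- function(schedule) {
  tr <- schedule$trials
  prev <- NA_character_
  for (i in seq_len(nrow(tr))) {
    expected <- if (tr$cue_kind[i] == "contextual") {
      if (tr$cue_symbol[i] == "square") "grammar" else "count"
    } else {
      resolve_episodic(prev, tr$cue_symbol[i])
    }
    if (expected != tr$resolved_task[i]) {
      stop("stored/derived task divergence at trial ", i)
    }
    prev <- tr$resolved_task[i]
  }
  invisible(TRUE)
}

#' Write a BIDS-style events TSV
#'
#' One row per stream element (trials and null events), onsets in seconds at
#' the cue (trials) or the element start plus jitter (nulls).
#'
#' @param schedule An `ag_schedule`.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in a comment-free extra column.
#' @return The data frame written, invisibly.
#' @export
write_events_tsv <- function(schedule, path, seed = NA_integer_) {
  on <- schedule_onsets(schedule)
  tr <- schedule$trials
  is_trial <- on$type == "trial"
  df <- data.frame(
    onset = on$cue_onset_ms / 1000,
    duration = (on$duration_ms - on$jitter_ms) / 1000,
    trial_type = ifelse(is_trial, tr$condition[on$trial], "null"),
    cue_symbol = ifelse(is_trial, tr$cue_symbol[on$trial], "n/a"),
    sequence = ifelse(is_trial, tr$sequence[on$trial], "n/a"),
    correct_response = ifelse(is_trial, tr$correct_response[on$trial], "n/a"),
    jitter_ms = on$jitter_ms,
    seed = seed
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
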