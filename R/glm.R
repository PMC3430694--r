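# Canonical double-gamma HRF: response gamma with shape 6, undershoot gamma
# with shape 16, peak-to-undershoot ratio 6:1, support truncated at 32 s,
# normalized to unit peak.  The same continuous function is used by the BOLD
# simulator and the design-matrix builder, so a noiseless simulation lies
# exactly in the span of the matching design.

.hrf_raw <- function(t) dgamma(t, shape = 6, rate = 1) -
  dgamma(t, shape = 16, rate = 1) / 6

.hrf_peak <- local({
  peak <- NULL
  function() {
    if (is.null(peak)) {
      peak <<- optimize(.hrf_raw, c(0, 32), maximum = TRUE,
                        tol = 1e-10)$objective
    }
    peak
  }
})

#' Total duration of the canonical HRF kernel (seconds)
#' @return 32.
#' @export
hrf_duration <- function() 32

#' Evaluate the canonical double-gamma HRF at arbitrary times
#'
#' Zero outside `[0, 32]` s; unit peak (maximum value 1 at about 5 s).
#'
#' @param t Numeric vector of times in seconds.
#' @return Numeric vector of HRF values.
#' @export
hrf_eval <- function(t) {
  out <- numeric(length(t))
  ok <- t >= 0 & t <= hrf_duration()
  out[ok] <- .hrf_raw(t[ok]) / .hrf_peak()
  out
}

#' Sample the canonical HRF on a regular grid
#'
#' @param dt Sampling step in seconds (> 0).
#' @return Numeric vector `hrf_eval(seq(0, 32, by = dt))`.
#' @export
canonical_hrf <- function(dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  hrf_eval(seq(0, hrf_duration(), by = dt))
}

# One HRF-convolved regressor per trial: column t holds the kernel evaluated
# at (volume time - onset_t).  Events are duration-0 impulses at the cue.
trial_regressors <- function(onsets_s, n_vols, tr) {
  vol_t <- (seq_len(n_vols) - 1L) * tr
  vapply(onsets_s, function(o) hrf_eval(vol_t - o), numeric(n_vols))
}

#' Discrete-cosine high-pass drift basis
#'
#' DCT regressors with periods longer than `cutoff_s` seconds, the standard
#' fMRI high-pass implementation (cutoff 128 s in this pipeline).
#'
#' @param n_vols Number of volumes.
#' @param tr Repetition time (s).
#' @param cutoff_s High-pass cutoff period (s).
#' @return Matrix `n_vols x K` with `K = floor(2 * n_vols * tr / cutoff_s)`
#'   (possibly 0 columns).
#' @export
dct_drift <- function(n_vols, tr, cutoff_s = 128) {
  K <- floor(2 * n_vols * tr / cutoff_s)
  if (K < 1L) return(matrix(numeric(0), nrow = n_vols, ncol = 0L))
  i <- seq_len(n_vols) - 1L
  X <- vapply(seq_len(K), function(k) {
    cos(pi * k * (2 * i + 1) / (2 * n_vols))
  }, numeric(n_vols))
  colnames(X) <- paste0("drift", seq_len(K))
  X
}

#' Randomly assign correct trials to cross-validation runs
#'
#' The session is divided into `n_runs` arbitrary runs for cross-validation:
#' per condition, `floor(n_correct / n_runs)` correct trials go to each run
#' (8 per run at study scale, 48/6), drawn at random without overlap.  Correct
#' trials in excess of the divisible count are dropped at random (they join
#' the nuisance regressor), and erroneous trials are spread at random across
#' runs but flagged so they never enter a condition regressor.
#'
#' @param schedule An `ag_schedule`.
#' @param behavior Optional data frame from `simulate_behavior()`; trials with
#'   `correct == FALSE` are flagged as errors.  `NULL` treats all trials as
#'   correct.
#' @param n_runs Number of runs (study value 6).
#' @return Object of class `run_assignment`: data frame with `trial`,
#'   `condition`, `run`, `role` in \{"assigned", "dropped", "error"\};
#'   attribute `n_runs`.
#' @export
assign_trials_to_runs <- function(schedule, behavior = NULL, n_runs = 6L) {
  stopifnot(inherits(schedule, "ag_schedule"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  tr <- schedule$trials
  correct <- rep(TRUE, nrow(tr))
  if (!is.null(behavior)) {
    stopifnot(nrow(behavior) == nrow(tr))
    correct <- behavior$correct
  }
  out <- data.frame(trial = tr$index, condition = tr$condition,
                    run = NA_integer_, role = "error",
                    stringsAsFactors = FALSE)
  out$role[correct] <- "dropped"
  for (cc in CONDITIONS) {
    idx <- which(tr$condition == cc & correct)
    per_run <- length(idx) %/% n_runs
    if (per_run < 1L) {
      stop("too few correct trials in condition ", cc, ": ", length(idx),
           " available, need at least ", n_runs)
    }
    keep <- sample(idx, per_run * n_runs)
    out$run[keep] <- rep(seq_len(n_runs), each = per_run)
    out$role[keep] <- "assigned"
  }
  err <- which(!correct)
  if (length(err)) out$run[err] <- sample.int(n_runs, length(err), replace = TRUE)
  class(out) <- c("run_assignment", "data.frame")
  attr(out, "n_runs") <- n_runs
  out
}

#' Build the design matrix for one cross-validation run's GLM
#'
#' Columns: one HRF-convolved regressor per condition built from that run's
#' assigned trials (duration-0 events at cue onset), one nuisance regressor
#' pooling every other event (other runs' trials, dropped trials, erroneous
#' trials, and null events), the discrete-cosine drift basis, and an
#' intercept.
#'
#' @param schedule An `ag_schedule`.
#' @param assignment A `run_assignment`.
#' @param run Run index whose trials form the condition regressors.
#' @param n_vols Number of volumes (defaults to the simulator's grid for this
#'   schedule).
#' @param cutoff_s High-pass cutoff period (s).
#' @return List with `X` (matrix), `condition_cols` (indices of the four
#'   condition columns), `n_vols`.
#' @export
build_run_design <- function(schedule, assignment, run,
                             n_vols = NULL, cutoff_s = 128) {
  stopifnot(inherits(schedule, "ag_schedule"),
            inherits(assignment, "run_assignment"))
  on <- schedule_onsets(schedule)
  tr_on <- on$cue_onset_ms[on$type == "trial"] / 1000
  null_on <- on$cue_onset_ms[on$type == "null"] / 1000
  if (is.null(n_vols)) {
    session_end_s <- max(on$onset_ms + on$duration_ms) / 1000
    n_vols <- ceiling((session_end_s + hrf_duration()) / schedule$tr)
  }
  tr_s <- schedule$tr
  has_trials <- nrow(schedule$trials) > 0L
  cols <- list()
  if (has_trials) {
    for (cc in CONDITIONS) {
      idx <- assignment$trial[assignment$condition == cc &
                                assignment$role == "assigned" &
                                assignment$run == run]
      if (length(idx) == 0L) {
        stop("empty condition regressor: no trials of ", cc, " in run ", run)
      }
      R <- trial_regressors(tr_on[idx], n_vols, tr_s)
      cols[[cc]] <- rowSums(R)
    }
  }
  other <- assignment$trial[!(assignment$role == "assigned" &
                                assignment$run == run)]
  nuis_on <- c(tr_on[other], null_on)
  nuisance <- if (length(nuis_on)) {
    rowSums(trial_regressors(nuis_on, n_vols, tr_s))
  } else {
    numeric(n_vols)
  }
  drift <- dct_drift(n_vols, tr_s, cutoff_s)
  cond_block <- if (has_trials) do.call(cbind, cols) else NULL
  X <- cbind(cond_block, nuisance = nuisance, drift,
             intercept = rep(1, n_vols))
  cond_cols <- if (has_trials) seq_along(CONDITIONS) else integer(0)
  if (has_trials) colnames(X)[cond_cols] <- CONDITIONS
  list(X = X, condition_cols = cond_cols, n_vols = n_vols)
}

#' Ordinary least squares GLM fit
#'
#' @param Y Timeseries matrix, volumes x voxels (a `bold_timeseries` is also
#'   accepted).
#' @param X Design matrix, volumes x regressors.
#' @return List with `betas` (regressors x voxels), `sigma2` (residual
#'   variance per voxel), `df` (residual degrees of freedom).
#' @export
fit_glm <- function(Y, X) {
  if (inherits(Y, "bold_timeseries")) Y <- Y$Y
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  if (nrow(X) <= ncol(X)) stop("need more volumes than regressors")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  list(betas = betas, sigma2 = colSums(res^2) / df, df = df)
}

#' Extract the runs x conditions x voxels beta array
#'
#' Two variants are provided.  `"per-run"` (default) fits one GLM per run
#' partition, each with the four condition regressors for that run's assigned
#' trials plus a single pooled nuisance regressor for everything else.
#' `"single"` fits one GLM with `n_runs x 4` run-by-condition regressors plus
#' a nuisance regressor for dropped/erroneous trials and null events; under
#' noise the two differ slightly, and `"single"` matches the generative model
#' of the simulator exactly.
#'
#' @param schedule An `ag_schedule`.
#' @param assignment A `run_assignment`.
#' @param Y Timeseries (volumes x voxels) or a `bold_timeseries`.
#' @param variant `"per-run"` or `"single"`.
#' @param cutoff_s High-pass cutoff period (s).
#' @return Object of class `beta_array`: numeric array
#'   `n_runs x 4 x n_voxels` with `normalized = FALSE` attribute.
#' @export
extract_beta_array <- function(schedule, assignment, Y,
                               variant = c("per-run", "single"),
                               cutoff_s = 128) {
  variant <- match.arg(variant)
  if (inherits(Y, "bold_timeseries")) Y <- Y$Y
  Y <- as.matrix(Y)
  n_runs <- attr(assignment, "n_runs")
  n_vox <- ncol(Y)
  betas <- array(NA_real_, dim = c(n_runs, 4L, n_vox),
                 dimnames = list(paste0("run", seq_len(n_runs)),
                                 CONDITIONS, NULL))
  if (variant == "per-run") {
    for (r in seq_len(n_runs)) {
      d <- build_run_design(schedule, assignment, r, n_vols = nrow(Y),
                            cutoff_s = cutoff_s)
      fit <- fit_glm(Y, d$X)
      betas[r, , ] <- fit$betas[d$condition_cols, , drop = FALSE]
    }
  } else {
    on <- schedule_onsets(schedule)
    tr_on <- on$cue_onset_ms[on$type == "trial"] / 1000
    null_on <- on$cue_onset_ms[on$type == "null"] / 1000
    cols <- list()
    for (r in seq_len(n_runs)) {
      for (cc in CONDITIONS) {
        idx <- assignment$trial[assignment$condition == cc &
                                  assignment$role == "assigned" &
                                  assignment$run == r]
        if (length(idx) == 0L) {
          stop("empty condition regressor: no trials of ", cc, " in run ", r)
        }
        cols[[paste0("run", r, "_", cc)]] <-
          rowSums(trial_regressors(tr_on[idx], nrow(Y), schedule$tr))
      }
    }
    other <- assignment$trial[assignment$role != "assigned"]
    nuis_on <- c(tr_on[other], null_on)
    nuisance <- if (length(nuis_on)) {
      rowSums(trial_regressors(nuis_on, nrow(Y), schedule$tr))
    } else {
      numeric(nrow(Y))
    }
    drift <- dct_drift(nrow(Y), schedule$tr, cutoff_s)
    X <- cbind(do.call(cbind, cols), nuisance = nuisance, drift,
               intercept = rep(1, nrow(Y)))
    fit <- fit_glm(Y, X)
    for (r in seq_len(n_runs)) {
      for (j in seq_along(CONDITIONS)) {
        betas[r, j, ] <- fit$betas[paste0("run", r, "_", CONDITIONS[j]), ]
      }
    }
  }
  structure(betas, class = "beta_array", normalized = FALSE)
}

#' Cell-mean beta estimator from trial amplitudes
#'
#' The beta estimate for a run-by-condition cell in the orthogonal-design
#' limit: the mean amplitude of that cell's assigned trials.  Useful for
#' large calibration studies where simulating and deconvolving full BOLD
#' timeseries adds nothing but cost.
#'
#' @param amplitudes Trials x voxels matrix.
#' @param assignment A `run_assignment` for the same schedule.
#' @return A `beta_array` (`n_runs x 4 x n_voxels`, unnormalized).
#' @export
betas_from_cell_means <- function(amplitudes, assignment) {
  amplitudes <- as.matrix(amplitudes)
  n_runs <- attr(assignment, "n_runs")
  n_vox <- ncol(amplitudes)
  betas <- array(NA_real_, dim = c(n_runs, 4L, n_vox),
                 dimnames = list(paste0("run", seq_len(n_runs)),
                                 CONDITIONS, NULL))
  for (r in seq_len(n_runs)) {
    for (j in seq_along(CONDITIONS)) {
      idx <- assignment$trial[assignment$condition == CONDITIONS[j] &
                                assignment$role == "assigned" &
                                assignment$run == r]
      betas[r, j, ] <- colMeans(amplitudes[idx, , drop = FALSE])
    }
  }
  structure(betas, class = "beta_array", normalized = FALSE)
}

#' z-normalize a beta array per voxel
#'
#' Standardizes each voxel's betas to mean 0 and SD 1 across all run x
#' condition cells, removing mean signal-intensity differences between
#' voxels.  Voxels with constant or non-finite betas cannot be standardized;
#' they are set to NaN and listed in the `excluded_voxels` attribute (they are
#' excluded from the tuned-voxel accounting downstream).  Idempotent.
#'
#' @param betas A `beta_array`.
#' @return The normalized `beta_array` (`normalized = TRUE`).
#' @export
znormalize <- function(betas) {
  stopifnot(inherits(betas, "beta_array"))
  d <- dim(betas)
  flat <- matrix(betas, nrow = d[1L] * d[2L], ncol = d[3L])
  m <- colMeans(flat)
  s <- apply(flat, 2L, sd)
  bad <- !is.finite(m) | !is.finite(s) | s == 0
  s[bad] <- 1
  flat <- sweep(sweep(flat, 2L, m), 2L, s, "/")
  flat[, bad] <- NaN
  out <- array(flat, dim = d, dimnames = dimnames(betas))
  structure(out, class = "beta_array", normalized = TRUE,
            excluded_voxels = which(bad))
}

#' Write a beta array as a long-format TSV
#'
#' @param betas A `beta_array`.
#' @param path Output path.
#' @param subject Subject label recorded per row.
#' @export
write_beta_tsv <- function(betas, path, subject = 1L) {
  d <- dim(betas)
  df <- data.frame(
    subject = subject,
    run = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    condition = rep(rep(CONDITIONS, each = d[1L]), times = d[3L]),
    voxel = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    beta = as.vector(unclass(betas))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a long-format beta TSV back into a beta array
#'
#' @param path TSV written by `write_beta_tsv()` (single subject).
#' @return A `beta_array`.
#' @export
read_beta_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  n_runs <- max(df$run)
  n_vox <- max(df$voxel)
  betas <- array(NA_real_, dim = c(n_runs, 4L, n_vox),
                 dimnames = list(paste0("run", seq_len(n_runs)),
                                 CONDITIONS, NULL))
  betas[cbind(df$run, match(df$condition, CONDITIONS), df$voxel)] <- df$beta
  structure(betas, class = "beta_array", normalized = FALSE)
}
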