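#' Construct a synthetic voxel population with condition tuning
#'
#' Each voxel carries a 4-vector of mean responses, one per condition
#' (CG, CC, EG, EC).  A tuned voxel's preferred condition is elevated by
#' `tuning_gain` over the other three (which sit at 0); an untuned voxel has
#' all four means equal.  Trial-level Gaussian noise is added downstream by
#' `simulate_trial_amplitudes()`.
#'
#' @param n_voxels Number of voxels.
#' @param proportions Named numeric of length 5 over
#'   `c("CG","CC","EG","EC","untuned")`, summing to 1.  Counts are realized by
#'   largest-remainder rounding.
#' @param tuning_gain Elevation of the preferred condition's mean (signal
#'   units, >= 0).
#' @param noise_sd Trial-level noise SD; scalar or per-voxel vector (>= 0).
#' @param baseline Scalar baseline offset added to every trial amplitude.
#' @return Object of class `voxel_population`: list with `n_voxels`, `mu`
#'   (n_voxels x 4 matrix), `noise_sd` (length n_voxels),
#'   `designated_preference` (condition or NA per voxel), `baseline`.
#' @export
make_voxel_population <- function(n_voxels,
                                  proportions = c(CG = 0.25, CC = 0.25,
                                                  EG = 0.25, EC = 0.25,
                                                  untuned = 0),
                                  tuning_gain = 1, noise_sd = 1,
                                  baseline = 0) {
  n_voxels <- as.integer(n_voxels)
  if (n_voxels < 0L) stop("n_voxels must be >= 0")
  if (tuning_gain < 0) stop("tuning_gain must be >= 0")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  groups <- c(CONDITIONS, "untuned")
  p <- proportions[groups]
  if (anyNA(p)) stop("proportions must be named over ",
                     paste(groups, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  # largest-remainder rounding to integer counts
  raw <- p * n_voxels
  counts <- floor(raw)
  rem <- n_voxels - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  pref <- rep(groups, counts)
  mu <- matrix(0, nrow = n_voxels, ncol = 4L,
               dimnames = list(NULL, CONDITIONS))
  for (j in seq_along(CONDITIONS)) {
    mu[pref == CONDITIONS[j], j] <- tuning_gain
  }
  noise_sd <- rep_len(noise_sd, n_voxels)
  out <- list(n_voxels = n_voxels, mu = mu,
              noise_sd = noise_sd,
              designated_preference = ifelse(pref == "untuned",
                                             NA_character_, pref),
              baseline = baseline)
  class(out) <- "voxel_population"
  out
}

#' @export
print.voxel_population <- function(x, ...) {
  cat("Voxel population:", x$n_voxels, "voxels\n")
  print(table(factor(x$designated_preference, levels = CONDITIONS),
              useNA = "ifany"))
  invisible(x)
}

#' Simulate per-trial response amplitudes
#'
#' The amplitude of voxel v on trial t is
#' `baseline + mu[v, condition(t)] + N(0, noise_sd[v])`.
#'
#' @param pop A `voxel_population`.
#' @param schedule An `ag_schedule` (null events contribute no amplitudes).
#' @return Numeric matrix, trials x voxels.
#' @export
simulate_trial_amplitudes <- function(pop, schedule) {
  stopifnot(inherits(pop, "voxel_population"), inherits(schedule, "ag_schedule"))
  cond <- schedule$trials$condition
  n_t <- length(cond)
  mean_mat <- pop$baseline + pop$mu[, cond, drop = FALSE]  # voxels x trials
  noise <- matrix(rnorm(n_t * pop$n_voxels), nrow = pop$n_voxels) * pop$noise_sd
  t(mean_mat + noise)
}

#' Simulate HRF-convolved BOLD timeseries on the TR grid
#'
#' Each trial contributes `amplitude x` a canonical double-gamma HRF impulse
#' response placed at its cue onset; the series is sampled at volume
#' acquisition times `0, TR, 2 TR, ...`.  Scanner noise is additive Gaussian,
#' optionally AR(1), optionally plus a slow sinusoidal drift.
#'
#' @param amplitudes Trials x voxels matrix from `simulate_trial_amplitudes()`.
#' @param schedule The `ag_schedule` the amplitudes were generated for.
#' @param tr Repetition time in seconds.
#' @param noise_sd Scanner noise SD (volume level).
#' @param ar AR(1) coefficient of the scanner noise (default 0, white).
#' @param drift_amp,drift_period_s Optional sinusoidal drift amplitude (signal
#'   units) and period (seconds); `drift_amp = 0` disables it.
#' @return Object of class `bold_timeseries`: list with `Y` (volumes x voxels),
#'   `tr`, `n_vols`, `onsets_s` (trial cue onsets).
#' @export
simulate_bold <- function(amplitudes, schedule, tr = 2, noise_sd = 0,
                          ar = 0, drift_amp = 0, drift_period_s = 300) {
  stopifnot(inherits(schedule, "ag_schedule"))
  on <- schedule_onsets(schedule)
  onsets_s <- on$cue_onset_ms[on$type == "trial"] / 1000
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != length(onsets_s)) {
    stop("amplitudes has ", nrow(amplitudes), " rows but the schedule has ",
         length(onsets_s), " trials")
  }
  session_end_s <- max(on$onset_ms + on$duration_ms) / 1000
  if (hrf_duration() > session_end_s) stop("HRF kernel longer than session")
  n_vols <- ceiling((session_end_s + hrf_duration()) / tr)
  R <- trial_regressors(onsets_s, n_vols, tr)        # volumes x trials
  Y <- R %*% amplitudes
  if (noise_sd > 0) {
    eps <- matrix(rnorm(n_vols * ncol(Y)), nrow = n_vols)
    if (ar != 0) {
      eps <- apply(eps, 2L, function(e) {
        as.numeric(stats::filter(e, ar, method = "recursive"))
      })
      eps <- eps * sqrt(1 - ar^2)  # restore unit marginal variance
    }
    Y <- Y + noise_sd * eps
  }
  if (drift_amp != 0) {
    tgrid <- (seq_len(n_vols) - 1L) * tr
    Y <- Y + drift_amp * sin(2 * pi * tgrid / drift_period_s)
  }
  structure(list(Y = Y, tr = tr, n_vols = n_vols, onsets_s = onsets_s),
            class = "bold_timeseries")
}

#' Default behavioral parameters
#'
#' Per-condition error probabilities follow an additive decomposition of the
#' study-scale marginal rates (grammar 5.5% vs count 3.0%; episodic 5.6% vs
#' contextual 2.9%; grand mean 4.25%), and reaction-time means follow the task
#' margins (grammar 798 ms, count 812 ms).  The RT spread is not constrained
#' by those margins; 150 ms is a typical single-trial value for speeded
#' two-choice responses.  These are generator defaults, not fitted values.
#'
#' @return List with `error_prob`, `rt_mean_ms`, `rt_sd_ms`, each named over
#'   the four conditions.
#' @export
behavior_defaults <- function() {
  list(
    error_prob = c(CG = 0.0415, CC = 0.0165, EG = 0.0685, EC = 0.0435),
    rt_mean_ms = c(CG = 798, CC = 812, EG = 798, EC = 812),
    rt_sd_ms   = c(CG = 150, CC = 150, EG = 150, EC = 150)
  )
}

#' Simulate per-trial behavior (accuracy and reaction time)
#'
#' Errors are Bernoulli with a per-condition probability; reaction times are
#' Gaussian truncated to the response window (0, 2000] ms, sampled by
#' inverse-CDF.
#'
#' @param schedule An `ag_schedule`.
#' @param params Behavioral parameters, see `behavior_defaults()`.
#' @param window_ms Response window (upper truncation), default 2000 ms.
#' @return Data frame with `trial`, `condition`, `correct`, `rt_ms`.
#' @export
simulate_behavior <- function(schedule, params = behavior_defaults(),
                              window_ms = 2000) {
  stopifnot(inherits(schedule, "ag_schedule"))
  p <- params$error_prob
  if (any(p < 0 | p > 1)) stop("error probabilities must lie in [0, 1]")
  if (any(params$rt_sd_ms < 0)) stop("rt sd must be >= 0")
  cond <- schedule$trials$condition
  n <- length(cond)
  err <- rbinom(n, 1L, p[cond]) == 1L
  m <- params$rt_mean_ms[cond]
  s <- params$rt_sd_ms[cond]
  lo <- pnorm((0 - m) / s)
  hi <- pnorm((window_ms - m) / s)
  rt <- m + s * qnorm(lo + runif(n) * (hi - lo))
  data.frame(trial = seq_len(n), condition = cond,
             correct = !err, rt_ms = rt)
}

#' Write simulated behavior to TSV
#' @param behavior Data frame from `simulate_behavior()`.
#' @param path Output path.
#' @export
write_behavior_tsv <- function(behavior, path) {
  write.table(behavior, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(behavior)
}
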