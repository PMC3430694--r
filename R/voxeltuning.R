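# Winner-take-all voxel tuning with leave-one-run-out cross-validation.
# For each fold, one run is held out as the analysis run; the condition
# preference of every voxel is the condition with the largest mean beta across
# the remaining classification runs; a majority-vote reliability filter keeps
# a voxel only if its preference is also its within-run winner in at least
# half (ceil(k/2)) of the k classification runs; the tuning curve is read
# exclusively from the held-out run.

# Row-wise argmax over a conditions-in-columns matrix; exact ties or
# non-finite rows -> NA.
.argmax_or_na <- function(M) {
  out <- max.col(M, ties.method = "first")
  mx <- M[cbind(seq_len(nrow(M)), out)]
  hits <- rowSums(M == mx)          # mx recycles down columns: row-wise compare
  bad <- !is.finite(mx) | is.na(hits) | hits != 1L
  bad[is.na(bad)] <- TRUE
  out[bad] <- NA_integer_
  out
}

#' Classify one voxel's condition preference from classification runs
#'
#' The preference is the condition with the largest mean beta across the
#' classification runs.  An exact tie yields no preference (`NA`); any
#' non-finite beta flags the voxel as excluded.
#'
#' @param classification_betas Matrix, classification runs x 4 conditions.
#' @return List with `preference` (condition name or NA), `per_run`
#'   (per-run winning condition, NA on within-run ties), `excluded` (logical).
#' @export
classify_preference <- function(classification_betas) {
  M <- as.matrix(classification_betas)
  stopifnot(ncol(M) == 4L)
  if (any(!is.finite(M))) {
    return(list(preference = NA_character_, per_run = rep(NA_character_, nrow(M)),
                excluded = TRUE))
  }
  means <- matrix(colMeans(M), nrow = 1L)
  pref <- .argmax_or_na(means)
  per_run <- .argmax_or_na(M)
  list(preference = CONDITIONS[pref],
       per_run = CONDITIONS[per_run],
       excluded = FALSE)
}

#' Majority-vote reliability filter
#'
#' A voxel's preference is reliable when it is also the within-run winner in
#' at least half of the classification runs: `ceil(k/2)` of `k`, i.e. 3 of 5
#' at study scale.
#'
#' @param preference Condition name (not NA).
#' @param per_run_preferences Character vector of per-run winning conditions.
#' @return Logical scalar.
#' @export
reliability_filter <- function(preference, per_run_preferences) {
  if (is.na(preference)) stop("preference must not be NA")
  sum(per_run_preferences == preference, na.rm = TRUE) >=
    ceiling(length(per_run_preferences) / 2)
}

#' Leave-one-run-out voxel tuning
#'
#' For each of the `n_runs` folds, classifies every voxel's preference on the
#' other runs, applies the reliability filter, and reads the 4-point tuning
#' curve from the held-out analysis run.  The number of voxels tuned to each
#' condition is left free (no fixed quota per condition).
#'
#' @param betas A normalized `beta_array` (`n_runs x 4 x n_voxels`).
#' @return List of `n_runs` fold results, each a list with `analysis_run`,
#'   `preference` (condition index 1..4 or NA per voxel), `reliable`
#'   (logical per voxel), `votes` (classification runs x voxels condition
#'   indices), `tuning_curve` (4 x voxels, analysis-run betas), `excluded`
#'   (logical per voxel).  Class `tuning_folds`.
#' @export
loocv_tuning <- function(betas) {
  stopifnot(inherits(betas, "beta_array"))
  if (!isTRUE(attr(betas, "normalized"))) {
    stop("betas must be z-normalized before tuning (see znormalize())")
  }
  d <- dim(betas)
  n_runs <- d[1L]; n_vox <- d[3L]
  if (n_runs < 2L) stop("need at least 2 runs for leave-one-run-out")
  b <- unclass(betas)
  excluded <- colSums(!is.finite(matrix(b, nrow = n_runs * 4L))) > 0L
  k <- n_runs - 1L
  folds <- vector("list", n_runs)
  for (a in seq_len(n_runs)) {
    cls <- b[-a, , , drop = FALSE]                    # k x 4 x V
    cm <- matrix(colSums(matrix(cls, nrow = k)), nrow = 4L) / k   # 4 x V
    pref <- .argmax_or_na(t(cm))
    # per-run winners: rows = run x voxel pairs, columns = conditions
    flat <- matrix(aperm(cls, c(1L, 3L, 2L)), ncol = 4L)
    votes <- matrix(.argmax_or_na(flat), nrow = k)    # k x V
    need <- ceiling(k / 2)
    agree <- colSums(votes == rep(pref, each = k), na.rm = TRUE)
    reliable <- !is.na(pref) & agree >= need & !excluded
    pref[excluded] <- NA_integer_
    folds[[a]] <- list(analysis_run = a,
                       preference = pref,
                       reliable = reliable,
                       votes = votes,
                       tuning_curve = matrix(b[a, , ], nrow = 4L,
                                             dimnames = list(CONDITIONS, NULL)),
                       excluded = excluded)
  }
  structure(folds, class = "tuning_folds", n_voxels = n_vox)
}

#' Summarize leave-one-run-out tuning folds
#'
#' Tuned-voxel counts per condition (reliable voxels only) are aggregated
#' across folds by mean (default) or sum; mean tuning curves are averaged
#' over the reliable voxels preferring each condition, then over folds.
#' Per fold, the four condition counts plus the untuned count equal the
#' number of valid (non-excluded) voxels.
#'
#' @param folds A `tuning_folds` list from `loocv_tuning()`.
#' @param aggregate `"mean"` (study scale: per-subject counts on the
#'   voxel-count scale) or `"sum"`.
#' @return Object of class `tuning_summary`: list with `counts` (named
#'   4-vector), `untuned_fraction`, `curves` (4 x 4 matrix, preferred
#'   condition in rows, response condition in columns), `per_fold_counts`
#'   (folds x 4), `n_voxels`, `n_excluded`, `n_folds`, `aggregate`.
#' @export
summarize_tuning <- function(folds, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(folds, "tuning_folds"), length(folds) >= 1L)
  n_folds <- length(folds)
  per_fold <- matrix(0, nrow = n_folds, ncol = 4L,
                     dimnames = list(NULL, CONDITIONS))
  untuned <- numeric(n_folds)
  curves_acc <- array(NA_real_, dim = c(n_folds, 4L, 4L))
  n_excluded <- sum(folds[[1L]]$excluded)
  n_valid <- attr(folds, "n_voxels") - n_excluded
  for (f in seq_len(n_folds)) {
    fd <- folds[[f]]
    tuned_pref <- fd$preference[fd$reliable]
    per_fold[f, ] <- tabulate(tuned_pref, nbins = 4L)
    untuned[f] <- n_valid - sum(per_fold[f, ])
    for (j in 1:4) {
      sel <- which(fd$reliable & fd$preference == j)
      if (length(sel)) {
        curves_acc[f, j, ] <- rowMeans(fd$tuning_curve[, sel, drop = FALSE])
      }
    }
  }
  agg <- if (aggregate == "mean") colMeans(per_fold) else colSums(per_fold)
  curves <- apply(curves_acc, c(2L, 3L), mean, na.rm = TRUE)
  dimnames(curves) <- list(preferred = CONDITIONS, condition = CONDITIONS)
  structure(list(counts = agg,
                 untuned_fraction = mean(untuned) / max(n_valid, 1L),
                 curves = curves,
                 per_fold_counts = per_fold,
                 n_voxels = attr(folds, "n_voxels"),
                 n_excluded = n_excluded,
                 n_folds = n_folds,
                 aggregate = aggregate),
            class = "tuning_summary")
}

#' @export
print.tuning_summary <- function(x, ...) {
  cat("Tuned-voxel counts (", x$aggregate, " over ", x$n_folds, " folds, ",
      x$n_voxels, " voxels):\n", sep = "")
  print(round(x$counts, 2))
  cat("untuned fraction:", round(x$untuned_fraction, 3), "\n")
  invisible(x)
}

#' Tuning success: target condition vs the mean of the other three
#'
#' Across subjects, pairs each subject's mean analysis-run beta of the
#' voxels tuned to condition `condition` (the curve's peak entry) with the
#' mean of those same voxels' betas over the other three conditions, and
#' runs a paired t test.  Subjects without any reliable voxel for the
#' condition are excluded with a warning and the degrees of freedom reduced.
#'
#' @param summaries List of per-subject `tuning_summary` objects.
#' @param condition Condition name ("CG", "CC", "EG", "EC").
#' @return List with `t`, `df`, `p`, `n`, `n_excluded`, `flag`.
#' @export
tuning_success <- function(summaries, condition) {
  j <- match(condition, CONDITIONS)
  if (is.na(j)) stop("unknown condition: ", condition)
  target <- vapply(summaries, function(s) s$curves[j, j], numeric(1L))
  others <- vapply(summaries, function(s) mean(s$curves[j, -j]), numeric(1L))
  ok <- is.finite(target) & is.finite(others)
  n_excl <- sum(!ok)
  if (n_excl > 0L) {
    warning(n_excl, " subject(s) without reliable ", condition,
            "-tuned voxels excluded")
  }
  if (sum(ok) < 2L) stop("need at least 2 subjects with ", condition,
                         "-tuned voxels")
  res <- paired_t(target[ok], others[ok])
  res$n <- sum(ok)
  res$n_excluded <- n_excl
  res
}

#' Null reliability rate from vote-pattern enumeration
#'
#' Enumerates all `n_conditions^k` equally likely patterns of i.i.d. per-run
#' winners and returns the fraction in which some condition wins at least
#' `ceil(k/2)` runs.  This is the rate at which a qualifying vote majority
#' exists under the null; it upper-bounds the pipeline's null tuned fraction,
#' which additionally requires the across-run mean winner to coincide with
#' the vote majority (see the methods vignette).
#'
#' @param k Number of classification runs (study value 5).
#' @param n_conditions Number of conditions (4).
#' @return Named list with `rate` (majority-existence probability) and
#'   `per_condition` (`rate / n_conditions`).
#' @export
null_reliability_rate <- function(k = 5L, n_conditions = 4L) {
  pat <- do.call(expand.grid, rep(list(seq_len(n_conditions)), k))
  need <- ceiling(k / 2)
  maj <- apply(as.matrix(pat), 1L, function(v) max(tabulate(v, n_conditions)))
  rate <- mean(maj >= need)
  list(rate = rate, per_condition = rate / n_conditions)
}
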