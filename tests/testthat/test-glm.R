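test_that("the canonical HRF is a unit-peak double-gamma with a 5-6 s peak", {
  h <- canonical_hrf(0.01)
  expect_equal(h[1L], 0)
  expect_equal(max(h), 1, tolerance = 1e-5)  # grid max vs continuous peak
  tgrid <- seq(0, hrf_duration(), by = 0.01)
  peak_t <- tgrid[which.max(h)]
  expect_gte(peak_t, 5); expect_lte(peak_t, 6)
  # undershoot: negative lobe after ~10 s, about 1/6 of the peak
  expect_lt(min(h), 0)
  expect_lt(abs(min(h)) , 0.5)
  # refinement consistency: coarser grid is a subsample of the finer one
  h2 <- canonical_hrf(0.005)
  expect_equal(h, h2[seq(1L, length(h2), by = 2L)], tolerance = 1e-6)
  expect_error(canonical_hrf(0), "dt")
})

test_that("the DCT drift basis implements the 128 s high-pass cutoff", {
  X <- dct_drift(300, 2, 128)
  expect_equal(ncol(X), floor(2 * 300 * 2 / 128))
  # slowest basis function completes half a cycle over the session
  expect_equal(unname(X[1L, 1L]), cos(pi / 600), tolerance = 1e-12)
  expect_equal(ncol(dct_drift(10, 2, 128)), 0L)
})

test_that("run assignment gives disjoint equal-size runs per condition", {
  set.seed(10)
  sch <- generate_schedule()
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  for (cc in conditions()) {
    sel <- asn$condition == cc & asn$role == "assigned"
    expect_equal(unname(table(asn$run[sel])), rep(8L, 6L), ignore_attr = TRUE)
  }
  expect_equal(sum(asn$role == "assigned"), 192L)
  expect_equal(anyDuplicated(asn$trial), 0L)
  # different seeds give different assignments with the same count profile
  set.seed(11); a1 <- assign_trials_to_runs(sch, NULL, 6L)
  set.seed(12); a2 <- assign_trials_to_runs(sch, NULL, 6L)
  expect_false(identical(a1$run, a2$run))
  expect_equal(table(a1$run, a1$condition), table(a2$run, a2$condition))
})

test_that("erroneous and remainder trials are flagged and kept out of condition regressors", {
  set.seed(13)
  sch <- generate_schedule()
  beh <- data.frame(trial = seq_len(192L), correct = rep(TRUE, 192L))
  kill <- which(sch$trials$condition == "CG")[1L]
  beh$correct[kill] <- FALSE
  asn <- assign_trials_to_runs(sch, beh, 6L)
  expect_equal(asn$role[kill], "error")
  # 47 correct CG trials: 7 per run assigned, 5 dropped
  cg <- asn$condition == "CG"
  expect_equal(sum(cg & asn$role == "assigned"), 42L)
  expect_equal(sum(cg & asn$role == "dropped"), 5L)
  expect_equal(unname(table(asn$run[cg & asn$role == "assigned"])),
               rep(7L, 6L), ignore_attr = TRUE)
  # deficit: more runs than correct trials per condition
  set.seed(14)
  small <- generate_schedule(n_per_condition = 6L, n_null = 0L)
  expect_error(assign_trials_to_runs(small, NULL, 8L), "too few correct")
})

test_that("run design matrices have the expected structure", {
  set.seed(15)
  sch <- generate_schedule(n_per_condition = 12L, n_null = 4L)
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  d <- build_run_design(sch, asn, 1L)
  K <- floor(2 * d$n_vols * sch$tr / 128)
  expect_equal(ncol(d$X), 4L + 1L + K + 1L)
  expect_equal(colnames(d$X)[1:4], conditions())
  # each condition column is the sum of that run's per-trial kernels
  on <- schedule_onsets(sch)
  tr_on <- on$cue_onset_ms[on$type == "trial"] / 1000
  idx <- asn$trial[asn$condition == "CG" & asn$role == "assigned" & asn$run == 1L]
  expect_length(idx, 2L)
  vol_t <- (seq_len(d$n_vols) - 1L) * sch$tr
  manual <- rowSums(vapply(tr_on[idx], function(o) hrf_eval(vol_t - o),
                           numeric(d$n_vols)))
  expect_equal(unname(d$X[, "CG"]), manual)
  # run with a condition absent fails loudly
  asn2 <- asn
  asn2$role[asn2$condition == "CG" & asn2$run == 2L] <- "dropped"
  expect_error(build_run_design(sch, asn2, 2L), "empty condition regressor")
})

test_that("an all-null schedule yields only nuisance, drift, and intercept columns", {
  set.seed(16)
  sch <- generate_schedule(n_per_condition = 6L, n_null = 8L)
  sch$trials <- sch$trials[0L, ]
  sch$stream <- sch$stream[sch$stream$type == "null", ]
  sch$stream$trial <- NA_integer_
  asn <- structure(data.frame(trial = integer(), condition = character(),
                              run = integer(), role = character()),
                   class = c("run_assignment", "data.frame"), n_runs = 6L)
  d <- build_run_design(sch, asn, 1L)
  expect_length(d$condition_cols, 0L)
  expect_true(all(colnames(d$X) %in%
                    c("nuisance", paste0("drift", 1:99), "intercept")))
})

test_that("OLS recovers exact betas on noiseless data and rejects rank deficiency", {
  set.seed(17)
  X <- cbind(1, rnorm(60), rnorm(60)); colnames(X) <- c("a", "b", "c")
  B <- matrix(c(0.5, -1, 2, 1, 0, 3), nrow = 3L)
  fit <- fit_glm(X %*% B, X)
  expect_equal(fit$betas, B, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(fit$sigma2), c(0, 0), tolerance = 1e-18)
  Xd <- cbind(X, d = X[, "b"])
  expect_error(fit_glm(X %*% B, Xd), "collinear")
  expect_error(fit_glm(matrix(0, 3, 1), matrix(rnorm(12), 3, 4)),
               "more volumes")
})

test_that("condition betas are unbiased near zero under pure noise", {
  set.seed(18)
  sch <- generate_schedule(n_per_condition = 12L, n_null = 4L)
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  d <- build_run_design(sch, asn, 1L)
  nvox <- 200L
  Y <- matrix(rnorm(d$n_vols * nvox), d$n_vols, nvox)
  fit <- fit_glm(Y, d$X)
  cond_betas <- fit$betas[1:4, ]
  se <- sd(cond_betas) / sqrt(length(cond_betas))
  expect_lt(abs(mean(cond_betas)), 3 * se + 0.05)
})

test_that("the exact-model GLM recovers generating amplitudes to machine precision", {
  set.seed(19)
  sch <- generate_schedule(n_per_condition = 12L, n_null = 4L)
  pop <- make_voxel_population(30, tuning_gain = 1.2, noise_sd = 0,
                               baseline = 0.4)
  amp <- simulate_trial_amplitudes(pop, sch)
  bold <- simulate_bold(amp, sch)
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  b <- extract_beta_array(sch, asn, bold, variant = "single")
  expect_equal(dim(unclass(b)), c(6L, 4L, 30L))
  target <- mu_beta_array(pop)
  expect_lt(max(abs(unclass(b) - (unclass(target) + 0.4))), 1e-6)
})

test_that("the per-run GLM absorbs unassigned trials in its nuisance regressor", {
  # no null events: the nuisance column is then exactly the summed kernel of
  # the unassigned trials, so a global amplitude shift of those trials lies
  # in its span and leaves the condition betas untouched
  set.seed(20)
  sch <- generate_schedule(n_per_condition = 12L, n_null = 0L)
  pop <- make_voxel_population(10, tuning_gain = 1, noise_sd = 0)
  amp <- simulate_trial_amplitudes(pop, sch)
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  b1 <- extract_beta_array(sch, asn, simulate_bold(amp, sch), variant = "per-run")
  # globally shift the amplitudes of trials not assigned to run 1
  amp2 <- amp
  unassigned <- asn$trial[!(asn$role == "assigned" & asn$run == 1L)]
  amp2[unassigned, ] <- amp2[unassigned, ] + 5
  b2 <- extract_beta_array(sch, asn, simulate_bold(amp2, sch), variant = "per-run")
  expect_equal(unclass(b1)[1L, , ], unclass(b2)[1L, , ], tolerance = 1e-8)
})

test_that("permuting run labels permutes the beta array's first axis identically", {
  set.seed(21)
  sch <- generate_schedule(n_per_condition = 12L, n_null = 0L)
  pop <- make_voxel_population(8, tuning_gain = 1, noise_sd = 0.5)
  amp <- simulate_trial_amplitudes(pop, sch)
  bold <- simulate_bold(amp, sch)
  asn <- assign_trials_to_runs(sch, NULL, 6L)
  b <- extract_beta_array(sch, asn, bold, variant = "per-run")
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  asn2 <- asn
  asn2$run[asn2$role == "assigned"] <- perm[asn2$run[asn2$role == "assigned"]]
  b2 <- extract_beta_array(sch, asn2, bold, variant = "per-run")
  expect_equal(unclass(b2)[perm[1L], , ], unclass(b)[1L, , ], tolerance = 1e-10)
  expect_equal(unclass(b2)[perm[4L], , ], unclass(b)[4L, , ], tolerance = 1e-10)
})

test_that("z-normalization standardizes each voxel and is idempotent", {
  set.seed(22)
  b <- as_beta_array(array(rnorm(6 * 4 * 20, mean = 3, sd = 2), c(6, 4, 20)))
  z <- znormalize(b)
  flat <- matrix(unclass(z), nrow = 24L)
  expect_equal(colMeans(flat), rep(0, 20), tolerance = 1e-6)
  expect_equal(apply(flat, 2L, sd), rep(1, 20), tolerance = 1e-6)
  # affine invariance (positive scale)
  b2 <- as_beta_array(unclass(b) * 3.7 + 11)
  expect_equal(unclass(znormalize(b2)), unclass(z), tolerance = 1e-10)
  # idempotence
  expect_equal(unclass(znormalize(z)), unclass(z), tolerance = 1e-12)
  # constant voxels are flagged and NaN'd
  bc <- unclass(b); bc[, , 5L] <- 2
  zc <- znormalize(as_beta_array(bc))
  expect_equal(attr(zc, "excluded_voxels"), 5L, ignore_attr = TRUE)
  expect_true(all(is.nan(unclass(zc)[, , 5L])))
})

test_that("beta arrays round-trip through long-format TSV", {
  set.seed(23)
  b <- as_beta_array(array(rnorm(6 * 4 * 7), c(6, 4, 7),
                           dimnames = list(paste0("run", 1:6), conditions(),
                                           NULL)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_tsv(b, path, subject = 4L)
  back <- read_beta_tsv(path)
  expect_equal(unclass(back), unclass(b), tolerance = 1e-12)
})
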