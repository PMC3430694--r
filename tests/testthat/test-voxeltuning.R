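test_that("preference classification takes the across-run argmax with tie and NaN rules", {
  M <- rbind(c(0.2, 0.1, 0.9, 0.0),
             c(0.2, 0.1, 0.9, 0.0),
             c(0.2, 0.1, 0.9, 0.0),
             c(0.2, 0.1, 0.9, 0.0),
             c(0.2, 0.1, 0.9, 0.0))
  res <- classify_preference(M)
  expect_equal(res$preference, "EG")
  expect_false(res$excluded)
  # exact tie across conditions -> no preference
  tie <- classify_preference(matrix(1, 5L, 4L))
  expect_true(is.na(tie$preference))
  # NaN flags the voxel
  Mn <- M; Mn[2L, 3L] <- NaN
  expect_true(classify_preference(Mn)$excluded)
})

test_that("reliability requires the preference to win at least 3 of 5 runs", {
  expect_true(reliability_filter("EG", c("EG", "EG", "EG", "CC", "CG")))
  expect_false(reliability_filter("EG", c("EG", "EG", "CC", "CC", "CG")))
  expect_true(reliability_filter("EG", c("EG", "EG", "EG", "EG", "EG")))
  expect_error(reliability_filter(NA_character_, c("EG", "EG", "EG")), "NA")
})

test_that("noiseless tuned populations are perfectly recovered in every fold", {
  set.seed(30)
  pop <- make_voxel_population(200, tuning_gain = 1, noise_sd = 0)
  zb <- znormalize(mu_beta_array(pop))
  folds <- loocv_tuning(zb)
  expect_length(folds, 6L)
  truth <- match(pop$designated_preference, conditions())
  for (fd in folds) {
    expect_equal(fd$preference, truth)
    expect_true(all(fd$reliable))
  }
  s <- summarize_tuning(folds)
  expect_equal(unname(s$counts), rep(50, 4L), ignore_attr = TRUE)
  expect_equal(s$untuned_fraction, 0)
})

test_that("permuting condition labels permutes recovered preferences identically", {
  set.seed(31)
  b <- as_beta_array(array(rnorm(6 * 4 * 60), c(6, 4, 60)))
  f1 <- loocv_tuning(znormalize(b))
  perm <- c(2L, 4L, 1L, 3L)
  bp <- unclass(b)[, order(perm), , drop = FALSE]  # column j holds old perm^-1
  f2 <- loocv_tuning(znormalize(as_beta_array(bp)))
  for (a in 1:6) {
    expect_equal(f2[[a]]$preference, perm[f1[[a]]$preference])
    expect_equal(f2[[a]]$reliable, f1[[a]]$reliable)
  }
})

test_that("tuning curves come only from the held-out analysis run", {
  set.seed(32)
  b <- as_beta_array(array(rnorm(6 * 4 * 40), c(6, 4, 40)))
  zb <- znormalize(b)
  folds <- loocv_tuning(zb)
  for (a in 1:6) {
    expect_equal(folds[[a]]$tuning_curve,
                 matrix(unclass(zb)[a, , ], nrow = 4L,
                        dimnames = list(conditions(), NULL)))
  }
  # overwrite the classification runs for fold 3: its curve must not move
  zb2 <- unclass(zb)
  zb2[-3L, , ] <- rnorm(length(zb2[-3L, , ]))
  folds2 <- loocv_tuning(structure(zb2, class = "beta_array",
                                   normalized = TRUE))
  expect_equal(folds2[[3L]]$tuning_curve, folds[[3L]]$tuning_curve)
})

test_that("null calibration matches a direct simulation of the argmax+vote process", {
  # independent oracle: simulate per-voxel classification directly, without
  # the package's loocv code path
  set.seed(33)
  nrep <- 200000L
  x <- array(rnorm(nrep * 5L * 4L), c(nrep, 5L, 4L))
  cm <- apply(x, c(1L, 3L), mean)
  overall <- max.col(cm)
  votes_ok <- vapply(1:5, function(r) {
    max.col(x[, r, ]) == overall
  }, logical(nrep))
  oracle_rate <- mean(rowSums(votes_ok) >= 3L)
  se_oracle <- sqrt(oracle_rate * (1 - oracle_rate) / nrep)

  # pipeline estimate on iid-normal beta arrays
  set.seed(34)
  tuned <- 0; prefs <- integer(0); n_vox_total <- 0
  for (i in 1:12) {
    b <- as_beta_array(array(rnorm(6 * 4 * 500), c(6, 4, 500)))
    folds <- loocv_tuning(znormalize(b))
    s <- summarize_tuning(folds)
    tuned <- tuned + sum(s$counts)
    n_vox_total <- n_vox_total + 500
    prefs <- c(prefs, folds[[1L]]$preference)
  }
  emp_rate <- tuned / n_vox_total
  se_emp <- sqrt(emp_rate * (1 - emp_rate) / n_vox_total)
  expect_lt(abs(emp_rate - oracle_rate), 3 * (se_oracle + se_emp))
  # the vote-majority enumeration rate bounds the tuned fraction from above
  expect_lt(emp_rate, null_reliability_rate()$rate)
  # preference distribution uniform over the four conditions (99% binomial CI)
  tab <- tabulate(prefs, 4L)
  p0 <- 0.25; n <- sum(tab)
  ci <- 2.576 * sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(tab / n - p0) < ci + 0.01))
})

test_that("recovery accuracy is non-decreasing in the tuning gain (SNR sweep)", {
  gains <- c(0.1, 0.3, 0.6, 1.2, 2.4)
  acc <- vapply(gains, function(g) {
    set.seed(35)  # common random numbers across the grid
    sch <- generate_schedule(n_per_condition = 12L, n_null = 0L)
    pop <- make_voxel_population(200, tuning_gain = g, noise_sd = 1)
    amp <- simulate_trial_amplitudes(pop, sch)
    asn <- assign_trials_to_runs(sch, NULL, 6L)
    folds <- loocv_tuning(znormalize(betas_from_cell_means(amp, asn)))
    truth <- match(pop$designated_preference, conditions())
    mean(vapply(folds, function(fd) {
      mean(fd$preference == truth, na.rm = TRUE)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[5L], 0.9)
})

test_that("fold summaries conserve voxel counts and average correctly", {
  set.seed(36)
  b <- as_beta_array(array(rnorm(6 * 4 * 100), c(6, 4, 100)))
  folds <- loocv_tuning(znormalize(b))
  s <- summarize_tuning(folds)
  n_valid <- s$n_voxels - s$n_excluded
  # conservation per fold: tuned counts + untuned = valid voxels
  for (f in 1:6) {
    fd <- folds[[f]]
    tuned_f <- sum(s$per_fold_counts[f, ])
    untuned_f <- sum(!fd$reliable & !fd$excluded)
    expect_equal(tuned_f + untuned_f, n_valid)
  }
  untuned_per_fold <- n_valid - rowSums(s$per_fold_counts)
  expect_true(all(untuned_per_fold >= 0))
  expect_equal(mean(untuned_per_fold) / n_valid, s$untuned_fraction)
  # single fold with known composition
  one <- folds[1L]
  attr(one, "n_voxels") <- attr(folds, "n_voxels")
  class(one) <- "tuning_folds"
  s1 <- summarize_tuning(one)
  expect_equal(unname(s1$counts), unname(s$per_fold_counts[1L, ]),
               ignore_attr = TRUE)
  # duplicated folds equal either fold (idempotent mean)
  two <- folds[c(1L, 1L)]
  attr(two, "n_voxels") <- attr(folds, "n_voxels")
  class(two) <- "tuning_folds"
  s2 <- summarize_tuning(two)
  expect_equal(s2$counts, s1$counts)
  expect_equal(s2$curves, s1$curves)
  # sum aggregation
  ssum <- summarize_tuning(folds, aggregate = "sum")
  expect_equal(unname(ssum$counts), unname(colSums(s$per_fold_counts)),
               ignore_attr = TRUE)
})

test_that("tuning success detects a true gain and is zero for identical curves", {
  # identical target and other betas -> t = 0
  flat <- matrix(0.5, 4L, 4L, dimnames = list(conditions(), conditions()))
  summaries <- replicate(6L, structure(list(curves = flat),
                                       class = "tuning_summary"),
                         simplify = FALSE)
  res <- tuning_success(summaries, "EG")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # a real gain yields a significantly positive paired t at modest noise
  set.seed(37)
  sims <- lapply(1:12, function(s) {
    pop <- make_voxel_population(80, tuning_gain = 0.8, noise_sd = 1)
    sch <- generate_schedule(n_per_condition = 12L, n_null = 0L)
    amp <- simulate_trial_amplitudes(pop, sch)
    asn <- assign_trials_to_runs(sch, NULL, 6L)
    summarize_tuning(loocv_tuning(znormalize(betas_from_cell_means(amp, asn))))
  })
  res2 <- tuning_success(sims, "EG")
  expect_gt(res2$t, 2)
  expect_lt(res2$p, 0.05)
  expect_equal(res2$df, 11L)

  # subjects without tuned voxels are excluded with a warning
  bad <- structure(list(curves = matrix(NaN, 4L, 4L)), class = "tuning_summary")
  expect_warning(res3 <- tuning_success(c(sims, list(bad)), "EG"),
                 "excluded")
  expect_equal(res3$df, 11L)
  expect_equal(res3$n_excluded, 1L)
})

test_that("the vote-majority enumeration rate matches its closed form", {
  # sum_{k>=3} C(5,k) 3^(5-k) * 4 / 4^5
  closed <- 4 * (choose(5, 3) * 9 + choose(5, 4) * 3 + 1) / 4^5
  r <- null_reliability_rate()
  expect_equal(r$rate, closed)
  expect_equal(r$per_condition, closed / 4)
})
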