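test_that("the double-gamma HRF has canonical shape", {
  expect_equal(hrf_double_gamma(0), 0)
  expect_equal(hrf_double_gamma(-3), 0)
  tg <- seq(0, 32, by = 0.01)
  h <- hrf_double_gamma(tg)
  expect_equal(max(h), 1, tolerance = 1e-6)          # peak-normalized
  peak_t <- tg[which.max(h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 7)       # peak near 5 s
  expect_lt(min(h[tg > 10 & tg < 25]), 0)            # post-peak undershoot
  expect_gt(sum(h) * 0.01, 0)                        # positive net integral
})

test_that("design matrices have one convolved column per condition", {
  sched <- generate_event_schedule(sim_config(n_runs = 1, seed = 2))
  X <- build_design_matrix(sched, n_volumes = 228, tr = 2)
  expect_equal(length(attr(X, "task_cols")), 10)
  expect_equal(attr(X, "conditions"), 1:10)
  expect_true(all(is.finite(X)))
  # task columns are zero before their condition's first onset
  for (k in 1:10) {
    first <- min(sched$onset[sched$trial_type == k])
    pre <- which((0:227) * 2 < first)
    expect_true(all(abs(X[pre, k]) < 1e-12))
  }
})

test_that("empty schedules give an all-zero task block", {
  empty <- generate_event_schedule(sim_config(reps_per_run = 0))
  X <- build_design_matrix(empty, n_volumes = 50, tr = 2)
  expect_true(all(X[, attr(X, "task_cols")] == 0))
  expect_equal(length(attr(X, "task_cols")), 10)
})

test_that("convolution is linear over events", {
  ev <- function(onsets) tibble::tibble(onset = onsets, duration = 2.5,
                                        trial_type = 1L)
  both <- build_design_matrix(ev(c(10, 40)), 60, 2, cutoff = NULL)
  one <- build_design_matrix(ev(10), 60, 2, cutoff = NULL)
  two <- build_design_matrix(ev(40), 60, 2, cutoff = NULL)
  expect_equal(both[, 1], one[, 1] + two[, 1], tolerance = 1e-12)
})

test_that("events beyond the scan end raise a named error", {
  ev <- tibble::tibble(onset = 130, duration = 2.5, trial_type = 1L, run = 3L)
  expect_error(build_design_matrix(ev, 60, 2), "beyond scan end")
  expect_error(build_design_matrix(ev, 60, 2), "run 3")
})

test_that("the high-pass filter removes slow and keeps fast components", {
  tr <- 2; n <- 228
  tt <- (0:(n - 1)) * tr
  power <- function(x) sum(x^2)
  expect_equal(highpass(rep(5, n), tr), rep(0, n), tolerance = 1e-12)
  slow <- sin(2 * pi * tt / 200)
  fast <- sin(2 * pi * tt / 30)
  expect_lt(power(highpass(slow, tr)) / power(slow), 0.01)
  expect_gt(power(highpass(fast, tr)) / power(fast), 0.99)
  # idempotence
  x <- rnorm(n)
  expect_equal(highpass(highpass(x, tr), tr), highpass(x, tr),
               tolerance = 1e-10)
  # invalid cutoff
  expect_error(highpass(x, tr, cutoff = 3), "cutoff")
})

test_that("noise-free BOLD round-trips through the GLM to 1e-8", {
  cfg <- sim_config(n_subjects = 1, n_voxels = 5, n_runs = 2, rois = "OPA",
                    level = "bold", noise_sd_run = 0.7, seed = 5)
  bb <- simulate_bold(cfg, noise_sd_bold = 0)
  fit <- fit_experiment_glm(bb)
  amps <- attr(bb, "amplitudes")
  for (i in seq_len(nrow(fit))) {
    est <- fit$betas[[i]]
    truth <- amps$betas[[i]][, colnames(est)]
    expect_lt(max(abs(est - truth)), 1e-8)
  }
})

test_that("all-zero data give all-zero betas and rank deficiency errors", {
  sched <- generate_event_schedule(sim_config(n_runs = 1, seed = 6))
  X <- build_design_matrix(sched, 228, 2)
  Y <- matrix(0, 228, 3)
  expect_true(all(fit_run_glm(Y, X) == 0))
  Xbad <- cbind(X, X[, 1, drop = FALSE])
  colnames(Xbad)[ncol(Xbad)] <- "dup"
  attr(Xbad, "task_cols") <- attr(X, "task_cols")
  attr(Xbad, "conditions") <- attr(X, "conditions")
  expect_error(fit_run_glm(Y, Xbad), "rank deficient")
  expect_error(fit_run_glm(Y[1:100, ], X), "volumes")
})

test_that("betas are invariant to drift components inside the filter span", {
  sched <- generate_event_schedule(sim_config(n_runs = 1, seed = 7))
  X <- build_design_matrix(sched, 228, 2)
  task <- X[, attr(X, "task_cols")]
  B <- matrix(rnorm(4 * 10), 4, 10)
  Y <- task %*% t(B)
  drift <- (dct_basis(228, 2)[, 3] %o% rnorm(4)) * 50
  expect_equal(fit_run_glm(Y + drift, X), fit_run_glm(Y, X),
               tolerance = 1e-8)
})

test_that("filtering data and design equals modeling drift as regressors", {
  # Frisch-Waugh: projecting out the drift subspace from both sides leaves
  # the task estimates unchanged.
  sched <- generate_event_schedule(sim_config(n_runs = 1, seed = 8))
  X <- build_design_matrix(sched, 228, 2, cutoff = 120)
  set.seed(1)
  Y <- matrix(rnorm(228 * 4), 228, 4)
  with_drift <- fit_run_glm(Y, X)
  task_f <- highpass(X[, attr(X, "task_cols")], 2, 120)
  Xf <- structure(task_f, task_cols = attr(X, "task_cols"),
                  conditions = attr(X, "conditions"), tr = 2)
  filtered <- fit_run_glm(highpass(Y, 2, 120), Xf)
  expect_equal(with_drift, filtered, tolerance = 1e-8)
})

test_that("the OLS estimator is unbiased over noisy simulations", {
  sched <- generate_event_schedule(sim_config(n_runs = 1, seed = 9))
  X <- build_design_matrix(sched, 228, 2)
  task <- X[, attr(X, "task_cols")]
  truth <- seq(-1, 1, length.out = 10)
  set.seed(42)
  errs <- vapply(1:500, function(i) {
    Y <- matrix(task %*% truth + rnorm(228), ncol = 1)
    drop(fit_run_glm(Y, X)) - truth
  }, numeric(10))
  for (k in 1:10) expect_true(within_3se(errs[k, ]))
})

test_that("run averaging is exact arithmetic", {
  cfg <- tiny_config(seed = 12)
  b <- simulate_betas(cfg)
  cell <- b[b$hemisphere == "left", ]
  expect_identical(average_halves(cell, 2), cell$betas[[2]])
  expect_equal(average_halves(cell, c(1, 3)),
               (cell$betas[[1]] + cell$betas[[3]]) / 2)
  # mean over all runs equals the grand mean of per-run means
  expect_equal(average_halves(cell, 1:4),
               Reduce(`+`, cell$betas) / 4)
  # symmetric betas cancel
  m <- cell$betas[[1]]
  sym <- cell
  sym$betas <- list(m, -m, m, -m)
  expect_true(all(average_halves(sym, 1:2) == 0))
  expect_error(average_halves(b, 1), "single subject")
  expect_error(average_halves(cell, 9), "absent")
  bad <- cell
  bad$betas[[2]] <- bad$betas[[2]][1:3, ]
  expect_error(average_halves(bad, 1:2), "voxel sets")
})

test_that("bold simulation rejects schedules longer than the run", {
  cfg <- sim_config(n_subjects = 1, n_voxels = 2, n_runs = 1, rois = "OPA",
                    level = "bold", seed = 2)
  sched <- generate_event_schedule(sim_config(seed = 2))
  sched$onset <- sched$onset + 300
  expect_error(simulate_bold(cfg, schedule = sched), "shorter than")
})
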