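test_that("ROI extraction averages exactly over the mask", {
  arr <- array(0, c(4, 4, 3, 5))
  arr[2, 2, 2, ] <- 1:5
  mask1 <- array(FALSE, c(4, 4, 3)); mask1[2, 2, 2] <- TRUE
  expect_equal(extract_roi_mean(arr, mask1), 1:5)
  # uniform volume
  arr2 <- array(7, c(4, 4, 3, 5))
  maskA <- array(TRUE, c(4, 4, 3))
  expect_equal(extract_roi_mean(arr2, maskA), rep(7, 5))
  expect_error(extract_roi_mean(arr, array(FALSE, c(4, 4, 3))), "empty")
  expect_error(extract_roi_mean(arr, array(TRUE, c(3, 3, 3))), "grid")
})

test_that("extracted ROI mean matches the generator's ground truth", {
  truth <- snr_preset("study_like", seed = 5)
  sess <- simulate_volume_session(exp1, truth, dims = c(12L, 12L, 8L),
                                  roi_center = c(6, 8, 4),
                                  roi_radii = c(3, 2, 2))
  series <- extract_roi_mean(sess$data, sess$roi_mask)
  nvox <- sum(sess$roi_mask)
  tt <- (seq_len(exp1$n_scans) - 1) * exp1$tr
  drift <- truth$drift_amplitude * cos(2 * pi * tt / truth$drift_period)
  # residual after removing truth signal and drift = ROI-averaged noise,
  # with sd ~ noise_sd / sqrt(nvox)
  resid <- series - sess$roi_signal - drift
  expect_lt(sd(resid), 3 * truth$noise_sd / sqrt(nvox))
  expect_gt(cor(series - drift, sess$roi_signal), 0.8)
})

test_that("FIR bins recover a kernel exactly from noise-free data", {
  truth <- synthetic_truth(noise_sd = 0, drift_amplitude = 0, seed = 1)
  # one isolated 1 s event whose full response (kernel length + 1 s) fits
  # inside the peristimulus window: the OLS identity is exact
  iso <- event_table(onset = 10, duration = 1)
  y <- simulate_roi_timeseries(iso, truth, 80, 1)
  fe <- fit_fir(as.numeric(y), iso, 34, 1)
  clean <- attr(y, "clean_signal")
  expect_equal(fe$amplitudes, unname(clean[11:44]), tolerance = 1e-10)
  # block paradigm: response tails of earlier blocks leak into later
  # windows, so recovery is only near-exact there
  yb <- simulate_roi_timeseries(exp1$events, truth, exp1$n_scans, 1)
  feb <- fit_fir(as.numeric(yb), exp1$events, 20, 1)
  expect_equal(feb$amplitudes,
               unname(attr(yb, "clean_signal")[11:30]), tolerance = 0.05)
  # amplitude 0 gives ~0 bins
  t0 <- synthetic_truth(amplitude = 0, noise_sd = 0.3, seed = 2)
  y0 <- simulate_roi_timeseries(exp1$events, t0, exp1$n_scans, 1)
  fe0 <- fit_fir(as.numeric(y0) - mean(y0), exp1$events, 20, 1,
                 nuisance = dct_drift(134, 1, 128))
  expect_lt(max(abs(fe0$amplitudes)), 5 * t0$noise_sd)
})

test_that("pure-noise FIR amplitudes match analytic OLS standard errors", {
  set.seed(99)
  nuis <- dct_drift(134, 1, 128)
  nrep <- 1000
  b1 <- numeric(nrep)
  for (i in seq_len(nrep)) {
    fe <- fit_fir(rnorm(134), exp1$events, 20, 1, nuisance = nuis)
    b1[i] <- fe$amplitudes[1]
  }
  # analytic SE of bin 1 under unit noise
  fir <- fir_design(exp1$events, 20, 1, 134, 1)
  X <- cbind(fir, nuis, 1)
  se_analytic <- sqrt(chol2inv(chol(crossprod(X)))[1, 1])
  expect_equal(mean(b1), 0, tolerance = 5 * se_analytic / sqrt(nrep))
  expect_equal(sd(b1), se_analytic, tolerance = 0.1 * se_analytic)
})

test_that("event-design FIR stays estimable across jittered schedules", {
  ranks_ok <- vapply(1:50, function(s) {
    runs <- make_exp2_paradigm(seed = s)
    all(vapply(runs, function(r) {
      fir <- fir_design(r$events, 10, 1, r$n_scans, 1)
      X <- cbind(fir, dct_drift(r$n_scans, 1, 128), 1)
      qr(X)$rank == ncol(X)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ranks_ok))
})

test_that("predicted bin response reflects block plateau and species lag", {
  mh <- predicted_bin_response(human, 10, 20, 1)
  md <- predicted_bin_response(dog, 10, 20, 1)
  expect_true(which.max(mh) %in% 10:13)
  expect_lt(which.max(md), which.max(mh))
  # impulse duration: proportional to kernel samples at bin centers
  mi <- predicted_bin_response(human, 0.05, 20, 1, dt = 0.05)
  k <- sample_double_gamma(human, 0.05)
  kc <- k$values[round(((1:20) - 0.5) / 0.05) + 1]
  expect_gt(cor(mi, kc), 0.999999)
})

test_that("optimizer recovers generating parameters without noise", {
  target_dog <- predicted_bin_response(dog, 10, 20, 1)
  fit <- optimize_hrf(matrix(rep(target_dog, 5), 5, byrow = TRUE),
                      n_restarts = 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$params[["p1"]], 4.3, tolerance = 0.1)
  expect_equal(fit$params[["p2"]], 6.6, tolerance = 0.1)
  expect_equal(fit$params[["p5"]], 3.0, tolerance = 0.1)
  expect_lt(fit$params[["p6"]], 0.1)
  expect_gt(fit$mean_r2, 0.999)
  # human-generated data recovers human parameters
  target_h <- predicted_bin_response(human, 10, 20, 1)
  fit_h <- optimize_hrf(matrix(rep(target_h, 3), 3, byrow = TRUE),
                        n_restarts = 2, seed = 2)
  expect_equal(fit_h$params[["p1"]], 6, tolerance = 0.2)
  expect_equal(fit_h$params[["p2"]], 16, tolerance = 2)
  expect_equal(fit_h$params[["p5"]], 6, tolerance = 1.5)
})

test_that("optimizer improves on its start and stays inside bounds", {
  truth <- snr_preset("study_like")
  cohort <- simulate_fir_cohort(6, exp1, truth, seed = 31)
  init_r2 <- mean(hrf_fit_r2(cohort, human))
  fit <- optimize_hrf(cohort, n_restarts = 0)
  expect_gte(fit$mean_r2, init_r2 - 1e-12)
  expect_true(fit$params[["p1"]] >= 1 && fit$params[["p1"]] <= 10)
  expect_true(fit$params[["p2"]] >= 1 && fit$params[["p2"]] <= 20)
  expect_true(fit$params[["p5"]] >= 1 && fit$params[["p5"]] <= 10)
  expect_true(fit$params[["p6"]] >= 0 && fit$params[["p6"]] <= 5)
})

test_that("logistic reparametrization cannot leave the bounds", {
  set.seed(8)
  lo <- c(1, 1, 1, 0); hi <- c(10, 20, 10, 5)
  theta <- matrix(rnorm(10000 * 4, sd = 50), ncol = 4)
  p <- t(apply(theta, 1, caninehrf:::theta_to_param, lo = lo, hi = hi))
  expect_true(all(sweep(p, 2, lo, `>=`)))
  expect_true(all(sweep(p, 2, hi, `<=`)))
  # round trip in the interior
  p0 <- c(4.3, 6.6, 3, 2.5)
  expect_equal(caninehrf:::theta_to_param(
    caninehrf:::param_to_theta(p0, lo, hi), lo, hi), p0, tolerance = 1e-9)
})

test_that("self-consistency: re-optimizing fitted parameters is a fixed point", {
  fitted <- hrf_params(p1 = 3.8, p2 = 8, p5 = 4)
  target <- predicted_bin_response(fitted, 10, 20, 1)
  refit <- optimize_hrf(matrix(target, 1), n_restarts = 0,
                        init = fitted)
  expect_equal(refit$params[["p1"]], 3.8, tolerance = 0.05)
  expect_equal(refit$params[["p2"]], 8, tolerance = 0.05)
  expect_equal(refit$params[["p5"]], 4, tolerance = 0.05)
})

test_that("dog-kernel data prefers the dog parametrization", {
  truth <- snr_preset("study_like")
  wins <- vapply(1:40, function(s) {
    cohort <- simulate_fir_cohort(8, exp1, truth, seed = 2000 + 37 * s)
    cmp <- compare_hrf_fits(cohort, dog, human)
    cmp$mean_a > cmp$mean_b
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
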