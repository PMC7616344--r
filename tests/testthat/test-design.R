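spec16 <- sampling_spec(tr = 1, microtime_bins = 16, reference_bin = 8)

test_that("microtime boxcar places ones exactly over stimulation", {
  ev <- event_table(onset = 10, duration = 10, run_length = 134)
  u <- boxcar_microtime(ev, 134, spec16)
  expect_length(u, 134 * 16)
  expect_equal(which(u == 1), 161:320)  # [160, 320) in 0-based indices
  expect_equal(sum(boxcar_microtime(event_table(numeric(0), numeric(0)),
                                    134, spec16)), 0)
  u6 <- boxcar_microtime(exp1$events, exp1$n_scans, spec16)
  expect_equal(sum(u6), 960)  # 6 blocks x 10 s x 16 bins
  expect_error(boxcar_microtime(event_table(onset = 130, duration = 10),
                                134, spec16), "outside")
})

test_that("convolution reproduces the kernel and respects latency order", {
  k <- sample_double_gamma(human, spec16$dt)
  # unit impulse at t = 0: regressor = kernel at the sampled offsets
  u <- numeric(134 * 16); u[1] <- 1
  reg <- convolve_downsample(u, k, spec16)
  idx <- (seq_len(134) - 1) * 16 + 8
  expect_equal(reg[idx <= length(k$values)],
               k$values[idx[idx <= length(k$values)]])
  # all-zero stimulus
  expect_equal(convolve_downsample(numeric(134 * 16), k, spec16),
               numeric(134))
  # 10 s boxcar: human regressor peaks later than dog regressor
  ev <- event_table(onset = 10, duration = 10)
  u10 <- boxcar_microtime(ev, 60, spec16)
  rh <- convolve_downsample(u10, k, spec16)
  rd <- convolve_downsample(u10, sample_double_gamma(dog, spec16$dt),
                            spec16)
  expect_gt(which.max(rh), which.max(rd))
  # dt mismatch rejected
  k2 <- sample_double_gamma(human, 0.1)
  expect_error(convolve_downsample(u10, k2, spec16), "dt")
})

test_that("convolution is linear over disjoint event sets", {
  a <- event_table(onset = c(10, 50), duration = 5)
  b <- event_table(onset = c(30, 70), duration = 5)
  ab <- event_table(onset = c(10, 30, 50, 70), duration = 5)
  k <- sample_double_gamma(dog, spec16$dt)
  r <- function(ev) convolve_downsample(boxcar_microtime(ev, 100, spec16),
                                        k, spec16)
  expect_equal(r(ab), r(a) + r(b), tolerance = 1e-12)
})

test_that("FIR design has the staircase and summing structure", {
  ev <- event_table(onset = 10, duration = 1)
  m <- fir_design(ev, 20, 1, 134, 1)
  for (j in 0:19) expect_equal(which(m[, j + 1] == 1), 11 + j)
  # block paradigm: each column one 1 per block
  m6 <- fir_design(exp1$events, 20, 1, 134, 1)
  expect_true(all(colSums(m6) == 6))
  expect_true(all(m6 %in% c(0, 1)))
  # overlapping events sum; verify against a brute-force loop
  ev2 <- event_table(onset = c(20, 23), duration = 1)
  m2 <- fir_design(ev2, 10, 1, 60, 1)
  brute <- matrix(0, 60, 10)
  for (on in c(20, 23)) for (j in 0:9) {
    r <- on + j + 1
    if (r <= 60) brute[r, j + 1] <- brute[r, j + 1] + 1
  }
  expect_equal(unname(m2), brute)
  # truncation warning for late events
  expect_warning(fir_design(event_table(onset = 130, duration = 1),
                            20, 1, 134, 1), "truncat")
})

test_that("DCT drift columns match the cutoff arithmetic", {
  d134 <- dct_drift(134, 1, 128)
  d270 <- dct_drift(270, 1, 128)
  expect_equal(ncol(d134), 2)
  expect_equal(ncol(d270), 4)
  expect_equal(crossprod(d270), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(d0 <- dct_drift(20, 1, 60), "no drift")
  expect_equal(ncol(d0), 0)
  expect_error(dct_drift(134, 1, 1.5), "cutoff")
})

test_that("framewise displacement follows the Power convention", {
  expect_equal(framewise_displacement(matrix(0, 10, 6)), rep(0, 10))
  m <- matrix(0, 10, 6); m[5:10, 1] <- 0.3
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 0.3)
  expect_equal(fd[6], 0)
  mr <- matrix(0, 5, 6); mr[3:5, 4] <- 0.002
  expect_equal(framewise_displacement(mr, radius = 50)[3], 0.1)
  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("spike regressors use a strict threshold and one-hot columns", {
  sp <- spike_regressors(c(0, 0.6, 0.2, 0.55))
  expect_equal(sp$flagged, c(2, 4))
  expect_equal(sp$fraction, 0.5)
  expect_equal(colSums(sp$columns), c(spike_002 = 1, spike_004 = 1))
  expect_equal(ncol(spike_regressors(c(0, 0.1, 0.3))$columns), 0)
  expect_equal(spike_regressors(c(0, 0.5))$flagged, integer(0))  # strict >
})

test_that("assembled designs have the documented column counts", {
  motion <- matrix(rnorm(134 * 6, sd = 0.01), 134, 6)
  task <- task_regressors(exp1$events,
                          sample_double_gamma(human, spec16$dt),
                          134, spec16)
  X <- assemble_design(task, drift = dct_drift(134, 1, 128),
                       motion = motion, tr = 1)
  expect_equal(ncol(X$matrix), 10)  # 1 task + 2 drift + 6 motion + const
  expect_equal(sum(X$roles == "constant"), 1)
  basis <- hrf_basis(human, spec16$dt)
  task3 <- task_regressors(exp1$events, basis, 134, spec16)
  X3 <- assemble_design(task3, drift = dct_drift(134, 1, 128),
                        motion = motion, tr = 1)
  expect_equal(ncol(X3$matrix), 12)  # + TD and DD columns
  # duplicate spike columns rejected
  sp <- matrix(0, 134, 2); sp[10, 1] <- 1; sp[10, 2] <- 1
  colnames(sp) <- c("spike_a", "spike_b")
  expect_error(assemble_design(task, spikes = sp, tr = 1), "duplicate")
  # all-zero task rejected
  expect_error(assemble_design(cbind(task = numeric(134)), tr = 1),
               "all-zero")
})

test_that("scrubbing shields estimates from corrupted flagged scans", {
  set.seed(42)
  k <- sample_double_gamma(dog, spec16$dt)
  task <- task_regressors(exp1$events, k, 134, spec16)
  y <- 2 * task[, 1] + 1
  bad <- c(17, 60, 101)
  sp <- matrix(0, 134, 3)
  sp[cbind(bad, 1:3)] <- 1
  colnames(sp) <- sprintf("spike_%03d", bad)
  y_bad <- y; y_bad[bad] <- y_bad[bad] + c(50, -20, 8)
  X <- assemble_design(task, spikes = sp, tr = 1)
  fit_clean <- fit_ols(y, X)
  fit_corr <- fit_ols(y_bad, X)
  expect_equal(fit_corr$betas[["task"]], 2, tolerance = 1e-8)
  expect_equal(fit_corr$betas[["task"]], fit_clean$betas[["task"]],
               tolerance = 1e-8)
})
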