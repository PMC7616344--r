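test_that("parameter validation rejects implausible shapes", {
  expect_s3_class(hrf_params(), "hrf_params")
  expect_error(hrf_params(p1 = 16, p2 = 6), "p1.*smaller than")
  expect_error(hrf_params(p3 = 0), "dispersion")
  expect_error(hrf_params(p6 = -1), "p6")
  expect_error(hrf_params(p7 = 10), "p7")
  expect_equal(as.numeric(hrf_preset("human_canonical")),
               c(6, 16, 1, 1, 6, 0, 32))
  expect_equal(as.numeric(hrf_preset("dog_boch2020")),
               c(4.3, 6.6, 1, 1, 3, 0, 32))
})

test_that("sampled kernel matches the closed form, unit-sum normalized", {
  h <- sample_double_gamma(human, dt = 0.0625)
  expect_length(h$values, 513)
  expect_equal(sum(h$values), 1, tolerance = 1e-10)
  # against the closed-form oracle up to the normalization constant
  t <- seq(0, 32, by = 0.0625)
  raw <- oracle_double_gamma(t, 6, 16, 1, 1, 6, 0)
  expect_equal(h$values, raw / sum(raw), tolerance = 1e-12)
})

test_that("peak times: human ~5 s, dog ~3 s, human - dog ~2 s", {
  h <- sample_double_gamma(human, dt = 0.001)
  d <- sample_double_gamma(dog, dt = 0.001)
  expect_equal(peak_time(h), 4.999, tolerance = 1e-6)   # frozen oracle value
  expect_equal(peak_time(d), 3.019, tolerance = 1e-6)   # frozen oracle value
  expect_equal(peak_time(h), oracle_peak(6, 16))
  expect_equal(peak_time(d), oracle_peak(4.3, 6.6, p5 = 3))
  expect_gt(peak_time(h) - peak_time(d), 1.9)
  expect_lt(peak_time(h) - peak_time(d), 3.1)
})

test_that("peak_time handles impulses, ties and degenerate input", {
  imp <- structure(list(values = replace(numeric(100), 41, 1), dt = 0.1),
                   class = "sampled_hrf")
  expect_equal(peak_time(imp), 4.0)
  two <- structure(list(values = c(0, 1, 0, 1, 0), dt = 1),
                   class = "sampled_hrf")
  expect_equal(peak_time(two), 1)  # tie broken toward earlier time
  flat <- structure(list(values = numeric(10), dt = 1),
                    class = "sampled_hrf")
  expect_error(peak_time(flat), "constant")
})

test_that("temporal derivative converges to the analytic onset derivative", {
  dt <- 0.01
  t <- seq(0, 32, by = dt)
  raw <- oracle_double_gamma(t, 6, 16, 1, 1, 6, 0)
  norm <- raw / sum(raw)
  # central-difference oracle on the normalized closed form w.r.t. onset
  eps <- 1e-5
  up <- oracle_double_gamma(t, 6, 16, 1, 1, 6, eps)
  dn <- oracle_double_gamma(t, 6, 16, 1, 1, 6, 0)  # p6 = -eps invalid; forward
  analytic <- (dn / sum(dn) - up / sum(up)) / eps
  errs <- vapply(c(1, 0.1, 0.01), function(s) {
    td <- temporal_derivative(human, dt, shift = s)
    max(abs(td$values - analytic)) / max(abs(analytic))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # error shrinks with the shift
  expect_lt(errs[3], 0.02)                  # near-converged at 0.01 s
  # zero before onset
  p6_2 <- hrf_params(p6 = 2)
  td <- temporal_derivative(p6_2, dt = 0.1, shift = 0.5)
  expect_true(all(td$values[seq_len(20)] == 0))   # t < p6
  # zero crossing near the canonical peak
  td1 <- temporal_derivative(human, dt = 0.01, shift = 1)
  sgn <- sign(td1$values)
  crossings <- which(diff(sgn[sgn != 0]) != 0)
  tcross <- (which(diff(sign(td1$values + 1e-15)) != 0)[1]) * 0.01
  expect_true(abs(tcross - 5) <= 1.1)
})

test_that("dispersion derivative converges and integrates to zero", {
  dt <- 0.01
  dd_fine <- dispersion_derivative(human, dt, dp3 = 1e-4)$values
  dd_coarse <- dispersion_derivative(human, dt, dp3 = 0.05)$values
  dd_def <- dispersion_derivative(human, dt, dp3 = 0.01)$values
  # refinement: default closer to the fine-step limit than the coarse step
  expect_lt(max(abs(dd_def - dd_fine)), max(abs(dd_coarse - dd_fine)))
  # unit-sum normalization of both kernels makes the column sum exactly 0
  expect_equal(sum(dd_def), 0, tolerance = 1e-12)
  # non-degenerate in p3
  p3x2 <- hrf_params(p3 = 2)
  expect_gt(max(abs(dispersion_derivative(p3x2, dt)$values - dd_def)), 1e-4)
})

test_that("successive orthogonalization leaves residuals orthogonal", {
  b <- hrf_basis(human, dt = 0.0625, derivatives = TRUE,
                 orthogonalize = TRUE)
  g <- crossprod(b$columns)
  expect_lt(abs(g[1, 2]), 1e-8 * sqrt(g[1, 1] * max(g[2, 2], 1e-30)))
  expect_lt(abs(g[1, 3]), 1e-8)
  expect_lt(abs(g[2, 3]), 1e-8)
  # identical columns: second becomes zero
  m <- cbind(a = 1:5, b = 1:5)
  expect_equal(orthogonalize_basis(m)[, 2], rep(0, 5))
  # already-orthogonal columns unchanged
  m2 <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(orthogonalize_basis(m2), m2, tolerance = 1e-12)
})

test_that("kernel properties: monotone latency, onset shift, p5 limit", {
  # peak time strictly increasing in p1
  peaks <- vapply(3:9, function(p1)
    peak_time(sample_double_gamma(hrf_params(p1 = p1), 0.001)),
    numeric(1))
  expect_true(all(diff(peaks) > 0))
  # sampling with p6 = c equals the p6 = 0 kernel delayed by c
  dt <- 0.05
  h0 <- sample_double_gamma(human, dt)$values
  h2 <- sample_double_gamma(hrf_params(p6 = 2), dt)$values
  shift_bins <- round(2 / dt)
  overlap <- seq_len(length(h0) - shift_bins)
  ratio <- sum(h0[overlap]) # renormalization differs by truncated mass
  expect_equal(h2[overlap + shift_bins] * ratio, h0[overlap] ,
               tolerance = 1e-6)
  # p5 -> inf: kernel converges to the single gamma density (mode p1 - p3)
  big <- hrf_params(p5 = 1e8)
  hbig <- sample_double_gamma(big, 0.001)
  expect_equal(peak_time(hbig), 5.0, tolerance = 0.002)
})

test_that("HRF config files round-trip", {
  path <- tempfile(fileext = ".cfg")
  write_hrf_config(dog, path)
  back <- read_hrf_config(path)
  expect_equal(as.numeric(back), as.numeric(dog))
  writeLines(c("p1 = 6", "junk line"), path)
  expect_error(read_hrf_config(path), "malformed|must define")
})
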