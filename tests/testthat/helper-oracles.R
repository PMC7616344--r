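# Independent closed-form evaluation of the double-gamma difference,
# used as the oracle against the package's sampling path.
oracle_double_gamma <- function(t, p1, p2, p3, p4, p5, p6 = 0) {
  h <- dgamma(t - p6, shape = p1 / p3, scale = p3) -
    dgamma(t - p6, shape = p2 / p4, scale = p4) / p5
  h[t < p6] <- 0
  h
}

# dense-grid argmax of the closed form (0.001 s grid)
oracle_peak <- function(p1, p2, p3 = 1, p4 = 1, p5 = 6, p6 = 0, p7 = 32) {
  t <- seq(0, p7, by = 0.001)
  t[which.max(oracle_double_gamma(t, p1, p2, p3, p4, p5, p6))]
}

# literal 2^n enumeration of the signed-rank null (test-side oracle)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(w_plus = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

exp1 <- make_exp1_paradigm()
human <- hrf_preset("human_canonical")
dog <- hrf_preset("dog_boch2020")
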