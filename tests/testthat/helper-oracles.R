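# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (closed-form harmonic regression, fisher.test,
# the package's permutation enumerator) so that agreement is informative.

# Cosinor oracle: coarse grid over the acrophase with a per-phase linear
# fit of (mesor, amplitude), then iterative refinement of the SSE minimum.
oracle_cosinor <- function(times, values, period = 24) {
  sse_at <- function(phi) {
    x <- cos(2 * pi * (times - phi) / period)
    sum(stats::lm(values ~ x)$residuals^2)
  }
  grid <- seq(0, period - 0.01, by = 0.01)
  sse <- vapply(grid, sse_at, numeric(1))
  phi0 <- grid[which.min(sse)]
  opt <- stats::optimize(sse_at, c(phi0 - 0.02, phi0 + 0.02), tol = 1e-12)
  phi <- opt$minimum %% period
  x <- cos(2 * pi * (times - phi) / period)
  co <- stats::coef(stats::lm(values ~ x))
  amp <- unname(co[2])
  if (amp < 0) {
    amp <- -amp
    phi <- (phi + period / 2) %% period
  }
  sst <- sum((values - mean(values))^2)
  list(mesor = unname(co[1]), amplitude = amp, peak_hour = phi,
       r2 = 1 - opt$objective / sst)
}

# Independent permutation enumerator (iterative Heap-style, distinct from
# the package's recursive generator).
oracle_perms <- function(n) {
  out <- matrix(seq_len(n), nrow = 1)
  for (m in 2:n) {
    grown <- vector("list", m)
    for (pos in 1:m) {
      ins <- cbind(out[, seq_len(pos - 1), drop = FALSE], m,
                   out[, seq(pos, m - 1)[seq_len(m - pos)], drop = FALSE])
      grown[[pos]] <- ins
    }
    out <- do.call(rbind, grown)
  }
  out
}

# lm-based R^2 of a 24 h harmonic fit, for the exhaustive-permutation oracle.
oracle_r2 <- function(times, values, period = 24) {
  c1 <- cos(2 * pi * times / period)
  s1 <- sin(2 * pi * times / period)
  summary(stats::lm(values ~ c1 + s1))$r.squared
}

# Full-enumeration Fisher oracle over all 2x2 tables with fixed margins.
oracle_fisher <- function(a, b, c_, d, sidedness) {
  n <- a + b + c_ + d
  m1 <- a + b
  k1 <- a + c_
  xs <- max(0, m1 + k1 - n):min(m1, k1)
  probs <- stats::dhyper(xs, k1, n - k1, m1)
  p_obs <- stats::dhyper(a, k1, n - k1, m1)
  switch(sidedness,
         two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]))
}

# Absolute circular difference in hours on a 24 h circle.
circ_abs_h <- function(x) abs(((x + 12) %% 24) - 12)

# Independent ZT wrap: step-wise search for the representative in [-6,18).
oracle_zt <- function(tod, sunrise) {
  z <- tod - sunrise
  while (z < -6) z <- z + 24
  while (z >= 18) z <- z - 24
  z
}

# Small noiseless cohort used by several structural tests.
noiseless_cohort <- function(n_transcripts = 50, seed = 11) {
  simulate_cohort(simulation_config(
    n_per_group = 20, n_transcripts = n_transcripts,
    frac_rhythmic_g1 = 1, frac_rhythmic_g2 = 1, frac_shared = 1,
    amplitude_dist = c(2, 0.5), noise_sd = 0, phase_kappa = 0, seed = seed))
}

group_slice <- function(sim, group) {
  ids <- sim$metadata$subject_id[sim$metadata$group == group]
  list(matrix = sim$matrix[, ids, drop = FALSE],
       zt = sim$metadata$zt[match(ids, sim$metadata$subject_id)],
       metadata = sim$metadata[sim$metadata$group == group, ])
}
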