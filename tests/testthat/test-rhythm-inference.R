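test_that("analysis_config validates its fields", {
  expect_error(analysis_config(n_perm = 0), class = "configuration_error")
  expect_error(analysis_config(alpha = 0), class = "configuration_error")
  expect_error(analysis_config(alpha = 1), class = "configuration_error")
})

test_that("a noiseless rhythmic transcript attains the minimal empirical p", {
  sim <- noiseless_cohort(5, seed = 31)
  g1 <- group_slice(sim, "group1")
  cfg <- analysis_config(n_perm = 200, seed = 1)
  res <- empirical_rhythm_p(g1$matrix, g1$zt, cfg)
  expect_true(all(res$p_emp == 1 / 201))
  expect_true(all(res$is_rhythmic))
  # empirical p can never be zero and is bounded below by 1/(B+1)
  expect_true(all(res$p_emp >= 1 / 201))
})

test_that("empirical p-values are monotone nonincreasing in observed R2", {
  sim <- simulate_cohort(simulation_config(
    n_transcripts = 80, frac_rhythmic_g1 = 0.4, frac_rhythmic_g2 = 0.4,
    frac_shared = 0.4, noise_sd = 1, seed = 32))
  g1 <- group_slice(sim, "group1")
  res <- empirical_rhythm_p(g1$matrix, g1$zt,
                            analysis_config(n_perm = 300, seed = 2,
                                            null_mode = "pooled"))
  ord <- order(res$r2)
  expect_true(all(diff(res$p_emp[ord]) <= 1e-12))
})

test_that("exhaustive permutation p equals independent enumeration (n = 5)", {
  set.seed(33)
  zt <- c(-4, 1.5, 6, 11, 16)
  Y <- matrix(rnorm(15), 3, 5,
              dimnames = list(paste0("T", 1:3), paste0("S", 1:5)))
  res <- empirical_rhythm_p(Y, zt, analysis_config(seed = 1), exhaustive = TRUE)
  perms <- oracle_perms(5)
  expect_equal(nrow(perms), 120)
  for (i in 1:3) {
    null_r2 <- apply(perms, 1, function(p) oracle_r2(zt[p], Y[i, ]))
    obs <- oracle_r2(zt, Y[i, ])
    expect_equal(res$p_emp[i], mean(null_r2 >= obs - 1e-9), tolerance = 1e-9)
  }
})

test_that("exhaustive delta-R2 p equals enumeration over shuffle pairs (n = 4)", {
  set.seed(34)
  zt1 <- c(0, 5, 11, 17)
  zt2 <- c(2, 7, 13, 20)
  Y1 <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), paste0("P", 1:4)))
  Y2 <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), paste0("Q", 1:4)))
  res <- delta_r2_test(Y1, Y2, zt1, zt2, analysis_config(seed = 1),
                       exhaustive = TRUE)
  p1 <- oracle_perms(4)
  for (i in 1:2) {
    obs <- oracle_r2(zt1, Y1[i, ]) - oracle_r2(zt2, Y2[i, ])
    null_d <- as.vector(outer(
      apply(p1, 1, function(p) oracle_r2(zt1[p], Y1[i, ])),
      apply(p1, 1, function(p) oracle_r2(zt2[p], Y2[i, ])),
      "-"))
    expect_equal(res$p_loss[i], mean(null_d >= obs - 1e-9), tolerance = 1e-9)
    expect_equal(res$p_gain[i], mean(-null_d >= -obs - 1e-9), tolerance = 1e-9)
  }
})

test_that("identical data in both groups gives zero deltas and null p-values", {
  sim <- simulate_cohort(simulation_config(n_transcripts = 40, seed = 35))
  g1 <- group_slice(sim, "group1")
  res <- delta_r2_test(g1$matrix, g1$matrix, g1$zt, g1$zt,
                       analysis_config(n_perm = 200, seed = 3))
  expect_true(all(res$delta_loss == 0))
  expect_equal(res$delta_gain, -res$delta_loss)
  # type-I behaviour only: no excess of significant calls
  expect_lt(mean(res$p_loss < 0.05), 0.15)
})

test_that("rhythm-change classification applies the two-criterion rule", {
  row <- function(p1, pl, p2, pg) {
    list(g1 = data.frame(transcript_id = "t", p_emp = p1),
         g2 = data.frame(transcript_id = "t", p_emp = p2),
         d = data.frame(transcript_id = "t", p_loss = pl, p_gain = pg))
  }
  cases <- list(
    list(args = row(0.01, 0.02, 0.40, 0.98), want = "less_rhythmic_in_g2"),
    list(args = row(0.20, 0.01, 0.40, 0.98), want = "unchanged"),
    list(args = row(0.40, 0.98, 0.01, 0.02), want = "more_rhythmic_in_g2"),
    list(args = row(1.0, 1.0, 1.0, 1.0), want = "unchanged"),
    # simultaneous qualification resolves to unchanged
    list(args = row(0.01, 0.01, 0.01, 0.01), want = "unchanged"))
  for (cs in cases) {
    expect_identical(
      classify_rhythm_change(cs$args$g1, cs$args$g2, cs$args$d, 0.05),
      cs$want)
  }
  bad <- row(0.5, 0.5, 0.5, 0.5)
  bad$g2$transcript_id <- "other"
  expect_error(classify_rhythm_change(bad$g1, bad$g2, bad$d),
               class = "alignment_error")
})

test_that("classification is anti-symmetric under group swap", {
  sim <- simulate_cohort(simulation_config(
    n_transcripts = 60, frac_rhythmic_g1 = 0.5, frac_rhythmic_g2 = 0.1,
    frac_shared = 0.1, amplitude_dist = c(3, 0), noise_sd = 0.5, seed = 36))
  g1 <- group_slice(sim, "group1")
  g2 <- group_slice(sim, "group2")
  cfg <- analysis_config(n_perm = 200, seed = 4)
  r1 <- empirical_rhythm_p(g1$matrix, g1$zt, cfg)
  r2 <- empirical_rhythm_p(g2$matrix, g2$zt, cfg)
  fwd <- delta_r2_test(g1$matrix, g2$matrix, g1$zt, g2$zt, cfg)
  cat_fwd <- classify_rhythm_change(r1, r2, fwd, 0.05)
  # swapped direction: rebuild the reversed diff from the same statistics
  rev <- fwd
  rev[, c("r2_g1", "r2_g2")] <- fwd[, c("r2_g2", "r2_g1")]
  rev[, c("delta_loss", "delta_gain")] <- fwd[, c("delta_gain", "delta_loss")]
  rev[, c("p_loss", "p_gain")] <- fwd[, c("p_gain", "p_loss")]
  cat_rev <- classify_rhythm_change(r2, r1, rev, 0.05)
  map <- c(less_rhythmic_in_g2 = "more_rhythmic_in_g2",
           more_rhythmic_in_g2 = "less_rhythmic_in_g2",
           unchanged = "unchanged")
  expect_identical(unname(map[cat_fwd]), cat_rev)
})

test_that("phase/amplitude/base comparison handles the circular boundary", {
  zt <- seq(-6, 17, length.out = 24)
  ids <- "t1"
  y1 <- matrix(2 + 3 * cos(2 * pi * (zt - 23) / 24), 1,
               dimnames = list(ids, paste0("A", 1:24)))
  y2 <- matrix(2 + 3 * cos(2 * pi * (zt - 1) / 24), 1,
               dimnames = list(ids, paste0("B", 1:24)))
  res <- compare_phase_amp_base(y1, y2, zt, zt, ids,
                                analysis_config(n_perm = 19, seed = 5))
  expect_equal(res$phase_diff, 2, tolerance = 1e-9)
  expect_equal(res$amp_diff, 0, tolerance = 1e-9)
  expect_equal(res$base_diff, 0, tolerance = 1e-9)
  expect_error(compare_phase_amp_base(y1, y2, zt, zt, "absent",
                                      analysis_config(n_perm = 5)),
               class = "membership_error")
})

test_that("identical groups give zero parameter differences", {
  sim <- noiseless_cohort(10, seed = 37)
  g1 <- group_slice(sim, "group1")
  ids <- rownames(g1$matrix)[1:5]
  res <- compare_phase_amp_base(g1$matrix, g1$matrix, g1$zt, g1$zt, ids,
                                analysis_config(n_perm = 39, seed = 6))
  expect_true(all(abs(res$phase_diff) < 1e-9))
  expect_true(all(abs(res$amp_diff) < 1e-9))
  expect_true(all(abs(res$base_diff) < 1e-9))
})

test_that("fixed seeds make permutation results bit-reproducible", {
  sim <- simulate_cohort(simulation_config(n_transcripts = 30, seed = 38))
  g1 <- group_slice(sim, "group1")
  g2 <- group_slice(sim, "group2")
  cfg <- analysis_config(n_perm = 100, seed = 7)
  expect_identical(empirical_rhythm_p(g1$matrix, g1$zt, cfg),
                   empirical_rhythm_p(g1$matrix, g1$zt, cfg))
  expect_identical(delta_r2_test(g1$matrix, g2$matrix, g1$zt, g2$zt, cfg),
                   delta_r2_test(g1$matrix, g2$matrix, g1$zt, g2$zt, cfg))
})
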