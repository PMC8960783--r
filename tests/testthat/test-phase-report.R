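make_fits <- function(peaks, ids = sprintf("T%03d", seq_along(peaks))) {
  data.frame(transcript_id = ids, mesor = 0, amplitude = 1,
             peak_hour = peaks, r2 = 0.9, n_obs = 20, period_hours = 24,
             stringsAsFactors = FALSE)
}

test_that("peak-hour distribution summarizes concentrated and uniform phases", {
  fits <- make_fits(rep(4, 25))
  d <- peak_hour_distribution(fits, fits$transcript_id, n_bins = 24)
  expect_equal(sum(d$counts), 25)
  expect_equal(sum(d$counts > 0), 1)
  expect_equal(d$circular_mean, 4, tolerance = 1e-9)
  expect_equal(d$circular_concentration, 1, tolerance = 1e-9)

  set.seed(61)
  unif <- make_fits(runif(1500, 0, 24))
  du <- peak_hour_distribution(unif, unif$transcript_id)
  expect_lt(du$circular_concentration, 0.1)
  expect_equal(sum(du$counts), 1500)

  expect_warning(d0 <- peak_hour_distribution(fits, character(0)))
  expect_equal(sum(d0$counts), 0)
  expect_error(peak_hour_distribution(fits, "missing"),
               class = "membership_error")
})

test_that("bimodal generator phases are recovered by the distribution", {
  sim <- simulate_cohort(simulation_config(
    n_transcripts = 600, frac_rhythmic_g1 = 1, frac_rhythmic_g2 = 1,
    frac_shared = 1, phase_mode_hours = c(4, 16), phase_kappa = 8,
    noise_sd = 0, seed = 62))
  g1 <- group_slice(sim, "group1")
  fits <- fit_matrix(g1$matrix, g1$metadata)
  cl <- detect_peak_clusters(fits$peak_hour, k = 2, seed = 1)
  expect_lt(circ_abs_h(cl$centers[1] - 4), 1)
  expect_lt(circ_abs_h(cl$centers[2] - 16), 1)
})

test_that("circular k-means finds antiphase clumps and degenerates to the
           circular mean at k = 1", {
  set.seed(63)
  h <- c(rnorm(40, 11, 0.3), rnorm(40, 23, 0.3)) %% 24
  cl <- detect_peak_clusters(h, 2)
  expect_lt(circ_abs_h(cl$centers[1] - 11), 0.5)
  expect_lt(circ_abs_h(cl$centers[2] - 23), 0.5)
  expect_equal(length(cl$assignments), 80)

  one <- detect_peak_clusters(h, 1)
  theta <- 2 * pi * h / 24
  want <- (atan2(mean(sin(theta)), mean(cos(theta))) * 24 / (2 * pi)) %% 24
  expect_equal(one$centers, want, tolerance = 1e-9)
  expect_error(detect_peak_clusters(c(1, 1, 1), 2),
               class = "configuration_error")
})

test_that("circular k-means matches an exhaustive contiguous-arc oracle", {
  set.seed(64)
  h <- sort(runif(30, 0, 24))
  cl <- detect_peak_clusters(h, 2, n_start = 40)
  # optimal 2-clustering on a circle is contiguous on the sorted circle:
  # enumerate every pair of cut points
  circ_mean <- function(x) {
    th <- 2 * pi * x / 24
    (atan2(mean(sin(th)), mean(cos(th))) * 24 / (2 * pi)) %% 24
  }
  wss_of <- function(members) {
    sum(vapply(members, function(m) {
      sum(circ_abs_h(h[m] - circ_mean(h[m]))^2)
    }, numeric(1)))
  }
  best <- Inf
  n <- length(h)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    arc <- if (i < j) i:(j - 1) else c(i:n, seq_len(j - 1))
    best <- min(best, wss_of(list(arc, setdiff(1:n, arc))))
  }
  expect_equal(cl$withinss, best, tolerance = 1e-6)
})

test_that("cluster centers rotate with the data", {
  set.seed(65)
  h <- c(rnorm(30, 5, 0.4), rnorm(30, 14, 0.4)) %% 24
  base <- detect_peak_clusters(h, 2, seed = 2)
  rot <- detect_peak_clusters((h + 7) %% 24, 2, seed = 2)
  shifted <- sort((base$centers + 7) %% 24)
  expect_equal(rot$centers, shifted, tolerance = 1e-6)
})

test_that("phase-ordered heatmap rows are Z-scored and ordered by peak", {
  sim <- noiseless_cohort(40, seed = 66)
  g1 <- group_slice(sim, "group1")
  fits <- fit_matrix(g1$matrix, g1$metadata)
  res <- empirical_rhythm_p(g1$matrix, g1$zt,
                            analysis_config(n_perm = 50, seed = 1))
  hm <- phase_ordered_heatmap(g1$matrix, g1$metadata, fits, res, top_n = 40)
  expect_setequal(hm$row_order, rownames(g1$matrix))
  expect_setequal(hm$col_order, colnames(g1$matrix))
  expect_true(all(abs(rowMeans(hm$values)) < 1e-10))
  expect_true(all(abs(apply(hm$values, 1, sd) - 1) < 1e-10))
  expect_true(!is.unsorted(hm$peak_hours))
  expect_true(!is.unsorted(hm$zt))
  # noiseless cohort: per-row argmax column is circularly monotone
  pos <- apply(hm$values, 1, which.max)
  expect_lte(sum(diff(pos) < 0), 1)
})

test_that("heatmap handles constant rows and clamps top_n with a warning", {
  sim <- noiseless_cohort(10, seed = 67)
  g1 <- group_slice(sim, "group1")
  m <- g1$matrix
  m[3, ] <- 7
  fits <- fit_matrix(m, g1$metadata)
  res <- empirical_rhythm_p(m, g1$zt, analysis_config(n_perm = 20, seed = 1))
  expect_warning(hm <- phase_ordered_heatmap(m, g1$metadata, fits, res,
                                             top_n = 25),
                 "clamping")
  expect_equal(nrow(hm$values), 10)
  expect_identical(hm$constant_rows, rownames(m)[3])
  expect_false(anyNA(hm$values))
})

test_that("scatter tables put noiseless points on the fitted curve", {
  sim <- noiseless_cohort(5, seed = 68)
  g1 <- group_slice(sim, "group1")
  fits <- fit_matrix(g1$matrix, g1$metadata)
  id <- fits$transcript_id[1]
  sc <- rhythm_scatter(id, g1$matrix, g1$metadata, fits)
  expect_equal(range(sc$curve$zt), c(-6, 17.9))
  predicted <- fits$mesor[1] +
    fits$amplitude[1] * cos(2 * pi * (sc$points$zt - fits$peak_hour[1]) / 24)
  expect_lt(max(abs(sc$points$expression - predicted)), 1e-9)
  # curve maximum sits within one grid step of the fitted peak hour
  tmax <- sc$curve$zt[which.max(sc$curve$fitted)]
  expect_lt(circ_abs_h(tmax - fits$peak_hour[1]), 0.1 + 1e-9)
  # periodicity of the fitted curve
  expect_equal(sc$curve$fitted[sc$curve$zt == -6],
               fits$mesor[1] + fits$amplitude[1] *
                 cos(2 * pi * (18 - fits$peak_hour[1]) / 24),
               tolerance = 1e-12)
  expect_error(rhythm_scatter("nope", g1$matrix, g1$metadata, fits),
               class = "membership_error")
})
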