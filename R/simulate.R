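#' Configuration for the synthetic postmortem cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults
#' emulate a two-group postmortem brain cohort: 20 subjects per group,
#' times of death spread over the day, a small fraction of transcripts
#' rhythmic in each group with the two rhythmic sets largely distinct,
#' bimodal peak hours ~12 h apart, and additive Gaussian noise on
#' log-scale expression.
#'
#' @param n_per_group subjects per group (default 20).
#' @param n_transcripts number of transcripts (default 2000).
#' @param frac_rhythmic_g1,frac_rhythmic_g2 fraction of transcripts rhythmic
#'   in group 1 (reference / unaffected) and group 2 (default 0.05 and
#'   0.025, matching observed rhythmic fractions of roughly 700 and 340 out
#'   of ~15,000 expressed transcripts).
#' @param frac_shared fraction of the larger rhythmic set that is rhythmic
#'   in both groups (default 0.026, i.e. largely distinct sets).
#' @param amplitude_dist `c(mean, sd)` of rhythm amplitude on the
#'   log-expression scale (default `c(1.5, 0.5)`, truncated below at 0.1).
#' @param mesor_dist `c(mean, sd)` of transcript mesors (default `c(5, 2)`).
#' @param phase_mode_hours circular cluster centers of peak hours in
#'   \eqn{[0,24)} (default `c(4, 16)`).
#' @param phase_kappa von Mises concentration of peak hours around the
#'   cluster centers (default 2; 0 gives uniform phases).
#' @param noise_sd additive Gaussian noise sd (default 0.5).
#' @param ultradian_frac fraction of transcripts given an extra 12 h
#'   component (default 0).
#' @param ultradian_amp amplitude of the 12 h component (default 1).
#' @param phase_shift_hours phase shift applied to group 2 for shared
#'   rhythmic transcripts (default 0: shared transcripts keep identical
#'   phase across groups).
#' @param tod_sampler `"uniform"` over \eqn{[0,24)}, or
#'   `"empirical-death-curve"` using `tod_weights` per 4 h bin.
#' @param tod_weights nonnegative weights for the six 4 h clock bins
#'   (used only by the weighted sampler).
#' @param sunrise_hour,sunset_hour clock hours of sunrise/sunset shared by
#'   all subjects (defaults 6 and 18).
#' @param period_hours fundamental period (default 24).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   datasets.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_per_group = 20,
                              n_transcripts = 2000,
                              frac_rhythmic_g1 = 0.05,
                              frac_rhythmic_g2 = 0.025,
                              frac_shared = 0.026,
                              amplitude_dist = c(1.5, 0.5),
                              mesor_dist = c(5, 2),
                              phase_mode_hours = c(4, 16),
                              phase_kappa = 2,
                              noise_sd = 0.5,
                              ultradian_frac = 0,
                              ultradian_amp = 1,
                              phase_shift_hours = 0,
                              tod_sampler = c("uniform", "empirical-death-curve"),
                              tod_weights = c(1.4, 1.2, 1, 0.8, 0.8, 0.8),
                              sunrise_hour = 6,
                              sunset_hour = 18,
                              period_hours = 24,
                              seed = 1L) {
  tod_sampler <- match.arg(tod_sampler)
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_transcripts = as.integer(n_transcripts),
              frac_rhythmic_g1 = frac_rhythmic_g1,
              frac_rhythmic_g2 = frac_rhythmic_g2,
              frac_shared = frac_shared,
              amplitude_dist = amplitude_dist, mesor_dist = mesor_dist,
              phase_mode_hours = phase_mode_hours, phase_kappa = phase_kappa,
              noise_sd = noise_sd, ultradian_frac = ultradian_frac,
              ultradian_amp = ultradian_amp,
              phase_shift_hours = phase_shift_hours,
              tod_sampler = tod_sampler, tod_weights = tod_weights,
              sunrise_hour = sunrise_hour, sunset_hour = sunset_hour,
              period_hours = period_hours, seed = as.integer(seed))
  for (f in c("frac_rhythmic_g1", "frac_rhythmic_g2", "frac_shared",
              "ultradian_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      td_stop("configuration_error", "`%s` must be a fraction in [0,1]", f)
    }
  }
  for (f in c("noise_sd", "ultradian_amp", "phase_kappa")) {
    if (cfg[[f]] < 0) td_stop("configuration_error", "`%s` must be >= 0", f)
  }
  if (any(cfg$phase_mode_hours < 0 | cfg$phase_mode_hours >= 24)) {
    td_stop("configuration_error", "`phase_mode_hours` must lie in [0,24)")
  }
  if (cfg$amplitude_dist[2] < 0 || cfg$mesor_dist[2] < 0) {
    td_stop("configuration_error", "distribution sds must be >= 0")
  }
  if (cfg$n_per_group < 1 || cfg$n_transcripts < 1) {
    td_stop("configuration_error",
            "`n_per_group` and `n_transcripts` must be positive")
  }
  n_g1 <- round(cfg$frac_rhythmic_g1 * cfg$n_transcripts)
  n_g2 <- round(cfg$frac_rhythmic_g2 * cfg$n_transcripts)
  n_shared <- round(cfg$frac_shared * max(n_g1, n_g2))
  if (n_shared > min(n_g1, n_g2)) {
    td_stop("configuration_error",
            "`frac_shared` implies %d shared rhythmic transcripts but the smaller rhythmic set has only %d",
            n_shared, min(n_g1, n_g2))
  }
  if (n_g1 + n_g2 - n_shared > cfg$n_transcripts) {
    td_stop("configuration_error",
            "rhythmic fractions imply more rhythmic transcripts than n_transcripts")
  }
  cfg$counts <- list(g1 = n_g1, g2 = n_g2, shared = n_shared)
  structure(cfg, class = "simulation_config")
}

# von Mises draws mapped to hours; kappa = 0 degenerates to uniform.
rvonmises_hours <- function(n, mu_hours, kappa, period = 24) {
  if (kappa <= 0) return(runif(n, 0, period))
  mu <- 2 * pi * mu_hours / period
  # Best-Fisher rejection sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta[i] <- (sign(u[3] - 0.5) * acos(f) + mu[(i - 1L) %% length(mu) + 1L]) %% (2 * pi)
      i <- i + 1L
    }
  }
  theta * period / (2 * pi)
}

#' Simulate a two-group time-of-death cohort with known rhythm ground truth
#'
#' Generates an expression matrix, subject metadata and a ground-truth
#' table. Each subject has a clock time of death drawn from the configured
#' sampler plus fixed sunrise/sunset; expression for a rhythmic transcript
#' in a given group is
#' \deqn{mesor + A \cos(2\pi (ZT - \phi)/24)
#'   [+ A_{12} \cos(2\pi (ZT - \phi_{12})/12)] + N(0, \sigma^2)}
#' and non-rhythmic transcripts have amplitude 0. Transcripts are
#' partitioned into group1-only rhythmic, group2-only rhythmic, shared, and
#' arrhythmic according to the configured fractions. Shared transcripts
#' keep identical phase across groups unless `phase_shift_hours` is set,
#' in which case group 2 peaks are shifted by that amount. Ultradian 12 h
#' components are generated but the downstream analysis always fits a
#' single 24 h sinusoid.
#'
#' @param config a [simulation_config()].
#' @return list with elements `matrix` (transcripts x subjects numeric
#'   matrix, dimnames set), `metadata` (subject table with `zt` attached)
#'   and `truth` (data.frame with one row per transcript x group:
#'   `transcript_id`, `group`, `is_rhythmic`, `amplitude`, `peak_hour`,
#'   `mesor`, `has_ultradian`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    td_stop("configuration_error",
            "`config` must be built with simulation_config()")
  }
  set.seed(config$seed)
  G <- config$n_transcripts
  n <- config$n_per_group
  transcript_ids <- sprintf("T%05d", seq_len(G))
  groups <- c("group1", "group2")
  subject_ids <- c(sprintf("G1S%02d", seq_len(n)), sprintf("G2S%02d", seq_len(n)))
  subject_group <- rep(groups, each = n)

  tod <- if (config$tod_sampler == "uniform") {
    runif(2 * n, 0, 24)
  } else {
    bin <- sample.int(6, 2 * n, replace = TRUE,
                      prob = config$tod_weights / sum(config$tod_weights))
    (bin - 1) * 4 + runif(2 * n, 0, 4)
  }
  metadata <- data.frame(subject_id = subject_ids, group = subject_group,
                         tod_clock = tod, sunrise = config$sunrise_hour,
                         sunset = config$sunset_hour,
                         stringsAsFactors = FALSE)
  metadata <- attach_zt(metadata)

  # partition transcripts: shared first, then group-only blocks
  cnt <- config$counts
  idx_shared <- seq_len(cnt$shared)
  idx_g1_only <- seq_len(cnt$g1 - cnt$shared) + cnt$shared
  idx_g2_only <- seq_len(cnt$g2 - cnt$shared) + cnt$g1
  rhythmic <- cbind(group1 = seq_len(G) %in% c(idx_shared, idx_g1_only),
                    group2 = seq_len(G) %in% c(idx_shared, idx_g2_only))

  mesor <- rnorm(G, config$mesor_dist[1], config$mesor_dist[2])
  mode_of <- sample.int(max(1L, length(config$phase_mode_hours)), G, replace = TRUE)
  phase <- rvonmises_hours(G, config$phase_mode_hours[mode_of], config$phase_kappa)
  amp_draw <- pmax(0.1, rnorm(G, config$amplitude_dist[1], config$amplitude_dist[2]))
  ultra <- runif(G) < config$ultradian_frac
  phase12 <- runif(G, 0, 12)

  amp <- cbind(group1 = ifelse(rhythmic[, 1], amp_draw, 0),
               group2 = ifelse(rhythmic[, 2], amp_draw, 0))
  peak <- cbind(group1 = phase,
                group2 = (phase + config$phase_shift_hours) %% 24)

  zt <- metadata$zt
  Y <- matrix(0, G, 2 * n, dimnames = list(transcript_ids, subject_ids))
  for (k in 1:2) {
    cols <- which(subject_group == groups[k])
    signal <- mesor +
      amp[, k] * cos(2 * pi * outer(-peak[, k], zt[cols], "+") / config$period_hours)
    if (any(ultra)) {
      signal[ultra, ] <- signal[ultra, , drop = FALSE] +
        config$ultradian_amp *
          cos(2 * pi * outer(-phase12[ultra], zt[cols], "+") / 12)
    }
    Y[, cols] <- signal
  }
  if (config$noise_sd > 0) {
    Y <- Y + matrix(rnorm(length(Y), 0, config$noise_sd), nrow(Y))
  }

  truth <- data.frame(
    transcript_id = rep(transcript_ids, times = 2),
    group = rep(groups, each = G),
    is_rhythmic = c(rhythmic[, 1], rhythmic[, 2]),
    amplitude = c(amp[, 1], amp[, 2]),
    peak_hour = c(ifelse(rhythmic[, 1], peak[, 1], NA_real_),
                  ifelse(rhythmic[, 2], peak[, 2], NA_real_)),
    mesor = rep(mesor, times = 2),
    has_ultradian = rep(ultra, times = 2),
    stringsAsFactors = FALSE
  )
  list(matrix = Y, metadata = metadata, truth = truth, config = config)
}

#' Write a simulated cohort as TSV fixture files
#'
#' Writes `expression.tsv` (first column `transcript_id`, one column per
#' subject), `metadata.tsv` (`subject_id`, `group`, `tod_clock`, `sunrise`,
#' `sunset`) and `truth.tsv`. Values round-trip losslessly through
#' [read_expression()] / [read_metadata()]; writing the same dataset twice
#' produces byte-identical files.
#'
#' @param dataset result of [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  if (nrow(dataset$matrix) == 0) {
    td_stop("io_error", "refusing to write an expression matrix with zero rows")
  }
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    td_stop("io_error", "cannot create directory %s", directory)
  }
  paths <- c(expression = file.path(directory, "expression.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_expression(dataset$matrix, paths[["expression"]])
  meta <- dataset$metadata[, c("subject_id", "group", "tod_clock",
                               "sunrise", "sunset")]
  write_tsv(meta, paths[["metadata"]])
  write_tsv(dataset$truth, paths[["truth"]])
  invisible(paths)
}
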