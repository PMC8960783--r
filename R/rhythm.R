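#' Analysis configuration for permutation-based rhythmicity tests
#'
#' @param n_perm number of TOD-randomized datasets for the null
#'   distributions (default 1000).
#' @param alpha nominal significance threshold (default 0.05).
#' @param seed integer RNG seed; per-operation permutation streams are
#'   derived from it so stages reproduce independently.
#' @param null_mode `"per_transcript"` compares each transcript's observed
#'   R-squared to its own null distribution; `"pooled"` pools the null
#'   R-squared values of all transcripts into one distribution.
#' @param mtc multiple-testing correction for rhythm calls: `"none"`
#'   (nominal p < alpha, the default) or `"BH"` (Benjamini-Hochberg, for a
#'   corrected-p foreground).
#' @return a validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_perm = 1000, alpha = 0.05, seed = 1L,
                            null_mode = c("per_transcript", "pooled"),
                            mtc = c("none", "BH")) {
  null_mode <- match.arg(null_mode)
  mtc <- match.arg(mtc)
  if (!is.numeric(n_perm) || n_perm < 1) {
    td_stop("configuration_error", "`n_perm` must be >= 1")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    td_stop("configuration_error", "`alpha` must lie in (0,1)")
  }
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), null_mode = null_mode, mtc = mtc),
            class = "analysis_config")
}

align_zt <- function(matrix, zt) {
  if (length(zt) != ncol(matrix)) {
    td_stop("alignment_error", "zt has %d entries but matrix has %d subjects",
            length(zt), ncol(matrix))
  }
  invisible(NULL)
}

#' Empirical rhythmicity p-values from TOD-randomized datasets
#'
#' For each transcript the observed cosinor R-squared is compared to a
#' null distribution obtained by shuffling the ZT labels across subjects
#' and refitting. One shuffle per permutation is applied to all
#' transcripts (dataset-level randomization), preserving cross-transcript
#' correlation. The empirical p-value is
#' \eqn{p = (1 + \#\{b : R^2_{null}(b) \ge R^2_{obs}\}) / (B + 1)}, which
#' can never be exactly zero. Under `null_mode = "pooled"` the null
#' R-squared values of all transcripts form a single reference
#' distribution.
#'
#' @param matrix numeric transcripts x subjects matrix with dimnames.
#' @param zt Zeitgeber time per subject, in matrix column order.
#' @param config an [analysis_config()].
#' @param period_hours fixed rhythm period, default 24.
#' @param exhaustive if `TRUE`, enumerate all `n!` distinct shuffles of the
#'   ZT vector instead of sampling (only for small cohorts); the p-value is
#'   then the exact fraction of shuffles (identity included) whose null
#'   R-squared reaches the observed one.
#' @return data.frame with columns `transcript_id`, `r2`, `p_emp`,
#'   `p_adj` (BH-adjusted, only when `config$mtc == "BH"`), `is_rhythmic`,
#'   plus the fit columns `mesor`, `amplitude`, `peak_hour`.
#' @export
empirical_rhythm_p <- function(matrix, zt, config = analysis_config(),
                               period_hours = 24, exhaustive = FALSE) {
  align_zt(matrix, zt)
  fit <- harmonic_fit_rows(matrix, zt, period_hours)
  sst <- rowSums((matrix - rowMeans(matrix))^2)
  obs <- fit$r2

  if (exhaustive) {
    perms <- all_permutations(length(zt))
    null_r2 <- vapply(seq_len(nrow(perms)), function(b) {
      harmonic_r2_rows(matrix, zt[perms[b, ]], period_hours, sst = sst)
    }, numeric(nrow(matrix)))
    null_r2 <- matrix(null_r2, nrow = nrow(matrix))
    p_emp <- rowMeans(null_r2 >= obs - 1e-12)
  } else {
    set.seed(config$seed + 101L)
    B <- config$n_perm
    exceed <- numeric(nrow(matrix))
    pooled <- if (config$null_mode == "pooled") numeric(0)
    for (b in seq_len(B)) {
      r2b <- harmonic_r2_rows(matrix, sample(zt), period_hours, sst = sst)
      if (config$null_mode == "per_transcript") {
        exceed <- exceed + (r2b >= obs)
      } else {
        pooled <- c(pooled, r2b)
      }
    }
    p_emp <- if (config$null_mode == "per_transcript") {
      (1 + exceed) / (B + 1)
    } else {
      (1 + vapply(obs, function(o) sum(pooled >= o), numeric(1))) /
        (length(pooled) + 1)
    }
  }

  out <- data.frame(transcript_id = rownames(matrix), r2 = unname(obs),
                    p_emp = unname(p_emp), stringsAsFactors = FALSE)
  if (config$mtc == "BH") {
    out$p_adj <- stats::p.adjust(out$p_emp, method = "BH")
    out$is_rhythmic <- out$p_adj < config$alpha
  } else {
    out$is_rhythmic <- out$p_emp < config$alpha
  }
  out$mesor <- unname(fit$mesor)
  out$amplitude <- unname(fit$amplitude)
  out$peak_hour <- unname(fit$peak_hour)
  out
}

#' Differential rhythmicity between two groups by a delta-R-squared
#' permutation test
#'
#' The observed statistic per transcript is the difference in cosinor
#' R-squared between groups, in both directions: `delta_loss = r2_g1 -
#' r2_g2` (rhythmicity lost in group 2 relative to the reference group 1)
#' and `delta_gain = -delta_loss`. The null distribution is built by
#' shuffling each group's ZT vector independently at every permutation,
#' refitting both groups and recomputing the difference;
#' \eqn{p_{loss} = (1 + \#\{\Delta_{null} \ge \Delta_{obs}\})/(B+1)} and
#' analogously for the gain direction.
#'
#' @param matrix_g1,matrix_g2 expression matrices for the two groups over
#'   the same transcripts (rownames must agree).
#' @param zt_g1,zt_g2 ZT per subject for each matrix.
#' @param config an [analysis_config()].
#' @param period_hours fixed rhythm period, default 24.
#' @param exhaustive if `TRUE`, enumerate all pairs of distinct shuffles of
#'   the two ZT vectors (small cohorts only) and report exact p-values.
#' @return data.frame with columns `transcript_id`, `r2_g1`, `r2_g2`,
#'   `delta_loss`, `p_loss`, `delta_gain`, `p_gain`.
#' @export
delta_r2_test <- function(matrix_g1, matrix_g2, zt_g1, zt_g2,
                          config = analysis_config(), period_hours = 24,
                          exhaustive = FALSE) {
  if (!identical(rownames(matrix_g1), rownames(matrix_g2))) {
    diff_ids <- c(setdiff(rownames(matrix_g1), rownames(matrix_g2)),
                  setdiff(rownames(matrix_g2), rownames(matrix_g1)))
    td_stop("alignment_error", "transcript sets differ between groups: %s",
            paste(utils::head(diff_ids, 10), collapse = ", "))
  }
  align_zt(matrix_g1, zt_g1)
  align_zt(matrix_g2, zt_g2)
  sst1 <- rowSums((matrix_g1 - rowMeans(matrix_g1))^2)
  sst2 <- rowSums((matrix_g2 - rowMeans(matrix_g2))^2)
  r2_g1 <- harmonic_r2_rows(matrix_g1, zt_g1, period_hours, sst = sst1)
  r2_g2 <- harmonic_r2_rows(matrix_g2, zt_g2, period_hours, sst = sst2)
  delta_loss <- r2_g1 - r2_g2

  if (exhaustive) {
    p1 <- all_permutations(length(zt_g1))
    p2 <- all_permutations(length(zt_g2))
    n_loss <- numeric(nrow(matrix_g1))
    n_gain <- numeric(nrow(matrix_g1))
    for (i in seq_len(nrow(p1))) {
      r2b1 <- harmonic_r2_rows(matrix_g1, zt_g1[p1[i, ]], period_hours, sst = sst1)
      for (j in seq_len(nrow(p2))) {
        r2b2 <- harmonic_r2_rows(matrix_g2, zt_g2[p2[j, ]], period_hours, sst = sst2)
        d <- r2b1 - r2b2
        n_loss <- n_loss + (d >= delta_loss - 1e-12)
        n_gain <- n_gain + (-d >= -delta_loss - 1e-12)
      }
    }
    total <- nrow(p1) * nrow(p2)
    p_loss <- n_loss / total
    p_gain <- n_gain / total
  } else {
    set.seed(config$seed + 202L)
    B <- config$n_perm
    n_loss <- numeric(nrow(matrix_g1))
    n_gain <- numeric(nrow(matrix_g1))
    for (b in seq_len(B)) {
      d <- harmonic_r2_rows(matrix_g1, sample(zt_g1), period_hours, sst = sst1) -
        harmonic_r2_rows(matrix_g2, sample(zt_g2), period_hours, sst = sst2)
      n_loss <- n_loss + (d >= delta_loss)
      n_gain <- n_gain + (-d >= -delta_loss)
    }
    p_loss <- (1 + n_loss) / (B + 1)
    p_gain <- (1 + n_gain) / (B + 1)
  }

  data.frame(transcript_id = rownames(matrix_g1),
             r2_g1 = unname(r2_g1), r2_g2 = unname(r2_g2),
             delta_loss = unname(delta_loss), p_loss = unname(p_loss),
             delta_gain = unname(-delta_loss), p_gain = unname(p_gain),
             stringsAsFactors = FALSE)
}

#' Classify a transcript's change in rhythmicity between groups
#'
#' Applies the two-criterion rule: a transcript is *less rhythmic in group
#' 2* iff it is significantly rhythmic in group 1 (`p_emp < alpha`) and its
#' loss of R-squared is significant (`p_loss < alpha`); it is *more
#' rhythmic in group 2* iff it is significantly rhythmic in group 2 and the
#' gain is significant. In the measure-zero case where both rules fire
#' (possible only at near-equal R-squared), the call is resolved to
#' `"unchanged"`, since the two definitions are mutually exclusive in
#' intent.
#'
#' @param res_g1,res_g2 one-transcript rows (or aligned data.frames) from
#'   [empirical_rhythm_p()] for each group.
#' @param diff matching row(s) from [delta_r2_test()].
#' @param alpha significance threshold (default 0.05).
#' @return character vector of categories: `"less_rhythmic_in_g2"`,
#'   `"more_rhythmic_in_g2"` or `"unchanged"`.
#' @export
classify_rhythm_change <- function(res_g1, res_g2, diff, alpha = 0.05) {
  if (!identical(res_g1$transcript_id, res_g2$transcript_id) ||
      !identical(res_g1$transcript_id, diff$transcript_id)) {
    td_stop("alignment_error",
            "transcript ids differ between rhythmicity and delta-R2 results")
  }
  less <- res_g1$p_emp < alpha & diff$p_loss < alpha
  more <- res_g2$p_emp < alpha & diff$p_gain < alpha
  out <- rep("unchanged", length(less))
  out[less & !more] <- "less_rhythmic_in_g2"
  out[more & !less] <- "more_rhythmic_in_g2"
  out
}

#' Phase, amplitude and mesor differences for transcripts rhythmic in both
#' groups
#'
#' Restricted to transcripts significantly rhythmic in both groups, this
#' compares the fitted rhythm parameters between groups. The phase
#' difference is the minimal circular difference of peak hours, signed, in
#' \eqn{(-12, 12]} (group 2 minus group 1); amplitude and mesor ("base")
#' differences are plain subtractions. P-values come from a group-label
#' permutation: subjects are reassigned to pseudo-groups of the original
#' sizes, both groups refit, and the observed absolute difference compared
#' to the null.
#'
#' @param matrix_g1,matrix_g2 expression matrices (same transcripts).
#' @param zt_g1,zt_g2 ZT per subject for each matrix.
#' @param rhythmic_both character vector of transcript ids rhythmic in
#'   both groups.
#' @param config an [analysis_config()].
#' @param period_hours fixed rhythm period, default 24.
#' @return data.frame with columns `transcript_id`, `phase_diff`,
#'   `amp_diff`, `base_diff`, `p_phase`, `p_amp`, `p_base`.
#' @export
compare_phase_amp_base <- function(matrix_g1, matrix_g2, zt_g1, zt_g2,
                                   rhythmic_both, config = analysis_config(),
                                   period_hours = 24) {
  missing_ids <- setdiff(rhythmic_both,
                         intersect(rownames(matrix_g1), rownames(matrix_g2)))
  if (length(missing_ids)) {
    td_stop("membership_error",
            "transcripts not present in both groups: %s",
            paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  if (length(rhythmic_both) == 0) {
    return(data.frame(transcript_id = character(0), phase_diff = numeric(0),
                      amp_diff = numeric(0), base_diff = numeric(0),
                      p_phase = numeric(0), p_amp = numeric(0),
                      p_base = numeric(0), stringsAsFactors = FALSE))
  }
  m1 <- matrix_g1[rhythmic_both, , drop = FALSE]
  m2 <- matrix_g2[rhythmic_both, , drop = FALSE]
  f1 <- harmonic_fit_rows(m1, zt_g1, period_hours)
  f2 <- harmonic_fit_rows(m2, zt_g2, period_hours)
  obs_phase <- circ_diff_hours(f2$peak_hour - f1$peak_hour, period_hours)
  obs_amp <- f2$amplitude - f1$amplitude
  obs_base <- f2$mesor - f1$mesor

  pooled <- cbind(m1, m2)
  zt_pool <- c(zt_g1, zt_g2)
  n1 <- ncol(m1)
  set.seed(config$seed + 303L)
  B <- config$n_perm
  ex_phase <- ex_amp <- ex_base <- numeric(length(rhythmic_both))
  for (b in seq_len(B)) {
    idx <- sample.int(ncol(pooled))
    i1 <- idx[seq_len(n1)]
    i2 <- idx[-seq_len(n1)]
    g1b <- harmonic_fit_rows(pooled[, i1, drop = FALSE], zt_pool[i1], period_hours)
    g2b <- harmonic_fit_rows(pooled[, i2, drop = FALSE], zt_pool[i2], period_hours)
    ex_phase <- ex_phase +
      (abs(circ_diff_hours(g2b$peak_hour - g1b$peak_hour, period_hours)) >=
         abs(obs_phase))
    ex_amp <- ex_amp + (abs(g2b$amplitude - g1b$amplitude) >= abs(obs_amp))
    ex_base <- ex_base + (abs(g2b$mesor - g1b$mesor) >= abs(obs_base))
  }
  data.frame(transcript_id = rhythmic_both,
             phase_diff = unname(obs_phase), amp_diff = unname(obs_amp),
             base_diff = unname(obs_base),
             p_phase = unname((1 + ex_phase) / (B + 1)),
             p_amp = unname((1 + ex_amp) / (B + 1)),
             p_base = unname((1 + ex_base) / (B + 1)),
             stringsAsFactors = FALSE)
}
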