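# Fixed-period cosinor fitting by closed-form harmonic regression.
#
# The sinusoid y = M + A*cos(2*pi*(t - phi)/T) is linear in (M, b1, b2)
# after the reparameterization b1 = A*cos(2*pi*phi/T), b2 = A*sin(2*pi*phi/T),
# so the least-squares solution is exact and deterministic; no iterative
# optimizer is needed for a fixed period.

harmonic_design <- function(times, period_hours = 24) {
  w <- 2 * pi * times / period_hours
  cbind(intercept = 1, c1 = cos(w), s1 = sin(w))
}

# Core vectorized fit: Y is transcripts x subjects, times length ncol(Y).
# Returns mesor, amplitude, peak_hour, r2 for every row in one pass.
harmonic_fit_rows <- function(Y, times, period_hours = 24) {
  X <- harmonic_design(times, period_hours)
  XtX <- crossprod(X)
  if (ncol(Y) < 4 || length(unique(round(times %% period_hours, 10))) < 3) {
    td_stop("rank_deficiency_error",
            "cosinor fit needs >= 4 observations at >= 3 distinct times")
  }
  B <- Y %*% X %*% solve(XtX)              # G x 3 coefficients
  fitted <- tcrossprod(B, X)               # G x n
  sse <- rowSums((Y - fitted)^2)
  sst <- rowSums((Y - rowMeans(Y))^2)
  degenerate <- sst <= 0
  r2 <- numeric(nrow(Y))
  r2[!degenerate] <- pmin(1, pmax(0, 1 - sse[!degenerate] / sst[!degenerate]))
  amplitude <- sqrt(B[, 2]^2 + B[, 3]^2)
  peak_hour <- (atan2(B[, 3], B[, 2]) * period_hours / (2 * pi)) %% period_hours
  amplitude[degenerate] <- 0
  peak_hour[degenerate] <- 0
  list(mesor = B[, 1], amplitude = amplitude, peak_hour = peak_hour,
       r2 = r2, degenerate = degenerate)
}

# R-squared only, for permutation loops (skips amplitude/phase work).
harmonic_r2_rows <- function(Y, times, period_hours = 24, sst = NULL) {
  X <- harmonic_design(times, period_hours)
  B <- Y %*% X %*% solve(crossprod(X))
  sse <- rowSums((Y - tcrossprod(B, X))^2)
  if (is.null(sst)) sst <- rowSums((Y - rowMeans(Y))^2)
  r2 <- 1 - sse / sst
  r2[sst <= 0] <- 0
  pmin(1, pmax(0, r2))
}

#' Fit a fixed-period cosinor to one transcript
#'
#' Least-squares fit of \eqn{y = M + A \cos(2\pi (t - \phi)/T)} against
#' Zeitgeber time, solved in closed form as the harmonic regression
#' \eqn{y = M + \beta_1 \cos(2\pi t/T) + \beta_2 \sin(2\pi t/T)} with
#' \eqn{A = \sqrt{\beta_1^2 + \beta_2^2}} and
#' \eqn{\phi = (T/2\pi)\,\mathrm{atan2}(\beta_2, \beta_1) \bmod T}.
#' The canonical parameterization has amplitude \eqn{A \ge 0} and peak hour
#' \eqn{\phi \in [0, T)}; the fitted curve attains its maximum at
#' \eqn{t = \phi}. Goodness of fit is \eqn{R^2 = 1 - SSE/SST} about the
#' mean of `values`.
#'
#' @param times numeric, observation times in hours (typically ZT).
#' @param values numeric expression values (log scale), same length.
#' @param period_hours fixed rhythm period, default 24.
#' @param transcript_id optional id carried into the result.
#' @return one-row data.frame with columns `transcript_id`, `mesor`,
#'   `amplitude`, `peak_hour`, `r2`, `n_obs`, `period_hours`, `degenerate`.
#'   A zero-variance input returns amplitude 0 and `r2 = 0` with
#'   `degenerate = TRUE` rather than an error.
#' @examples
#' t <- seq(0, 22, by = 2)
#' fit_cosinor(t, 5 + 3 * cos(2 * pi * (t - 8) / 24))
#' @export
fit_cosinor <- function(times, values, period_hours = 24, transcript_id = "transcript") {
  if (length(times) != length(values)) {
    td_stop("alignment_error", "times and values differ in length (%d vs %d)",
            length(times), length(values))
  }
  if (anyNA(times) || anyNA(values) || any(!is.finite(c(times, values)))) {
    td_stop("domain_error", "times and values must be finite")
  }
  f <- harmonic_fit_rows(matrix(values, nrow = 1), times, period_hours)
  data.frame(transcript_id = transcript_id, mesor = f$mesor,
             amplitude = f$amplitude, peak_hour = f$peak_hour, r2 = f$r2,
             n_obs = length(values), period_hours = period_hours,
             degenerate = f$degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fit cosinors to every transcript of an expression matrix
#'
#' Vectorized equivalent of calling [fit_cosinor()] on each row. Matrix
#' columns are aligned to metadata by subject id, so column order in the
#' file does not matter.
#'
#' @param matrix numeric matrix, transcripts x subjects, with rownames
#'   (transcript ids) and colnames (subject ids).
#' @param metadata data.frame with columns `subject_id` and `zt`
#'   (see [attach_zt()]).
#' @param period_hours fixed rhythm period, default 24.
#' @return data.frame with one row per transcript, columns as in
#'   [fit_cosinor()], transcript order preserved.
#' @export
fit_matrix <- function(matrix, metadata, period_hours = 24) {
  if (is.null(metadata$zt)) {
    td_stop("schema_error", "metadata has no `zt` column; call attach_zt() first")
  }
  unmatched <- setdiff(colnames(matrix), metadata$subject_id)
  unmatched2 <- setdiff(metadata$subject_id, colnames(matrix))
  if (length(unmatched) || length(unmatched2)) {
    td_stop("alignment_error",
            "subject ids unmatched between matrix and metadata: %s",
            paste(c(unmatched, unmatched2), collapse = ", "))
  }
  zt <- metadata$zt[match(colnames(matrix), metadata$subject_id)]
  f <- harmonic_fit_rows(matrix, zt, period_hours)
  data.frame(transcript_id = rownames(matrix), mesor = unname(f$mesor),
             amplitude = unname(f$amplitude), peak_hour = unname(f$peak_hour),
             r2 = unname(f$r2), n_obs = ncol(matrix),
             period_hours = period_hours, degenerate = unname(f$degenerate),
             stringsAsFactors = FALSE, row.names = NULL)
}
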