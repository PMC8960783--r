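# Internal helpers shared across modules.

#' Wrap a signed difference in hours onto the circle
#'
#' Minimal circular difference, mapped to the half-open interval (-12, 12].
#' Used for peak-hour comparisons where e.g. 23 h vs 1 h must give +2 h.
#'
#' @param x numeric vector of signed hour differences.
#' @param period period in hours (default 24).
#' @return numeric vector in (-period/2, period/2].
#' @keywords internal
circ_diff_hours <- function(x, period = 24) {
  half <- period / 2
  half - ((half - x) %% period)
}

#' Circular mean and resultant length of hours on a given period
#' @keywords internal
#' @noRd
circ_stats_hours <- function(hours, period = 24) {
  theta <- 2 * pi * hours / period
  c_ <- mean(cos(theta))
  s_ <- mean(sin(theta))
  mean_h <- (atan2(s_, c_) * period / (2 * pi)) %% period
  list(mean = mean_h, resultant = sqrt(c_^2 + s_^2))
}

# All permutations of 1..n as a matrix (n! rows). Guarded for small n only;
# used by the exhaustive permutation modes.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    block <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Fail with a classed error so callers/tests can match on condition class.
td_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "todrhythm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Validate that a numeric vector is finite, optionally within [lo, hi).
check_hours <- function(x, name, lo = 0, hi = 24) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    td_stop("domain_error", "`%s` must be finite numeric", name)
  }
  if (any(x < lo | x >= hi)) {
    bad <- which(x < lo | x >= hi)
    td_stop("domain_error", "`%s` outside [%g,%g) at position(s) %s",
            name, lo, hi, paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(x)
}
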