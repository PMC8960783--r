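#' Fisher's exact test for the overlap of two transcript sets
#'
#' Builds the 2x2 contingency table of membership in `set_a` and `set_b`
#' within a common background universe and tests whether the overlap is
#' larger (or smaller) than expected by chance. The p-value is the exact
#' hypergeometric-based Fisher probability for the requested sidedness.
#' The reported odds ratio is the sample (cross-product) odds ratio, with
#' Haldane's 0.5 continuity correction applied only when a cell is zero —
#' and only to the odds ratio, never to the p-value.
#'
#' @param set_a,set_b character vectors of transcript ids; must be subsets
#'   of `background`.
#' @param background character vector: the universe of expressed
#'   transcripts.
#' @param sidedness `"two_sided"` (default), `"greater"` (over-enrichment
#'   of the overlap) or `"less"`.
#' @return one-row data.frame: `n_overlap`, `n_a_only`, `n_b_only`,
#'   `n_neither`, `background_n`, `odds_ratio`, `p_value`, `sidedness`.
#' @examples
#' fisher_overlap(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
fisher_overlap <- function(set_a, set_b, background,
                           sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (length(background) == 0) {
    td_stop("membership_error", "background universe is empty")
  }
  background <- unique(background)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  outside <- c(setdiff(set_a, background), setdiff(set_b, background))
  if (length(outside)) {
    td_stop("membership_error", "ids outside the background universe: %s",
            paste(utils::head(outside, 10), collapse = ", "))
  }
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(set_a) - n11
  n21 <- length(set_b) - n11
  n22 <- length(background) - n11 - n12 - n21
  fisher_overlap_counts(n11, n12, n21, n22, sidedness)
}

#' Fisher overlap test from precomputed 2x2 counts
#'
#' Same test as [fisher_overlap()] but starting from the four cells of the
#' contingency table, for use when only published counts are available.
#'
#' @param n_overlap transcripts in both sets.
#' @param n_a_only,n_b_only transcripts in exactly one set.
#' @param n_neither background transcripts in neither set.
#' @param sidedness as in [fisher_overlap()].
#' @return one-row data.frame as in [fisher_overlap()].
#' @export
fisher_overlap_counts <- function(n_overlap, n_a_only, n_b_only, n_neither,
                                  sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  cells <- c(n_overlap, n_a_only, n_b_only, n_neither)
  if (any(cells < 0)) td_stop("membership_error", "negative cell count")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  # degenerate margins (an empty row or column) carry no information
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
  } else {
    alt <- switch(sidedness, two_sided = "two.sided", greater = "greater",
                  less = "less")
    p <- stats::fisher.test(tab, alternative = alt)$p.value
  }
  cc <- if (any(cells == 0)) 0.5 else 0
  or <- ((n_overlap + cc) * (n_neither + cc)) /
    ((n_a_only + cc) * (n_b_only + cc))
  data.frame(n_overlap = n_overlap, n_a_only = n_a_only, n_b_only = n_b_only,
             n_neither = n_neither, background_n = sum(cells),
             odds_ratio = or, p_value = min(1, p), sidedness = sidedness,
             stringsAsFactors = FALSE)
}

#' Rank-rank hypergeometric overlap of two rhythmicity rankings
#'
#' A threshold-free comparison of two p-value rankings over the same
#' transcript universe. Both lists are ranked ascending by p-value (most
#' rhythmic first; ties broken by transcript id for determinism). For each
#' grid point \eqn{(i \cdot step, j \cdot step)} the overlap between the
#' top-\eqn{i \cdot step} transcripts of list a and the top-\eqn{j \cdot
#' step} of list b is scored with a hypergeometric tail test, stored as
#' \eqn{-\log_{10} p} signed positive for over-enrichment (observed
#' overlap at or above its expectation) and negative for under-enrichment.
#'
#' @param pvals_a,pvals_b named numeric vectors of per-transcript
#'   rhythmicity p-values over the same transcript universe.
#' @param step rank stride of the grid; default `ceiling(n/100)`.
#' @return object of class `"rrho_map"`: list with `grid` (signed
#'   -log10 p matrix, rows indexed by list-a thresholds, columns by list-b
#'   thresholds), `thresholds`, `step`, `n_ranked`, and `orientation`
#'   (`"[1,1] corner = most significant in both lists"`).
#' @export
rrho <- function(pvals_a, pvals_b, step = NULL) {
  if (is.null(names(pvals_a)) || is.null(names(pvals_b))) {
    td_stop("alignment_error", "pvals_a and pvals_b must be named by transcript")
  }
  if (!setequal(names(pvals_a), names(pvals_b)) ||
      length(pvals_a) != length(pvals_b)) {
    td_stop("alignment_error",
            "pvals_a and pvals_b must cover the same transcript universe")
  }
  n <- length(pvals_a)
  if (is.null(step)) step <- ceiling(n / 100)
  step <- as.integer(step)
  if (step < 1) td_stop("configuration_error", "`step` must be >= 1")
  if (step > n) td_stop("configuration_error", "`step` (%d) exceeds n_ranked (%d)", step, n)

  rank_ids <- function(p) names(p)[order(p, names(p), method = "radix")]
  ord_a <- rank_ids(pvals_a)
  ord_b <- rank_ids(pvals_b)
  # position of each list-a-ranked transcript within list b's ranking
  pos_in_b <- match(ord_a, ord_b)

  thresholds <- seq(step, by = step, length.out = ceiling(n / step))
  thresholds[length(thresholds)] <- min(thresholds[length(thresholds)], n)
  thresholds <- unique(pmin(thresholds, n))
  nt <- length(thresholds)
  grid <- matrix(0, nt, nt, dimnames = list(thresholds, thresholds))
  # cumulative overlap counts: overlap(i,j) = #{first i of a with pos_in_b <= j}
  for (ii in seq_len(nt)) {
    i <- thresholds[ii]
    pos_top <- sort(pos_in_b[seq_len(i)])
    k <- findInterval(thresholds, pos_top)   # overlap counts for all j
    p_over <- phyper(k - 1, i, n - i, thresholds, lower.tail = FALSE)
    p_under <- phyper(k, i, n - i, thresholds, lower.tail = TRUE)
    expected <- i * thresholds / n
    grid[ii, ] <- ifelse(k >= expected, -log10(p_over), log10(p_under))
  }
  structure(list(grid = grid, thresholds = thresholds, step = step,
                 n_ranked = n,
                 orientation = "[1,1] corner = most significant in both lists"),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("RRHO map: %d x %d grid, %d transcripts, step %d\n",
              nrow(x$grid), ncol(x$grid), x$n_ranked, x$step))
  cat(sprintf("signed -log10 p range: [%.2f, %.2f]; %s\n",
              min(x$grid), max(x$grid), x$orientation))
  invisible(x)
}
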