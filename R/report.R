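#' Peak-hour distribution of rhythmic transcripts
#'
#' Histogram of fitted peak hours over a rhythmic transcript set, with the
#' circular mean and circular concentration (mean resultant length; 0 for
#' uniform phases, 1 when all peaks coincide). Postmortem cohorts often
#' show bimodal peak-hour structure with modes ~12 h apart, which this
#' summary makes visible.
#'
#' @param fits data.frame of cosinor fits from [fit_matrix()].
#' @param rhythmic_ids transcript ids to summarize (subset of `fits`).
#' @param n_bins number of equal-width bins (default 24).
#' @param convention bin the hours on `"[0,24)"` (default) or `"[-6,18)"`.
#' @return list of class `"phase_distribution"`: `bin_edges`, `counts`,
#'   `circular_mean` (hours in \eqn{[0,24)}), `circular_concentration`,
#'   `peak_hours` (named vector). An empty rhythmic set yields zero counts
#'   with a warning rather than an error.
#' @export
peak_hour_distribution <- function(fits, rhythmic_ids, n_bins = 24,
                                   convention = c("[0,24)", "[-6,18)")) {
  convention <- match.arg(convention)
  if (n_bins < 2) td_stop("configuration_error", "`n_bins` must be >= 2")
  missing_ids <- setdiff(rhythmic_ids, fits$transcript_id)
  if (length(missing_ids)) {
    td_stop("membership_error", "rhythmic ids absent from fits: %s",
            paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  lo <- if (convention == "[0,24)") 0 else -6
  edges <- seq(lo, lo + 24, length.out = n_bins + 1)
  if (length(rhythmic_ids) == 0) {
    warning("empty rhythmic set: returning an empty phase distribution")
    return(structure(list(bin_edges = edges, counts = integer(n_bins),
                          circular_mean = NA_real_,
                          circular_concentration = NA_real_,
                          peak_hours = setNames(numeric(0), character(0))),
                     class = "phase_distribution"))
  }
  ph <- fits$peak_hour[match(rhythmic_ids, fits$transcript_id)]
  ph_conv <- ((ph - lo) %% 24) + lo
  counts <- as.integer(table(cut(ph_conv, edges, right = FALSE,
                                 include.lowest = FALSE)))
  cs <- circ_stats_hours(ph)
  structure(list(bin_edges = edges, counts = counts,
                 circular_mean = cs$mean,
                 circular_concentration = cs$resultant,
                 peak_hours = setNames(ph, rhythmic_ids)),
            class = "phase_distribution")
}

#' Circular k-means clustering of peak hours
#'
#' Lloyd-style k-means on the 24 h circle: distances are minimal circular
#' differences in hours, cluster centers are circular means, and the best
#' of `n_start` seeded restarts (by within-cluster sum of squared circular
#' distances) is returned. With `k = 1` the center is the circular mean.
#'
#' @param peak_hours numeric vector of hours in \eqn{[0,24)}.
#' @param k number of clusters.
#' @param n_start random restarts (default 20).
#' @param seed RNG seed for the restarts (default 1).
#' @return list: `centers` (hours in \eqn{[0,24)}, ascending),
#'   `assignments` (cluster index per input, matching the sorted centers),
#'   `withinss` (total squared circular distance).
#' @export
detect_peak_clusters <- function(peak_hours, k, n_start = 20, seed = 1L) {
  if (k < 1) td_stop("configuration_error", "`k` must be >= 1")
  uniq <- unique(round(peak_hours %% 24, 9))
  if (length(uniq) < k) {
    td_stop("configuration_error",
            "k = %d exceeds the %d distinct peak hours", k, length(uniq))
  }
  h <- peak_hours %% 24
  n <- length(h)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(n_start)) {
    centers <- sample(uniq, k)
    for (iter in 1:100) {
      d <- abs(vapply(centers, function(c_) circ_diff_hours(h - c_), numeric(n)))
      d <- matrix(d, nrow = n)
      assign <- max.col(-d, ties.method = "first")
      new_centers <- vapply(seq_len(k), function(j) {
        pts <- h[assign == j]
        if (!length(pts)) centers[j] else circ_stats_hours(pts)$mean
      }, numeric(1))
      if (max(abs(circ_diff_hours(new_centers - centers))) < 1e-9) {
        centers <- new_centers
        break
      }
      centers <- new_centers
    }
    d <- matrix(abs(vapply(centers, function(c_) circ_diff_hours(h - c_),
                           numeric(n))), nrow = n)
    assign <- max.col(-d, ties.method = "first")
    wss <- sum(d[cbind(seq_len(n), assign)]^2)
    if (is.null(best) || wss < best$withinss - 1e-12) {
      best <- list(centers = centers, assignments = assign, withinss = wss)
    }
  }
  ord <- order(best$centers %% 24)
  list(centers = (best$centers %% 24)[ord],
       assignments = match(best$assignments, ord),
       withinss = best$withinss)
}

#' Phase-ordered heatmap specification
#'
#' Builds the report table behind a phase-ordered expression heatmap: the
#' `top_n` most rhythmic transcripts (ranked by ascending empirical
#' p-value, then descending R-squared, then transcript id) are selected,
#' each row Z-transformed (mean 0, sd 1), rows ordered by fitted peak hour
#' and columns by subject ZT. For a cross-group panel — transcripts
#' selected in one group but rendered with another group's expression —
#' pass that other group's `matrix`/`metadata` together with the selection
#' group's `fits` and `results`.
#'
#' @param matrix expression matrix to render (transcripts x subjects).
#' @param metadata subject metadata with `zt` for the rendered subjects.
#' @param fits cosinor fits of the selection group (row order source).
#' @param results rhythmicity results of the selection group
#'   ([empirical_rhythm_p()] output covering every matrix transcript).
#' @param top_n number of transcripts to keep (default 200, the
#'   conventional report size); clamped with a warning if it exceeds the
#'   transcript count.
#' @return list of class `"heatmap_spec"`: `values` (Z-scored matrix, rows
#'   in peak-hour order, columns in ZT order), `row_order`, `col_order`,
#'   `peak_hours`, `zt`, `constant_rows` (ids excluded from Z-scoring).
#' @export
phase_ordered_heatmap <- function(matrix, metadata, fits, results,
                                  top_n = 200) {
  missing_ids <- setdiff(rownames(matrix), results$transcript_id)
  if (length(missing_ids)) {
    td_stop("membership_error",
            "results lack p_emp for matrix transcripts: %s",
            paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  if (top_n > nrow(matrix)) {
    warning(sprintf("top_n = %d exceeds the %d transcripts; clamping",
                    top_n, nrow(matrix)))
    top_n <- nrow(matrix)
  }
  res <- results[match(rownames(matrix), results$transcript_id), ]
  sel <- order(res$p_emp, -res$r2, res$transcript_id)[seq_len(top_n)]
  ids <- rownames(matrix)[sel]
  peak <- fits$peak_hour[match(ids, fits$transcript_id)]
  row_ord <- order(peak, ids)
  row_order <- ids[row_ord]
  zt <- metadata$zt[match(colnames(matrix), metadata$subject_id)]
  col_ord <- order(zt)
  col_order <- colnames(matrix)[col_ord]

  sub <- matrix[row_order, col_order, drop = FALSE]
  row_sd <- apply(sub, 1, sd)
  constant <- row_sd == 0
  z <- sub
  z[!constant, ] <- (sub[!constant, , drop = FALSE] -
                       rowMeans(sub[!constant, , drop = FALSE])) /
    row_sd[!constant]
  z[constant, ] <- 0
  structure(list(values = z, row_order = row_order, col_order = col_order,
                 peak_hours = setNames(peak[row_ord], row_order),
                 zt = setNames(zt[col_ord], col_order),
                 constant_rows = row_order[constant]),
            class = "heatmap_spec")
}

#' Plot-ready table for a single-transcript rhythm scatterplot
#'
#' Returns the observed (ZT, expression) points for one transcript plus
#' its fitted sinusoid sampled every 0.1 h over the \eqn{[-6, 18)} ZT
#' axis, the conventional scale for time-of-death scatterplots.
#'
#' @param transcript_id transcript to plot.
#' @param matrix expression matrix containing it.
#' @param metadata subject metadata with `zt`.
#' @param fit the transcript's row from [fit_matrix()] / [fit_cosinor()].
#' @return list: `points` (data.frame `subject_id`, `zt`, `expression`)
#'   and `curve` (data.frame `zt`, `fitted` =
#'   `mesor + amplitude * cos(2*pi*(zt - peak_hour)/period)`).
#' @export
rhythm_scatter <- function(transcript_id, matrix, metadata, fit) {
  if (!transcript_id %in% rownames(matrix)) {
    td_stop("membership_error", "unknown transcript: %s", transcript_id)
  }
  fit_row <- fit[fit$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(fit_row) != 1) {
    td_stop("alignment_error", "fit does not contain exactly one row for %s",
            transcript_id)
  }
  zt <- metadata$zt[match(colnames(matrix), metadata$subject_id)]
  grid <- seq(-6, 18 - 0.1, by = 0.1)
  period <- fit_row$period_hours
  curve_at <- function(t) {
    fit_row$mesor +
      fit_row$amplitude * cos(2 * pi * (t - fit_row$peak_hour) / period)
  }
  list(points = data.frame(subject_id = colnames(matrix), zt = zt,
                           expression = as.numeric(matrix[transcript_id, ]),
                           stringsAsFactors = FALSE),
       curve = data.frame(zt = grid, fitted = curve_at(grid)))
}
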