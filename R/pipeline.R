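#' Run the full time-of-death rhythmicity pipeline
#'
#' Orchestrates the complete analysis on a two-group cohort: attach
#' Zeitgeber time, fit cosinors per group, compute permutation-based
#' rhythmicity p-values per group, run the delta-R-squared differential
#' rhythmicity test, classify every transcript, compare phase / amplitude
#' / mesor for transcripts rhythmic in both groups, compare the rhythmic
#' sets (Fisher's exact test and RRHO), and build the phase-ordered
#' heatmap specifications (within-group and cross-group panels). All
#' stage results are written as TSVs into `out_dir` together with a JSON
#' run manifest recording seeds, thresholds, package version and
#' transcript counts; re-running with the same inputs and manifest
#' parameters reproduces byte-identical result files.
#'
#' @param expression path to an expression TSV, or a transcripts x
#'   subjects matrix.
#' @param metadata path to a metadata TSV, or a subject data.frame.
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @param reference_group the group treated as reference ("unaffected")
#'   for the loss/gain direction naming (default `"group1"`).
#' @param group_labels the two allowed group labels.
#' @param top_n transcripts per heatmap panel (default 200).
#' @param rrho_step RRHO rank stride; default `ceiling(n/100)`.
#' @param photoperiod_scale passed to [attach_zt()].
#' @return invisibly, a list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(expression, metadata, out_dir,
                         config = analysis_config(),
                         reference_group = "group1",
                         group_labels = c("group1", "group2"),
                         top_n = 200, rrho_step = NULL,
                         photoperiod_scale = FALSE) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(metadata)) metadata <- read_metadata(metadata, group_labels)
  if (!reference_group %in% group_labels) {
    td_stop("configuration_error",
            "`reference_group` must be one of the group labels")
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    td_stop("io_error", "cannot create output directory %s", out_dir)
  }

  metadata <- attach_zt(metadata, photoperiod_scale = photoperiod_scale)
  g1 <- reference_group
  g2 <- setdiff(group_labels, reference_group)[1]
  ids_g1 <- metadata$subject_id[metadata$group == g1]
  ids_g2 <- metadata$subject_id[metadata$group == g2]
  missing_subj <- setdiff(c(ids_g1, ids_g2), colnames(expression))
  if (length(missing_subj)) {
    td_stop("alignment_error", "subjects missing from the matrix: %s",
            paste(missing_subj, collapse = ", "))
  }
  m_g1 <- expression[, ids_g1, drop = FALSE]
  m_g2 <- expression[, ids_g2, drop = FALSE]
  zt_g1 <- metadata$zt[match(ids_g1, metadata$subject_id)]
  zt_g2 <- metadata$zt[match(ids_g2, metadata$subject_id)]

  res_g1 <- empirical_rhythm_p(m_g1, zt_g1, config)
  res_g2 <- empirical_rhythm_p(m_g2, zt_g2, config)
  fits_g1 <- fit_matrix(m_g1, metadata[metadata$group == g1, ])
  fits_g2 <- fit_matrix(m_g2, metadata[metadata$group == g2, ])

  diff <- delta_r2_test(m_g1, m_g2, zt_g1, zt_g2, config)
  diff$category <- classify_rhythm_change(res_g1, res_g2, diff, config$alpha)

  rhythmic_g1 <- res_g1$transcript_id[res_g1$is_rhythmic]
  rhythmic_g2 <- res_g2$transcript_id[res_g2$is_rhythmic]
  rhythmic_both <- intersect(rhythmic_g1, rhythmic_g2)
  param_diff <- compare_phase_amp_base(m_g1, m_g2, zt_g1, zt_g2,
                                       rhythmic_both, config)

  overlap <- fisher_overlap(rhythmic_g1, rhythmic_g2,
                            rownames(expression))
  rrho_map <- rrho(setNames(res_g1$p_emp, res_g1$transcript_id),
                   setNames(res_g2$p_emp, res_g2$transcript_id),
                   step = rrho_step)

  meta_g1 <- metadata[metadata$group == g1, ]
  meta_g2 <- metadata[metadata$group == g2, ]
  n_top <- min(top_n, nrow(expression))
  heatmaps <- list(
    g1_in_g1 = phase_ordered_heatmap(m_g1, meta_g1, fits_g1, res_g1, n_top),
    g1_in_g2 = phase_ordered_heatmap(m_g2, meta_g2, fits_g1, res_g1, n_top),
    g2_in_g2 = phase_ordered_heatmap(m_g2, meta_g2, fits_g2, res_g2, n_top),
    g2_in_g1 = phase_ordered_heatmap(m_g1, meta_g1, fits_g2, res_g2, n_top)
  )

  # write stage TSVs
  write_tsv(metadata, file.path(out_dir, "metadata_zt.tsv"))
  write_fits <- function(f, name) {
    write_tsv(f[, c("transcript_id", "mesor", "amplitude", "peak_hour",
                    "r2", "n_obs", "period_hours")],
              file.path(out_dir, name))
  }
  write_fits(fits_g1, "fits_group1.tsv")
  write_fits(fits_g2, "fits_group2.tsv")
  write_tsv(res_g1[, c("transcript_id", "r2", "p_emp", "is_rhythmic")],
            file.path(out_dir, "rhythmicity_group1.tsv"))
  write_tsv(res_g2[, c("transcript_id", "r2", "p_emp", "is_rhythmic")],
            file.path(out_dir, "rhythmicity_group2.tsv"))
  write_tsv(diff, file.path(out_dir, "differential_rhythmicity.tsv"))
  write_tsv(param_diff, file.path(out_dir, "phase_amp_base_diff.tsv"))
  write_tsv(overlap, file.path(out_dir, "fisher_overlap.tsv"))
  rrho_df <- data.frame(rank_a = rownames(rrho_map$grid), rrho_map$grid,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(rrho_df, file.path(out_dir, "rrho_grid.tsv"))
  for (panel in names(heatmaps)) {
    hm <- heatmaps[[panel]]
    write_expression(hm$values,
                     file.path(out_dir, sprintf("heatmap_%s.tsv", panel)))
  }

  manifest <- list(
    package = "todrhythm",
    version = as.character(packageVersion("todrhythm")),
    seed = config$seed, n_perm = config$n_perm, alpha = config$alpha,
    null_mode = config$null_mode, mtc = config$mtc,
    reference_group = g1, group_labels = group_labels,
    photoperiod_scale = photoperiod_scale, top_n = n_top,
    n_transcripts = nrow(expression),
    n_subjects = list(group1 = length(ids_g1), group2 = length(ids_g2)),
    counts = list(
      rhythmic_group1 = length(rhythmic_g1),
      rhythmic_group2 = length(rhythmic_g2),
      rhythmic_both = length(rhythmic_both),
      less_rhythmic_in_g2 = sum(diff$category == "less_rhythmic_in_g2"),
      more_rhythmic_in_g2 = sum(diff$category == "more_rhythmic_in_g2")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(metadata = metadata, fits_g1 = fits_g1, fits_g2 = fits_g2,
                 rhythmicity_g1 = res_g1, rhythmicity_g2 = res_g2,
                 differential = diff, param_diff = param_diff,
                 overlap = overlap, rrho = rrho_map, heatmaps = heatmaps,
                 manifest = manifest))
}
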