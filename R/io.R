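# TSV readers/writers for the pipeline's canonical interfaces.
# TSV, UTF-8, '.' decimal separator throughout; fail-fast on malformed or
# missing values (no imputation is attempted).

write_tsv <- function(df, path) {
  # %.17g preserves doubles exactly through a text round-trip
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' First column `transcript_id`, one column per subject id.
#' @param matrix numeric transcripts x subjects matrix with dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(transcript_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix TSV
#'
#' Expects a header line with `transcript_id` followed by subject ids, and
#' decimal values. Duplicate transcript ids, non-numeric cells and ragged
#' rows are rejected with the offending line number. Missing values are an
#' error unless `drop_incomplete = TRUE`, in which case rows containing
#' any missing value are dropped and the count reported via `message()`.
#'
#' @param path TSV file as written by [write_expression()].
#' @param drop_incomplete drop rows with missing values instead of failing.
#' @return numeric matrix, transcripts x subjects, dimnames set; subject
#'   ids preserved in file order.
#' @export
read_expression <- function(path, drop_incomplete = FALSE) {
  if (!file.exists(path)) td_stop("io_error", "file not found: %s", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "transcript_id") {
    td_stop("parse_error",
            "expression header must start with `transcript_id` (line 1)")
  }
  n_fields <- utils::count.fields(path, sep = "\t", quote = "")
  ragged <- which(n_fields != length(header))
  if (length(ragged)) {
    td_stop("parse_error", "ragged row(s) at line(s) %s",
            paste(utils::head(ragged, 5), collapse = ", "))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  dup <- duplicated(df$transcript_id)
  if (any(dup)) {
    td_stop("parse_error", "duplicated transcript id `%s` at line %d",
            df$transcript_id[which(dup)[1]], which(dup)[1] + 1L)
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                               dimnames = list(df$transcript_id,
                                               colnames(raw))))
  non_numeric <- is.na(m) & !is.na(raw)
  if (any(non_numeric)) {
    lines <- which(rowSums(non_numeric) > 0) + 1L
    td_stop("parse_error", "non-numeric cell(s) at line(s) %s",
            paste(utils::head(lines, 5), collapse = ", "))
  }
  if (anyNA(m)) {
    bad_rows <- which(rowSums(is.na(m)) > 0)
    if (!drop_incomplete) {
      td_stop("parse_error",
              "missing/non-numeric value(s) at data line(s) %s",
              paste(utils::head(bad_rows + 1L, 5), collapse = ", "))
    }
    message(sprintf("dropping %d row(s) with missing values", length(bad_rows)))
    m <- m[-bad_rows, , drop = FALSE]
  }
  m
}

#' Read a subject metadata TSV
#'
#' Expects columns `subject_id`, `group`, `tod_clock`, `sunrise`,
#' `sunset`. Hour fields are validated against the half-open \eqn{[0,24)}
#' convention and group values against the configured labels.
#'
#' @param path metadata TSV.
#' @param group_labels allowed group labels, default
#'   `c("group1", "group2")`.
#' @return data.frame of subject records (without `zt`; see [attach_zt()]).
#' @export
read_metadata <- function(path, group_labels = c("group1", "group2")) {
  if (!file.exists(path)) td_stop("io_error", "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "tod_clock", "sunrise", "sunset")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    td_stop("schema_error", "metadata is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  bad_group <- which(!df$group %in% group_labels)
  if (length(bad_group)) {
    td_stop("validation_error",
            "unknown group label(s) `%s` at row(s) %s (allowed: %s)",
            paste(unique(df$group[bad_group]), collapse = ", "),
            paste(utils::head(bad_group, 5), collapse = ", "),
            paste(group_labels, collapse = ", "))
  }
  for (col in c("tod_clock", "sunrise", "sunset")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] >= 24)
    if (length(bad)) {
      td_stop("validation_error", "`%s` outside [0,24) at row(s) %s",
              col, paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}
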