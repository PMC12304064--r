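pairs_columns <- c("id", "test_qt_ms", "ref_qt_ms", "test_qtc_ms", "ref_qtc_ms")

#' Read a paired-study CSV
#'
#' Expects the schema written by [write_pairs_csv()] /
#' [simulate_study()]: `id, test_qt_ms, ref_qt_ms, test_qtc_ms,
#' ref_qtc_ms`. Missing columns are named in the error; non-numeric
#' cells are reported with their row number.
#'
#' @param path CSV path.
#' @param metric `"qt"` or `"qtc"`; selects which pair of columns becomes
#'   the series.
#' @return a [paired_series()].
#' @export
read_pairs_csv <- function(path, metric = c("qt", "qtc")) {
  metric <- match.arg(metric)
  if (!file.exists(path)) abort(sprintf("pairs file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(pairs_columns, names(df))
  if (length(missing)) {
    abort(sprintf("pairs CSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  num <- df
  for (col in setdiff(pairs_columns, "id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column %s, row %d",
                    df[[col]][bad[1]], col, bad[1]))
    }
    num[[col]] <- v
  }
  test_col <- paste0("test_", metric, "_ms")
  ref_col <- paste0("ref_", metric, "_ms")
  paired_series(num[[test_col]], num[[ref_col]], ids = df$id, metric = metric)
}

#' Write a paired study as CSV
#'
#' Full float precision (17 significant digits) so a write/read
#' round trip reproduces the values exactly.
#'
#' @param study data frame with columns `id, test_qt_ms, ref_qt_ms,
#'   test_qtc_ms, ref_qtc_ms` (as returned by [simulate_study()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pairs_csv <- function(study, path) {
  missing <- setdiff(pairs_columns, names(study))
  if (length(missing)) {
    abort(sprintf("study is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  out <- study[pairs_columns]
  for (col in setdiff(pairs_columns, "id")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an agreement report as JSON
#'
#' Field-for-field mirror of the `agreement_report`, at full float
#' precision.
#'
#' @param report an [agreement_report()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  obj <- unclass(report)
  obj$grade_counts <- as.list(obj$grade_counts)
  obj$grade_pct <- as.list(obj$grade_pct)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
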