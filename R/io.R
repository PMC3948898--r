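# TSV/JSON readers and writers for the pipeline's table dialects.
# Undefined metrics serialize as "NA" in TSV and null in JSON; percentages
# are written with 3 decimals.

#' Read a TSV table against a required-column schema
#'
#' Tab-separated, header row required. Missing required columns raise an
#' error naming them; extra columns are tolerated with a warning. Columns
#' listed in `numeric_cols` are coerced, and an unparsable cell raises an
#' error with its row number.
#'
#' @param path File path.
#' @param required_cols Character vector of required column names.
#' @param numeric_cols Character vector of columns that must parse as
#'   numeric (`NA` allowed for empty cells).
#' @return Data frame.
#' @export
read_table <- function(path, required_cols = character(0),
                       numeric_cols = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(df), union(required_cols, numeric_cols))
  if (length(required_cols) > 0 && length(extra) > 0) {
    warning(sprintf("extra column(s) ignored by schema: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0) {
      stop(sprintf("column '%s': unparsable value at row %d", col, bad[1]),
           call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

# round percentage columns to 3 decimals for rendering
.fmt_report <- function(df) {
  for (col in intersect(c("acc", "ppv", "fpr"), names(df))) {
    df[[col]] <- round(df[[col]], 3)
  }
  df
}

#' Write a result table as TSV or JSON
#'
#' TSV output is tab-separated with a header, `NA` for undefined values and
#' deterministic column order; JSON output maps undefined values to null.
#' Percentage columns (`acc`, `ppv`, `fpr`) are rounded to 3 decimals.
#'
#' @param results Data frame.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  results <- .fmt_report(results)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write ROC curve points as two-column TSV
#'
#' @param roc A [roc_curve()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
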