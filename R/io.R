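#' Read a rated text corpus
#'
#' Reads a corpus as JSONL (one JSON object per line with at least `id` and
#' `text`, typically also `rating`, optionally group/demographic fields) or
#' as CSV with the same columns. UTF-8 only.
#'
#' @param path File path; format inferred from the extension
#'   (`.jsonl`/`.json` vs `.csv`) unless given.
#' @param format `"jsonl"`, `"csv"`, or `"auto"`.
#' @return Data frame with one row per document; `id` coerced to character.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  if (!all(c("id", "text") %in% names(df)))
    stop("corpus must have `id` and `text` columns", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate document ids in corpus", call. = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Write a feature table
#'
#' One row per document, the 131 feature columns plus any id/metadata
#' columns; missing values are written as empty cells, never 0.
#'
#' @param table Data frame (e.g. from [gen_rated_corpus()] or batteries
#'   bound row-wise).
#' @param path Output CSV path.
#' @export
write_features <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read parcel time series with a network-label sidecar
#'
#' @param ts_path CSV/TSV of parcels x timepoints (no header row of names
#'   required; rows are parcels).
#' @param labels_path CSV with columns `parcel` and `network`.
#' @return List with `ts` (matrix) and `labels` (character per parcel).
#' @export
read_timeseries <- function(ts_path, labels_path) {
  sep <- if (grepl("\\.tsv$", ts_path, ignore.case = TRUE)) "\t" else ","
  ts <- as.matrix(utils::read.table(ts_path, sep = sep, header = FALSE))
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("parcel", "network") %in% names(lab)))
    stop("label sidecar needs `parcel` and `network` columns", call. = FALSE)
  if (nrow(lab) != nrow(ts))
    stop("label sidecar rows (", nrow(lab), ") do not match parcels (",
         nrow(ts), ")", call. = FALSE)
  list(ts = ts, labels = lab$network[order(lab$parcel)])
}
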