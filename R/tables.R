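# Tabular report writing (CSV/JSON).

#' Write a homogeneous record table to CSV or JSON
#'
#' @param records a data.frame, or a list of identically-named lists.
#' @param path output path.
#' @param format "csv" or "json"; defaults from the file extension.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path,
                        format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "csv"
  }
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (!length(records)) {
      df <- data.frame()
    } else {
      nm <- names(records[[1L]])
      same <- vapply(records, function(r) identical(names(r), nm), logical(1L))
      if (is.null(nm) || !all(same))
        stop("records are heterogeneous: all rows must share field names")
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  } else {
    stop("records must be a data.frame or a list of named lists")
  }
  if (format == "csv") {
    utils::write.csv(format_numeric_df(df), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# >= 6 significant digits in CSV output without scientific-notation surprises
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 8)
  }
  df
}

#' Read back a table written by [write_table]
#'
#' @param path CSV or JSON path.
#' @return a data.frame.
#' @export
read_table_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
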