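# Result serialization: lossless JSON (full R serialization via jsonlite)
# and a flat key/type/value CSV for spreadsheet consumption.  Both formats
# round-trip every scalar field and index set of the result objects.

#' Write an analysis result to disk
#'
#' Works for any of the package's result objects (`controllability_result`,
#' `bounds_result`, `ssc_report`, ...).  JSON uses a lossless serialization
#' of the full object; CSV writes one row per field with a type column so
#' that [read_report()] can restore integer index sets exactly.
#'
#' @param result a result object (a classed list of atomic fields).
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(jsonlite::serializeJSON(result, digits = NA), path)
  } else {
    fields <- unclass(result)
    fields <- fields[!vapply(fields, is.null, logical(1))]
    rows <- data.frame(
      key = c("__class__", names(fields)),
      type = c("character",
               vapply(fields, function(x) class(x)[1], character(1))),
      value = c(paste(class(result), collapse = ";"),
                vapply(fields, function(x) {
                  s <- if (is.double(x)) sprintf("%.17g", x) else as.character(x)
                  paste(s, collapse = ";")
                }, character(1))),
      names_ = c("", vapply(fields, function(x)
        paste(names(x), collapse = ";"), character(1))),
      stringsAsFactors = FALSE
    )
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a result written by [write_report()]
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return the restored result object.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json")
    return(jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n")))
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  cls <- strsplit(rows$value[rows$key == "__class__"], ";")[[1]]
  rows <- rows[rows$key != "__class__", , drop = FALSE]
  out <- vector("list", nrow(rows))
  names(out) <- rows$key
  for (i in seq_len(nrow(rows))) {
    vals <- if (rows$value[i] == "") character(0)
            else strsplit(rows$value[i], ";")[[1]]
    x <- switch(rows$type[i],
                integer = as.integer(vals),
                numeric = as.numeric(vals),
                logical = as.logical(vals),
                vals)
    if (nzchar(rows$names_[i]))
      names(x) <- strsplit(rows$names_[i], ";")[[1]]
    out[[i]] <- x
  }
  structure(out, class = cls)
}
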