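# Result tables: one row per (subject, condition, channel) evaluation.

.RESULT_SCHEMA <- c("subject", "condition", "channel", "roi", "r", "p",
                    "model_tag")

#' Write evaluation records as a deterministic TSV
#'
#' Records must share the schema (subject, condition, channel, roi, r, p,
#' model_tag); rows are sorted by subject, condition, channel.
#'
#' @param rows a data.frame, or list of single-row records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.RESULT_SCHEMA)), .RESULT_SCHEMA))
  } else {
    schemas <- lapply(rows, function(r) sort(names(r)))
    if (length(unique(vapply(schemas, paste, "", collapse = ","))) != 1L)
      stop("records have heterogeneous schemas")
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  if (nrow(df) && !all(.RESULT_SCHEMA %in% names(df)))
    stop("records must carry fields: ", paste(.RESULT_SCHEMA, collapse = ", "))
  if (nrow(df)) {
    df <- df[.RESULT_SCHEMA]
    df <- df[order(df$subject, df$condition, df$channel), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results TSV written by \code{writeResultsTable}
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readResultsTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(subject = "character",
                                   condition = "character",
                                   channel = "character", roi = "character",
                                   r = "numeric", p = "numeric",
                                   model_tag = "character"))
}
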