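# Praat TextGrid reading/writing, plus a delimited fallback.

#' Read a Praat TextGrid (long or short form) or a delimited fallback table
#'
#' Interval tiers are read as-is; point tiers become zero-length intervals.
#' The fallback format is a tab- or comma-separated table with columns
#' \code{tier}, \code{start}, \code{end}, \code{label}.
#'
#' @param path file path.
#' @return an \linkS4class{AnnotationTrack}.
#' @export
readTextGrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty annotation file: ", path)
  if (grepl("ooTextFile", lines[1], fixed = TRUE) ||
      any(grepl("\"TextGrid\"|= \"TextGrid\"", lines[1:min(3, length(lines))]))) {
    .parseTextGrid(lines, path)
  } else {
    .parseAnnotationTable(path)
  }
}

.tgNum <- function(line, lineno) {
  m <- regmatches(line, regexpr("-?[0-9]+(\\.[0-9]+)?([eE]-?[0-9]+)?", line))
  if (!length(m)) stop(sprintf("TextGrid parse error at line %d: expected a number in '%s'",
                               lineno, trimws(line)))
  as.numeric(m[[1]])
}

.tgStr <- function(line) {
  m <- regmatches(line, regexpr("\"[^\"]*\"", line))
  if (!length(m)) return(NA_character_)
  gsub("^\"|\"$", "", m[[1]])
}

.parseTextGrid <- function(lines, path) {
  # Unified long/short-form parser: walk the token stream of quoted strings
  # and numbers that follows the global xmin/xmax/size preamble.
  nl <- length(lines)
  i <- 1L
  # skip header (two lines + optional blank), find global xmin
  while (i <= nl && !grepl("xmin|^-?[0-9]", trimws(lines[i])) ) i <- i + 1L
  if (i > nl) stop("TextGrid parse error at line ", nl, ": no global xmin found")
  i <- i + 2L # skip global xmin, xmax
  # tiers flag line ("tiers? <exists>" or "<exists>") then size
  while (i <= nl && !grepl("size|^[0-9]+$", trimws(lines[i]))) i <- i + 1L
  if (i > nl) stop("TextGrid parse error: tier count not found")
  nTiers <- as.integer(.tgNum(lines[i], i)); i <- i + 1L
  tiers <- list()
  for (t in seq_len(nTiers)) {
    # find tier class
    while (i <= nl && !grepl("IntervalTier|TextTier", lines[i])) i <- i + 1L
    if (i > nl) stop("TextGrid parse error at line ", nl, ": tier ", t, " class not found")
    klass <- if (grepl("IntervalTier", lines[i])) "interval" else "point"
    i <- i + 1L
    # next quoted string is the tier name
    while (i <= nl && is.na(.tgStr(lines[i]))) i <- i + 1L
    nm <- .tgStr(lines[i]); i <- i + 1L
    i <- i + 2L # tier xmin, xmax
    while (i <= nl && !grepl("size|intervals:|points:|^[0-9]+$", trimws(lines[i]))) i <- i + 1L
    nInt <- as.integer(.tgNum(lines[i], i)); i <- i + 1L
    start <- numeric(nInt); end <- numeric(nInt); label <- character(nInt)
    for (k in seq_len(nInt)) {
      if (klass == "interval") {
        while (i <= nl && !grepl("xmin|^-?[0-9]", trimws(lines[i]))) i <- i + 1L
        if (i + 2L > nl) stop("TextGrid parse error at line ", nl,
                              ": truncated interval in tier '", nm, "'")
        start[k] <- .tgNum(lines[i], i)
        end[k] <- .tgNum(lines[i + 1L], i + 1L)
        label[k] <- .tgStr(lines[i + 2L])
        i <- i + 3L
      } else {
        while (i <= nl && !grepl("number|^-?[0-9]", trimws(lines[i]))) i <- i + 1L
        if (i + 1L > nl) stop("TextGrid parse error at line ", nl,
                              ": truncated point in tier '", nm, "'")
        start[k] <- end[k] <- .tgNum(lines[i], i)
        label[k] <- .tgStr(lines[i + 1L])
        i <- i + 2L
      }
    }
    df <- data.frame(start = start, end = end, label = label,
                     stringsAsFactors = FALSE)
    tiers[[nm]] <- df
  }
  tryCatch(AnnotationTrack(tiers),
           error = function(e) stop("invalid TextGrid '", path, "': ",
                                    conditionMessage(e)))
}

.parseAnnotationTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("tier", "start", "end", "label")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns tier, start, end, label")
  tiers <- split(df[c("start", "end", "label")], df$tier)
  AnnotationTrack(tiers)
}

#' Write an AnnotationTrack as a long-form Praat TextGrid
#'
#' Zero-length intervals are written as point tiers.
#'
#' @param annot an \linkS4class{AnnotationTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTextGrid <- function(annot, path) {
  tl <- tiers(annot)
  xmax <- max(c(0, unlist(lapply(tl, function(t) t$end))))
  out <- c("File type = \"ooTextFile\"",
           "Object class = \"TextGrid\"",
           "",
           "xmin = 0",
           sprintf("xmax = %.10g", xmax),
           "tiers? <exists>",
           sprintf("size = %d", length(tl)),
           "item []:")
  for (t in seq_along(tl)) {
    tier <- tl[[t]]
    isPoint <- nrow(tier) > 0 && all(tier$start == tier$end)
    out <- c(out, sprintf("    item [%d]:", t),
             sprintf("        class = \"%s\"",
                     if (isPoint) "TextTier" else "IntervalTier"),
             sprintf("        name = \"%s\"", names(tl)[t]),
             "        xmin = 0",
             sprintf("        xmax = %.10g", xmax))
    if (isPoint) {
      out <- c(out, sprintf("        points: size = %d", nrow(tier)))
      for (k in seq_len(nrow(tier)))
        out <- c(out, sprintf("        points [%d]:", k),
                 sprintf("            number = %.10g", tier$start[k]),
                 sprintf("            mark = \"%s\"", tier$label[k]))
    } else {
      out <- c(out, sprintf("        intervals: size = %d", nrow(tier)))
      for (k in seq_len(nrow(tier)))
        out <- c(out, sprintf("        intervals [%d]:", k),
                 sprintf("            xmin = %.10g", tier$start[k]),
                 sprintf("            xmax = %.10g", tier$end[k]),
                 sprintf("            text = \"%s\"", tier$label[k]))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
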