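#' Read a delimited feature table
#'
#' Delimiter is auto-detected from the header line (tab wins over
#' comma) unless given. Required columns: `id`, `mz`, `rt`, `area`;
#' `sample` is optional. Errors name the missing column or the first
#' malformed row.
#'
#' @param path Path to a UTF-8 CSV/TSV file with a header.
#' @param sep Optional delimiter override.
#' @return Data frame of validated features.
#' @export
read_feature_table <- function(path, sep = NULL) {
  tbl <- .read_delim(path, sep)
  req <- c("id", "mz", "rt", "area")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) {
    stop("feature table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("mz", "rt", "area")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) & !is.na(tbl[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at row ", bad[1], " of ", path,
           call. = FALSE)
    }
    tbl[[col]] <- v
  }
  tbl$id <- as.character(tbl$id)
  if (any(tbl$rt < 0, na.rm = TRUE) || any(tbl$area < 0, na.rm = TRUE)) {
    stop("negative rt/area in ", path, call. = FALSE)
  }
  tbl
}

#' Read a reference-standard table
#'
#' Required columns: `name`, `formula`, `rt`; all formulas are parsed to
#' validate them.
#'
#' @inheritParams read_feature_table
#' @return Data frame of standards.
#' @export
read_standards <- function(path, sep = NULL) {
  tbl <- .read_delim(path, sep)
  miss <- setdiff(c("name", "formula", "rt"), names(tbl))
  if (length(miss)) {
    stop("standards table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl$rt <- as.numeric(tbl$rt)
  invisible(lapply(tbl$formula, parse_formula))  # validate
  tbl
}

.read_delim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

#' Write a table as comma-delimited text with stable formatting
#'
#' Numeric columns are written with full (17 significant digit)
#' precision so that identical inputs yield byte-identical files.
#'
#' @param tbl Data frame (list columns are dropped).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(tbl, path) {
  keep <- !vapply(tbl, is.list, logical(1))
  tbl <- tbl[, keep, drop = FALSE]
  for (col in names(tbl)) {
    if (is.numeric(tbl[[col]])) {
      tbl[[col]] <- sprintf("%.17g", tbl[[col]])
      tbl[[col]][tbl[[col]] == "NA"] <- ""
    }
  }
  utils::write.table(tbl, path, sep = ",", row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
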