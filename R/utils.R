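# Interval convention: length-2 integer vector c(start, end), 0-based
# half-open. Converted to 1-based only in human-readable reports.

iv <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, end >= start)
  c(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) x[2] - x[1]

iv_overlap <- function(a, b) {
  max(0L, min(a[2], b[2]) - max(a[1], b[1]))
}

## substring of a plain character sequence by 0-based half-open interval
substr0 <- function(seq, x) substr(seq, x[1] + 1L, x[2])

`%||%` <- function(a, b) if (is.null(a)) b else a

rb_log <- function(..., level = "INFO") {
  opt <- getOption("retroburst.log_level", "INFO")
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L, QUIET = 5L)
  if (levels[[level]] >= levels[[opt]]) {
    message(sprintf("[%s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

#' Write a tabular report as TSV
#'
#' Writes a data frame as a UTF-8 tab-separated file with a header line.
#' Numeric (double) columns are formatted with a fixed number of decimals so
#' reports are byte-stable across platforms.
#'
#' @param rows A data frame (may have zero rows; the header is still written).
#' @param path Output file path.
#' @param digits Number of decimals used for double columns (default 4).
#' @return Invisibly, the path written.
#' @export
write_tsv_report <- function(rows, path, digits = 4) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(out[[j]], digits = digits, format = "f"))
    }
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
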