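# Output dialects: locale-independent CSV (full precision) and aligned text
# tables (4 significant digits), both written atomically.

write_atomic <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write output file: ", path)
  invisible(path)
}

write_atomic_csv <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE,
                     na = "", eol = "\n", fileEncoding = "UTF-8")
  }, path)
}

#' Write a result table to CSV or aligned text
#'
#' CSV output keeps full floating-point precision; text output is an aligned
#' table with 4 significant digits. Files are written atomically (temporary
#' file plus rename).
#'
#' @param results data frame (or an object with an `as.data.frame` method).
#' @param path output file.
#' @param format `"csv"` or `"text"`.
#' @return invisibly, the path.
#' @export
write_report <- function(results, path, format = c("csv", "text")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "csv") {
    write_atomic_csv(df, path)
  } else {
    write_atomic(function(tmp) {
      fmt <- df
      num <- vapply(fmt, is.numeric, logical(1))
      fmt[num] <- lapply(fmt[num], signif, digits = 4)
      writeLines(utils::capture.output(print(fmt, row.names = FALSE)), tmp)
    }, path)
  }
  invisible(path)
}
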