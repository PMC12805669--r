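#' Tab-separated trace files
#'
#' Traces are written in the format common MCMC trace viewers expect: one
#' comment line, a tab-separated header, then numeric rows (first column is
#' the iteration or sample index).
#'
#' @param df data.frame of numeric columns; first column should be the
#'   iteration/sample index.
#' @param path output path.
#' @param comment comment placed on the first line.
#' @export
write_trace <- function(df, path, comment = "glidetree trace") {
  if (any(!vapply(df, is.numeric, TRUE))) stop("write_trace: non-numeric column")
  if (any(!vapply(df, function(v) all(is.finite(v)), TRUE))) {
    stop("write_trace: non-finite values in trace")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE)
}
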