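#' Write a result table as TSV with embedded provenance
#'
#' Writes a data frame as tab-separated values preceded by `#`-prefixed
#' `key = value` header lines carrying the model parameters (and seed,
#' when given), so every output file is self-describing and round-trip
#' parseable with [read_table_tsv()].
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Optional [model_params()] echoed into the header.
#' @param extra Optional named list of additional scalars (e.g. `seed`,
#'   `M`) echoed into the header.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, params = NULL, extra = NULL) {
  hdr <- character(0)
  if (!is.null(params)) {
    stopifnot(inherits(params, "model_params"))
    hdr <- c(hdr, sprintf("# %s = %.15g", c("Ni", "Nf", "cost", "alpha"),
                          c(params$Ni, params$Nf, params$cost, params$alpha)))
  }
  for (nm in names(extra)) {
    hdr <- c(hdr, sprintf("# %s = %.15g", nm, as.numeric(extra[[nm]])))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @return `read_table_tsv()`: the data frame, with the parsed header as
#'   attribute `header` (named numeric vector).
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- numeric(0)
  if (any(is_hdr)) {
    kv <- sub("^#\\s*", "", lines[is_hdr])
    parts <- strsplit(kv, "=", fixed = TRUE)
    hdr <- as.numeric(trimws(vapply(parts, `[`, "", 2L)))
    names(hdr) <- trimws(vapply(parts, `[`, "", 1L))
  }
  df <- utils::read.table(text = lines[!is_hdr], header = TRUE, sep = "\t")
  attr(df, "header") <- hdr
  df
}
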