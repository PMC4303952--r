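# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Percentages are reported rounded half-up to one decimal (so 0.35 -> 0.4),
#' matching conventional table formatting rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# write.table with fixed, locale-independent settings: tab separator, dot
# decimal, LF line endings, no quoting -- so reruns are byte-identical.
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n", dec = ".")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
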