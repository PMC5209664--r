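#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (0.125 -> 0.13 at two digits), unlike [base::round()] which rounds
#' half to even. Used for all printed percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by a relative epsilon so values stored just under .5 (binary
  # representation) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with two-decimal half-up rounding
#'
#' @param num,den Numerator and denominator (vectors recycle).
#' @param digits Decimal places (default 2).
#' @return `round_half_up(100 * num / den, digits)`; `NA` where `den == 0`.
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_up(100 * num / den, digits)
  out[den == 0] <- NA_real_
  out
}

# formatted stop()
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# canonical site key used to match event loci across comparisons
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

# 1-based inclusive [start, end] -> 0-based half-open [start0, end0)
to_zero_based <- function(start, end) {
  list(start = start - 1L, end = end)
}

# 0-based half-open [start0, end0) -> 1-based inclusive [start, end]
from_zero_based <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

# header comment written on top of every TSV output
tool_comment <- function(params = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("epimutools")),
                  error = function(e) "dev")
  pstr <- if (length(params)) {
    paste(names(params), unlist(params), sep = "=", collapse = " ")
  } else ""
  sprintf("# epimutools %s %s", ver, pstr)
}

# write a data.table as TSV with a "#" comment line and a header line
write_tsv <- function(dt, path, params = NULL) {
  writeLines(tool_comment(params), path)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE, append = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  first <- readLines(path, n = 50L)
  n_comment <- 0L
  while (n_comment < length(first) && startsWith(first[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  data.table::fread(path, sep = "\t", header = TRUE, skip = n_comment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CONTEXTS <- c("CG", "CHG", "CHH")
GENERATIONS <- c("G0", "G10", "G11", "G10R1")
TREATMENTS <- c("D", "W")
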