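#' @import data.table
#' @importFrom stats cor rbinom rmultinom rnorm runif setNames p.adjust
#'   pnbinom sd rlnorm
#' @importFrom utils head tail write.table read.table
NULL

TAG_LEN <- 21L
ANCHOR <- "CATG"

#' Reverse-complement a nucleotide string
#'
#' Plain-character reverse complement over the IUPAC core alphabet
#' \{A,C,G,T,N\}; other characters map to N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    chartr("RYSWKMBDHV", "NNNNNNNNNN", toupper(x)))))
}

#' Format a percentage the way tag-accounting tables print it
#'
#' `100 * num / den`, rounded half-up to two decimals and formatted with
#' exactly two decimal places (so 64.4996 prints as "64.50").
#'
#' @param num numerator.
#' @param den denominator (must be positive).
#' @return character vector like "38.06".
#' @export
format_pct <- function(num, den) {
  stopifnot(all(den > 0))
  # round half-up, not banker's rounding: printed tables use half-up
  v <- floor(100 * num / den * 100 + 0.5) / 100
  sprintf("%.2f", v)
}

# half-up rounding to integer (printed table "Average" rows)
round_half_up <- function(x) floor(x + 0.5)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
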