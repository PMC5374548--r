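#' Construct a set of FASTQ records
#'
#' The package's in-memory representation of sequencing reads: a data frame
#' with character columns `name` (the full header line without the leading
#' `@`), `bases` (over the alphabet A/C/G/T/N) and `quals` (Phred+33 encoded,
#' same length as `bases`).
#'
#' @param name,bases,quals Character vectors of equal length.
#' @param validate Check the record invariants (alphabet, matching lengths,
#'   quality scores in \[0, 60\]). Disable only for trusted internal calls.
#' @return A data frame of class `fastq_reads`.
#' @examples
#' fastq_reads("r1", "ACGT", "IIII")
#' @export
fastq_reads <- function(name = character(), bases = character(),
                        quals = character(), validate = TRUE) {
  x <- data.frame(name = as.character(name), bases = as.character(bases),
                  quals = as.character(quals), stringsAsFactors = FALSE)
  if (validate) validate_reads(x)
  class(x) <- c("fastq_reads", "data.frame")
  x
}

validate_reads <- function(x) {
  bad <- which(nchar(x$bases) != nchar(x$quals))
  if (length(bad) > 0)
    stop("record ", bad[1], ": bases and quals differ in length", call. = FALSE)
  bad <- which(!grepl("^[ACGTN]*$", x$bases))
  if (length(bad) > 0)
    stop("record ", bad[1], ": bases outside the A/C/G/T/N alphabet",
         call. = FALSE)
  # Phred+33: scores in [0, 60] <=> ASCII '!' (33) .. '}' (93)
  bad <- which(grepl("[^!-}]", x$quals))
  if (length(bad) > 0)
    stop("record ", bad[1], ": quality characters outside Phred+33 [0, 60] ",
         "(Phred+64 input is not supported)", call. = FALSE)
  invisible(x)
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat("<fastq_reads> ", nrow(x), " records",
      if (nrow(x) > 0) paste0(", length ", min(nchar(x$bases)), "-",
                              max(nchar(x$bases)), " bp"), "\n", sep = "")
  if (nrow(x) > 0) print.data.frame(head(x, 6))
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode Phred+33 quality strings
#'
#' @param quals Character vector of quality strings.
#' @return A list of integer vectors of Phred scores.
#' @export
phred_scores <- function(quals) {
  lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_chars <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}
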