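#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `A,C,G,T,N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ATGTT", "ACGTN"))
revcomp <- function(x) {
  vapply(as.character(x), cpp_revcomp, character(1), USE.NAMES = FALSE)
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {%s} (first offender: %s)",
      what, paste(DNA_ALPHABET[seq_len(4 + allow_n)], collapse = ","),
      names(x)[bad][1] %||% which(bad)[1]
    ))
  }
  invisible(x)
}

usage_error <- function(msg) {
  abort(msg, class = "snpgraph_usage_error")
}

# coerce reads input (named character vector or data frame) to a tibble
# with name/seq/qual columns
as_reads_tbl <- function(reads) {
  if (is.character(reads)) {
    nm <- names(reads) %||% paste0("read", seq_along(reads))
    return(tibble(name = nm, seq = unname(toupper(reads)),
                  qual = strrep("I", nchar(reads))))
  }
  reads <- as_tibble(reads)
  if (!all(c("name", "seq") %in% names(reads))) {
    abort("reads must have 'name' and 'seq' columns")
  }
  if (!"qual" %in% names(reads)) reads$qual <- strrep("I", nchar(reads$seq))
  reads
}
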