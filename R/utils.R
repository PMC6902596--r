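# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` character strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp("ACGTN")
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) grepl("^[ACGTN]+$", x)

assert_dna <- function(x, what = "sequence") {
  bad <- !is_dna(x)
  if (any(bad)) {
    stop(what, " contains symbols outside {A,C,G,T,N} (ambiguity codes are rejected)",
         call. = FALSE)
  }
  invisible(x)
}

# deterministic md5 of an R object (used for pipeline provenance)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f)
  unname(tools::md5sum(f))
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
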