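# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between the first nchar(prefix) bases of each string in
# `x` and `prefix`.  Strings shorter than the prefix get distance NA.
# Vectorised position-by-position; prefix lengths here are primer-sized.
hamming_prefix <- function(x, prefix) {
  L <- nchar(prefix)
  d <- integer(length(x))
  d[nchar(x) < L] <- NA_integer_
  ok <- !is.na(d)
  if (!any(ok)) return(d)
  for (j in seq_len(L)) {
    d[ok] <- d[ok] + (substr(x[ok], j, j) != substr(prefix, j, j))
  }
  d
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  stop_if(any(bad), what, " contains characters outside ",
          if (allow_n) "A/C/G/T/N" else "A/C/G/T")
  invisible(x)
}
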