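#' Nucleotide string utilities
#'
#' Small helpers shared across the package. All sequences are plain uppercase
#' character strings over the DNA alphabet `{A, C, G, T}` written 5'->3';
#' coordinates reported to the user are 0-based and half-open.
#'
#' @name dna-utils
NULL

# Uppercase and validate a DNA string. Lowercase input is accepted and
# upcased; U is rejected (DNA only). Errors name the 1-based position of the
# first offending character.
dna_clean <- function(seq, arg = "seq", allow_empty = FALSE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    abort(sprintf("`%s` must be a single non-missing character string.", arg),
          class = "gibsim_error_input")
  }
  seq <- str_to_upper(seq)
  if (!allow_empty && nchar(seq) == 0L) {
    abort(sprintf("`%s` must be a non-empty DNA sequence.", arg),
          class = "gibsim_error_input")
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad != -1L) {
    chr <- substr(seq, bad, bad)
    hint <- if (chr == "U") " (RNA letter U is not accepted; DNA only)" else ""
    abort(sprintf("`%s` contains a non-ACGT character '%s' at position %d%s.",
                  arg, chr, as.integer(bad), hint),
          class = "gibsim_error_alphabet")
  }
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq A DNA string (case-insensitive; IUPAC ambiguity codes allowed).
#' @return The reverse complement, uppercase, 5'->3'.
#' @examples
#' revcomp("GACCC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    s <- str_to_upper(s)
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA of length n at a given GC fraction (uses the current RNG state).
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# All rotations considered; returns the lexicographically smallest rotation.
min_rotation <- function(seq) {
  n <- nchar(seq)
  if (n <= 1L) return(seq)
  doubled <- paste0(seq, seq)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  sort(rots)[1L]
}

# Canonical form of a circular double-stranded sequence: the smaller of the
# minimal rotations of the two strands.
canonical_circular <- function(seq) {
  a <- min_rotation(seq)
  b <- min_rotation(revcomp(seq))
  if (a <= b) a else b
}
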