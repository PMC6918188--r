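#' @useDynLib creFingerprint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC degenerate nucleotide codes and their base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_SETS)

# IUPAC code for each base subset (keys are sorted base strings)
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                 character(1))
  stats::setNames(names(IUPAC_SETS), keys)
})

# complement map over the full degenerate alphabet (R<->Y, K<->M, B<->V, D<->H)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of a DNA sequence or IUPAC pattern
#'
#' Works on the full 15-letter degenerate alphabet; degenerate codes map to
#' the code of the complemented base set (R to Y, K to M, B to V, D to H; S,
#' W and N are self-complementary). The operation is an involution:
#' `reverse_complement(reverse_complement(x))` returns `x`.
#'
#' @param x character vector of sequences/patterns over the IUPAC alphabet
#'   (case-insensitive; returned upper-case).
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("TTGACC")   # "GGTCAA"
#' reverse_complement("CACGTG")   # palindromic G-box
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  check_iupac(x)
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(IUPAC_COMPLEMENT[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_iupac <- function(x) {
  for (s in x) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% IUPAC_ALPHABET)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' at position %d of pattern '%s'",
                   chars[bad[1]], bad[1], s), call. = FALSE)
    }
  }
  invisible(x)
}

# DNA <-> integer codes: A=1, C=2, G=3, T=4, anything else (N etc.) = 5
DNA_BASES <- c("A", "C", "G", "T")

dna_to_int <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(chars, DNA_BASES)
  code[is.na(code)] <- 5L
  as.integer(code)
}

int_to_dna <- function(code) {
  paste(c(DNA_BASES, "N")[code], collapse = "")
}

revcomp_int <- function(code) {
  out <- 5L - rev(code)
  out[out == 0L] <- 5L   # N stays N
  out
}
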