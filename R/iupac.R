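# IUPAC nucleotide ambiguity handling. Base sets are encoded as 4-bit masks
# (A=1, C=2, G=4, T=8) so that subset / intersection questions reduce to
# bitwAnd. U is deliberately absent: inputs are DNA consensus sequences.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_LETTERS <- names(.IUPAC_BITS)

#' IUPAC nucleotide codes
#'
#' Utilities for the 15 standard IUPAC DNA codes. `iupacBases()` returns the
#' set of concrete bases a code stands for (e.g. `"R"` is A or G, `"N"` is
#' any base); `iupacLetters()` returns all valid code letters.
#'
#' @param code A single IUPAC code letter (case-insensitive).
#' @return `iupacBases()`: a character vector of bases from `A,C,G,T`;
#'   `iupacLetters()`: the 15 valid code letters.
#' @examples
#' iupacBases("N")
#' iupacBases("R")
#' @export
iupacBases <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  set <- .IUPAC_SETS[[code]]
  if (is.null(set)) {
    stop("'", code, "' is not an IUPAC nucleotide code", call. = FALSE)
  }
  set
}

#' @rdname iupacBases
#' @export
iupacLetters <- function() .IUPAC_LETTERS

# Bit masks for each character of a sequence; error names the offending
# position so callers can point at the exact residue.
.seqBits <- function(sequence, what = "sequence") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- which(is.na(bits))[1L]
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  unname(bits)
}

.validIupac <- function(sequence) {
  !grepl(sprintf("[^%s]", paste(.IUPAC_LETTERS, collapse = "")),
         toupper(sequence))
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements every base using the IUPAC pairing rules (A/T, C/G, R/Y, K/M,
#' B/V, D/H; S, W and N are self-complementary) and reverses the result, so
#' the operation is an involution.
#'
#' @param sequence A single DNA string over the IUPAC alphabet.
#' @return The reverse-complemented string, same length and alphabet.
#' @examples
#' revComp("GATC")    # palindromic restriction site
#' revComp("AACGTN")
#' @export
revComp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .seqBits(sequence)  # validates with positional diagnostics
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
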