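# Shared sequence helpers. All genomic coordinates in this package are
# 1-based inclusive (GenBank/GFF3 convention); this is the one place where
# that convention is documented for internal arithmetic.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of concrete bases each one admits.
# An 'N' (or any other ambiguity code) in the *subject* sequence never
# matches a motif symbol: only concrete A/C/G/T subject bases can match.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#' @param x a single nucleotide string (A/C/G/T/N and IUPAC codes)
#' @return the reverse complement string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS nucleotide sequence with the bacterial code
#'
#' Uses NCBI translation table 11 and drops the terminal stop codon if the
#' sequence ends in one. Internal stops are translated as `*` and left for
#' the caller to flag.
#'
#' @param cds nucleotide string whose length is a multiple of 3
#' @return amino-acid string without the terminal stop
#' @keywords internal
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  ))
  sub("\\*$", "", aa)
}

# split a string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic random DNA with a given GC content, using the current RNG
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
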