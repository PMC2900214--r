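# Shared low-level helpers: sequence manipulation, translation, validation.

#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom Biostrings readDNAStringSet readAAStringSet writeXStringSet
#' @importFrom Biostrings translate reverseComplement pairwiseAlignment
#' @importFrom Biostrings matchPattern getGeneticCode nucleotideSubstitutionMatrix
#' @importFrom Biostrings score pattern subject
#' @importFrom IRanges IRanges reduce
#' @importFrom stats runif setNames
#' @importFrom utils head read.delim write.table modifyList
NULL

BACTERIAL_CODE <- NULL  # filled at load; translation table 11
CODON_TABLE <- NULL     # all 64 codons -> amino acid / '*'

.onLoad <- function(libname, pkgname) {
  BACTERIAL_CODE <<- Biostrings::getGeneticCode("11")
  CODON_TABLE <<- setNames(unname(BACTERIAL_CODE), names(BACTERIAL_CODE))
}

COG_CATEGORIES <- c("B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                    "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Reverse complement of a nucleotide string
#'
#' Character-level reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x single nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string with the bacterial genetic code
#'
#' Translation uses table 11; TGA is a stop ('*'). Codons containing N (or
#' any non-ACGT letter) translate to X and are never counted as stops.
#' Trailing bases that do not fill a codon are ignored.
#'
#' @param dna nucleotide string.
#' @return amino-acid string (may contain '*' and 'X').
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna)
  n3 <- n - n %% 3L
  if (n3 < 3L) return("")
  starts <- seq.int(1L, n3, 3L)
  aa <- CODON_TABLE[substring(dna, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"  # codons containing N (or anything non-ACGT)
  paste(aa, collapse = "")
}

# Uppercase and collapse every non-ACGT letter to N.
normalize_dna <- function(x) gsub("[^ACGT]", "N", toupper(x))

# Random DNA of given length at a GC target (P(G)=P(C)=gc/2).
random_dna <- function(n, gc, rng_ok = TRUE) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Count mismatches between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

gc_fraction <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  acgt <- sum(tab[intersect(names(tab), c("A", "C", "G", "T"))])
  if (acgt == 0) stop("GC content undefined: no A/C/G/T bases")
  sum(tab[intersect(names(tab), c("G", "C"))]) / acgt
}

# Codons by amino acid under table 11 (sense codons only).
codons_for_aa <- function() {
  code <- BACTERIAL_CODE
  split(names(code), unname(code))
}
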