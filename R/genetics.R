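# Low-level nucleotide / codon machinery shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

## genetic code as a named vector: codon -> single-letter amino acid, "*" stop
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over A,C,G,T,N (case-insensitive;
#'   gaps `-` are preserved).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    comp <- chartr("ACGTN-", "TGCAN-", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a sequence string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## encode bases as integers 1..4 (A,C,G,T); gaps, N and anything else -> NA
seq_ints <- function(s) match(seq_chars(s), DNA_BASES)

ints_seq <- function(v) paste(DNA_BASES[v], collapse = "")

## random uniform DNA string
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

## split an in-frame DNA string into codons
codon_split <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

translate_codons <- function(codons) {
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

## transition partner of each base
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

## draw a substitution target for one base under a transition/transversion
## rate ratio kappa (probability weights kappa : 1 : 1)
mutate_base <- function(base, kappa) {
  others <- setdiff(DNA_BASES, base)
  w <- ifelse(is_transition(base, others), kappa, 1)
  sample(others, 1L, prob = w)
}

## character alignment matrix (rows = sequences) from a character vector
aln_char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

## integer-coded alignment matrix; gap/N/other -> NA
aln_int_matrix <- function(seqs) {
  m <- aln_char_matrix(seqs)
  im <- match(m, DNA_BASES)
  dim(im) <- dim(m)
  rownames(im) <- rownames(m)
  im
}
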