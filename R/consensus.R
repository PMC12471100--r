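# Consensus elements, ORF prediction, family clustering at the conventional
# 70% identity threshold, and tRNA primer-binding-site matching.

#' Majority-rule consensus of an alignment
#'
#' Per column the most frequent non-N symbol wins; a column whose plurality
#' winner is the gap character is dropped from the consensus. Base ties are
#' broken in the fixed order A < C < G < T; all-N columns are emitted as `N`.
#'
#' @param alignment A `copy_alignment`.
#' @param plurality Unused threshold retained for interface stability; the
#'   winner is always the plurality symbol.
#' @return Ungapped consensus DNA string.
#' @export
build_consensus <- function(alignment, plurality = 0.5) {
  stopifnot(inherits(alignment, "copy_alignment"))
  m <- aln_char_matrix(alignment$seqs)
  symbols <- c(DNA_BASES, "-")
  out <- apply(m, 2, function(col) {
    counts <- vapply(symbols, function(s) sum(col == s), integer(1))
    if (all(counts == 0)) return("N")                 # all-N column
    winner <- symbols[which.max(counts)]              # ties: A<C<G<T<-
    if (winner == "-" ) return("")                    # gap plurality: drop
    winner
  })
  paste(out, collapse = "")
}

#' Predict the longest ATG-initiated ORF
#'
#' Scans the three sense-strand frames for the longest open reading frame
#' that starts at `ATG`; the interval runs through the terminal stop codon
#' (or to the last complete codon when the frame ends open).
#'
#' @param seq Ungapped DNA string.
#' @param min_len Minimum ORF interval length in bp.
#' @return `NULL` when no ORF reaches `min_len`; otherwise a list with
#'   `interval` (0-based half-open, stop codon included) and `protein`
#'   (translation without the stop).
#' @export
find_orf <- function(seq, min_len = 300L) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    codons <- substring(seq, frame + seq(1L, by = 3L, length.out = ncod),
                        frame + seq(3L, by = 3L, length.out = ncod))
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    ## segment the frame at stops; ORF = first ATG .. stop (inclusive)
    seg_start <- 1L
    for (si in c(which(is_stop), ncod + 1L)) {
      if (si > seg_start) {
        atg <- which(is_atg[seg_start:(si - 1L)])
        if (length(atg) > 0) {
          a <- seg_start + atg[1L] - 1L
          e <- min(si, ncod)                          # include stop codon
          len <- (e - a + 1L) * 3L
          if (len >= min_len && (is.null(best) || len > best$len)) {
            start0 <- frame + (a - 1L) * 3L
            best <- list(len = len, interval = iv(start0, start0 + len),
                         codons = codons[a:e])
          }
        }
      }
      seg_start <- si + 1L
    }
  }
  if (is.null(best)) {
    rb_log("no ORF >= ", min_len, " bp found", level = "DEBUG")
    return(NULL)
  }
  cods <- best$codons
  if (cods[length(cods)] %in% STOP_CODONS) cods <- cods[-length(cods)]
  list(interval = best$interval, protein = translate_codons(cods))
}

#' Cluster copies into families by single-linkage identity
#'
#' Pairwise global identities (the [pairwise_identity()] scorer) are
#' single-linkage clustered at `threshold`: two copies share a family iff
#' they are connected by a chain of pairs with identity >= threshold. The
#' conventional cutoff for retrotransposon family designation is 70%;
#' consensus elements of distinct families typically sit at 40-64%
#' similarity, well below it. Family labels are deterministic: `F<k>` in
#' order of each family's smallest member id.
#'
#' @param copies Named character vector of (ungapped) copy sequences.
#' @param threshold Identity threshold in `[0, 1]`.
#' @return List with `families` (named character vector copy -> family
#'   label) and `identity` (the symmetric pairwise identity matrix used).
#' @export
cluster_families <- function(copies, threshold = 0.70) {
  stopifnot(length(copies) >= 1, !is.null(names(copies)))
  ids <- sort(names(copies))
  n <- length(ids)
  idm <- diag(1, n)
  dimnames(idm) <- list(ids, ids)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- pairwise_identity(copies[[ids[i]]],
                                                    copies[[ids[j]]])
      }
    }
  }
  ## union-find single linkage
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && idm[i, j] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fam_of_root <- stats::setNames(sprintf("F%d", seq_along(unique(roots))),
                                 unique(roots))
  families <- stats::setNames(fam_of_root[as.character(roots)], ids)
  list(families = families, identity = idm)
}

#' Locate the primer binding site against a tRNA library
#'
#' LTR retrotransposons prime first-strand cDNA synthesis with a host tRNA
#' whose 3' end anneals to the PBS just inside the 5'-LTR. The `search_span`
#' bases 3' of the 5'-LTR are scanned for the best reverse-complement match
#' to each tRNA's 3'-terminal 18 nt; the longest match with at most
#' `max_mismatch` mismatches wins (ties: fewer mismatches, then earlier tRNA
#' in file order, then smaller offset).
#'
#' @param consensus_seq Element (or consensus) DNA string.
#' @param ltr5_end 0-based position just past the 5'-LTR.
#' @param trna_lib Named character vector of tRNA sequences (or path to a
#'   FASTA readable by [read_fasta()]).
#' @param search_span Number of bases scanned 3' of the LTR.
#' @param min_match Minimum match length to report.
#' @param max_mismatch Maximum mismatches tolerated within the match.
#' @return `NULL` if nothing reaches `min_match`, else a list with `trna_id`,
#'   `offset` (0-based, relative to `ltr5_end`), `length`, `mismatches`.
#' @export
locate_pbs <- function(consensus_seq, ltr5_end, trna_lib, search_span = 30L,
                       min_match = 8L, max_mismatch = 1L) {
  if (is.character(trna_lib) && length(trna_lib) == 1 &&
      file.exists(trna_lib)) {
    trna_lib <- read_fasta(trna_lib)
  }
  stopifnot(length(trna_lib) >= 1, !is.null(names(trna_lib)))
  region <- substr(consensus_seq, ltr5_end + 1L,
                   min(nchar(consensus_seq), ltr5_end + search_span + 18L))
  rch <- seq_chars(region)
  best <- NULL
  for (ti in seq_along(trna_lib)) {
    t3 <- substr(trna_lib[[ti]], max(1L, nchar(trna_lib[[ti]]) - 17L),
                 nchar(trna_lib[[ti]]))
    target <- seq_chars(revcomp(t3))         # PBS = revcomp of tRNA 3' end
    tl <- length(target)
    for (off in 0:min(search_span - 1L, length(rch) - min_match)) {
      maxlen <- min(tl, length(rch) - off)
      if (maxlen < min_match) next
      cmp <- rch[off + seq_len(maxlen)] != target[seq_len(maxlen)]
      mmcum <- cumsum(cmp)
      lens <- which(mmcum <= max_mismatch)
      if (length(lens) == 0) next
      len <- max(lens)
      if (len < min_match) next
      mm <- mmcum[len]
      ## trailing mismatches do not count as part of the match
      while (len > min_match && cmp[len]) { len <- len - 1L; mm <- mm - 1L }
      if (len < min_match) next
      cand <- list(trna_id = names(trna_lib)[ti], offset = off,
                   length = len, mismatches = mm)
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length && cand$mismatches < best$mismatches)) {
        best <- cand
      }
    }
  }
  best
}
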