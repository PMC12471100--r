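# Full-unit LTR retrotransposon delimitation around seed loci: direct-repeat
# (LTR pair) detection by exact k-mer seeding, extension and terminus
# trimming, followed by 4-bp target-site-duplication confirmation.

#' Global pairwise identity of two DNA sequences
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, gap open 10, gap
#' extend 0.5); identity is matches over aligned columns, with gap columns
#' and any column involving `N` counted as non-matches. This scorer is shared
#' by LTR-pair identity and family clustering.
#'
#' @param a,b DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (identical(a, b) && !grepl("N", a, fixed = TRUE)) return(1)
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(0, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- 1
  mat["N", "N"] <- 0
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  mean(pa == sa & pa %in% DNA_BASES)
}

#' Extract an analysis window around an anchor locus
#'
#' @param contig DNA string of the contig.
#' @param anchor 0-based half-open interval `c(start, end)` within the
#'   contig (e.g. a BLAST-style seed hit).
#' @param total_span Window span in bp (default 15000, wide enough to hold a
#'   full element around a coding-region hit).
#' @return List with `seq` (the window), `offset` (0-based contig position of
#'   the window start; window coords + offset = contig coords).
#' @export
extract_window <- function(contig, anchor, total_span = 15000L) {
  n <- nchar(contig)
  if (anchor[1] < 0 || anchor[2] > n || anchor[2] <= anchor[1]) {
    stop("anchor interval outside contig", call. = FALSE)
  }
  mid <- (anchor[1] + anchor[2]) %/% 2L
  start <- max(0L, mid - total_span %/% 2L)
  start <- min(start, max(0L, n - total_span))
  end <- min(n, start + total_span)
  list(seq = substr(contig, start + 1L, end), offset = as.integer(start))
}

## positions (1-based) of every occurrence of a 3-mer pattern test at offset
has_triplet <- function(s, pos, triplet) {
  substr(s, pos, pos + 2L) == triplet
}

#' Find candidate LTR pairs (direct repeats) in a window
#'
#' Exact k-mer seeds of the window against itself are chained along
#' co-diagonals, extended to maximal gapless direct repeats, then trimmed or
#' extended so both copies start with `TGT` and end with `ACA` (the canonical
#' LTR termini) when `require_termini` is set. Every valid terminus
#' combination near the extended boundaries is emitted as its own candidate,
#' so downstream TSD confirmation can arbitrate between them.
#'
#' @param window DNA string to scan.
#' @param ltr_min_len,ltr_max_len Repeat length bounds, bp.
#' @param min_identity Minimum (gapless) identity of the repeat pair.
#' @param require_termini If TRUE, only candidates with canonical termini on
#'   both copies are returned; decayed copies can be admitted by raising
#'   `termini_mismatch`.
#' @param k Seed k-mer size.
#' @param max_gap Maximum gap between chained seeds, bp.
#' @param band Diagonal band width for seed chaining, bp.
#' @param max_span Maximum distance from left-repeat start to right-repeat
#'   end (bounds the full-unit size).
#' @param termini_mismatch Number of mismatches tolerated across the 12
#'   terminal bases (TGT + ACA on both copies) when `require_termini`.
#' @return List of candidates sorted by identity (desc), then length (desc),
#'   then left start. Each is a list with 0-based half-open `left` and
#'   `right` intervals, `identity`, and `termini_ok`.
#' @export
find_ltr_pairs <- function(window, ltr_min_len = 100L, ltr_max_len = 1000L,
                           min_identity = 0.8, require_termini = TRUE,
                           k = 12L, max_gap = 2000L, band = 50L,
                           max_span = 8000L, termini_mismatch = 0L) {
  n <- nchar(window)
  if (n < 2L * ltr_min_len) return(list())
  ch <- seq_chars(window)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(window, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  tab <- split(starts[ok], kmers[ok])
  tab <- tab[lengths(tab) >= 2L & lengths(tab) <= 12L]

  ## seeds: (i, j, d = j - i), 1-based starts of matching k-mers
  seeds <- list()
  for (p in tab) {
    pr <- utils::combn(p, 2L)
    d <- pr[2L, ] - pr[1L, ]
    keep <- d >= ltr_min_len & d <= max_span
    if (any(keep)) {
      seeds[[length(seeds) + 1L]] <- cbind(i = pr[1L, keep], d = d[keep])
    }
  }
  if (length(seeds) == 0) return(list())
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[order(seeds[, "d"], seeds[, "i"]), , drop = FALSE]

  ## chain seeds sharing a diagonal: group into d-bands, then split each
  ## band into chains at position gaps larger than max_gap
  d_brk <- c(TRUE, diff(seeds[, "d"]) > band)
  d_grp <- cumsum(d_brk)
  clusters <- list()
  for (g in split.data.frame(seeds, d_grp)) {
    g <- g[order(g[, "i"]), , drop = FALSE]
    i_brk <- c(TRUE, diff(g[, "i"]) > k + max_gap)
    for (chain in split.data.frame(g, cumsum(i_brk))) {
      clusters[[length(clusters) + 1L]] <- chain
    }
  }

  cands <- list()
  for (cl in clusters) {
    ## extension is gapless (single diagonal): anchor on the modal diagonal
    ## of the chain, so stray co-band seeds cannot corrupt the extent
    dtab <- table(cl[, "d"])
    d <- as.integer(names(dtab)[which.max(dtab)])
    on_d <- cl[, "d"] == d
    l <- min(cl[on_d, "i"]); e <- max(cl[on_d, "i"]) + k - 1L
    ## gapless extension with a mismatch-run cutoff, then trim back
    run <- 0L
    while (l > 1L && run < 4L) {
      if (ch[l - 1L] == ch[l - 1L + d] && ch[l - 1L] %in% DNA_BASES) {
        run <- 0L
      } else run <- run + 1L
      l <- l - 1L
    }
    while (l <= e && (ch[l] != ch[l + d] || !(ch[l] %in% DNA_BASES))) {
      l <- l + 1L
    }
    run <- 0L
    while (e + d < n && run < 4L) {
      if (ch[e + 1L] == ch[e + 1L + d] && ch[e + 1L] %in% DNA_BASES) {
        run <- 0L
      } else run <- run + 1L
      e <- e + 1L
    }
    while (e >= l && (ch[e] != ch[e + d] || !(ch[e] %in% DNA_BASES))) {
      e <- e - 1L
    }
    if (e - l + 1L < ltr_min_len) next

    ident_over <- function(s1, e1) {
      idx <- s1:e1
      mean(ch[idx] == ch[idx + d] & ch[idx] %in% DNA_BASES)
    }

    if (require_termini) {
      rng <- function(a, b) if (b < a) integer(0) else a:b
      srange <- rng(max(1L, l - 30L), min(l + 30L, e - ltr_min_len + 1L))
      erange <- rng(max(e - 30L, l + ltr_min_len - 1L), min(e + 30L, n - d))
      erange <- erange[erange >= 3L]
      s_opts <- srange[vapply(srange, function(s1) {
        mm <- sum(seq_chars(substr(window, s1, s1 + 2L)) != c("T", "G", "T")) +
              sum(seq_chars(substr(window, s1 + d, s1 + d + 2L)) !=
                  c("T", "G", "T"))
        mm <= termini_mismatch
      }, logical(1))]
      e_opts <- erange[vapply(erange, function(e1) {
        mm <- sum(seq_chars(substr(window, e1 - 2L, e1)) != c("A", "C", "A")) +
              sum(seq_chars(substr(window, e1 + d - 2L, e1 + d)) !=
                  c("A", "C", "A"))
        mm <= termini_mismatch
      }, logical(1))]
      if (length(s_opts) > 8L) s_opts <- s_opts[1:8]
      if (length(e_opts) > 8L) e_opts <- e_opts[order(-e_opts)][1:8]
      for (s1 in s_opts) {
        for (e1 in e_opts) {
          len <- e1 - s1 + 1L
          if (len < ltr_min_len || len > ltr_max_len) next
          if (e1 + d - (s1 - 1L) > max_span) next
          idf <- ident_over(s1, e1)
          if (idf < min_identity) next
          cands[[length(cands) + 1L]] <- list(
            left = iv(s1 - 1L, e1), right = iv(s1 - 1L + d, e1 + d),
            identity = idf, termini_ok = TRUE)
        }
      }
    } else {
      len <- e - l + 1L
      if (len < ltr_min_len || len > ltr_max_len) next
      if (e + d - (l - 1L) > max_span) next
      idf <- ident_over(l, e)
      if (idf < min_identity) next
      term <- has_triplet(window, l, "TGT") && has_triplet(window, l + d, "TGT") &&
        substr(window, e - 2L, e) == "ACA" &&
        substr(window, e + d - 2L, e + d) == "ACA"
      cands[[length(cands) + 1L]] <- list(
        left = iv(l - 1L, e), right = iv(l - 1L + d, e + d),
        identity = idf, termini_ok = term)
    }
  }
  if (length(cands) == 0) return(list())
  ## drop exact duplicates (same intervals reached from different clusters)
  key <- vapply(cands, function(x) paste(x$left, x$right, collapse = ","),
                character(1))
  cands <- cands[!duplicated(key)]
  ord <- order(-vapply(cands, `[[`, numeric(1), "identity"),
               -vapply(cands, function(x) iv_len(x$left), integer(1)),
               vapply(cands, function(x) x$left[1], integer(1)))
  cands <- cands[ord]
  ## drop boundary variants nested inside a better-or-equal candidate on the
  ## same diagonal; variants that beat their encloser's identity survive so
  ## TSD confirmation can arbitrate
  keep <- rep(TRUE, length(cands))
  for (j in seq_along(cands)) {
    for (m in seq_len(j - 1L)) {
      if (!keep[m]) next
      a <- cands[[m]]; b <- cands[[j]]
      same_d <- (a$right[1] - a$left[1]) == (b$right[1] - b$left[1])
      nested <- a$left[1] <= b$left[1] && a$right[2] >= b$right[2]
      if (same_d && nested && b$identity <= a$identity + 1e-9) {
        keep[j] <- FALSE
        break
      }
    }
  }
  cands[keep]
}

#' Confirm an LTR-pair candidate as a full-unit element via its TSDs
#'
#' Reads `tsd_len` bases immediately upstream of the 5'-LTR and downstream of
#' the 3'-LTR. The element is returned regardless of the outcome
#' ("if possible" semantics); `tsd_confirmed` is TRUE only when the two
#' flanks are equal, complete, and N-free.
#'
#' @param window DNA string the candidate was found in.
#' @param candidate One element of the [find_ltr_pairs()] result.
#' @param tsd_len TSD length, bp (canonical 4).
#' @return A list of class `ltr_element` with window-relative 0-based
#'   half-open intervals (`interval`, `ltr5_interval`, `ltr3_interval`,
#'   `internal_interval`), `tsd_left`, `tsd_right`, `tsd_confirmed`,
#'   `ltr_identity`, and `strand` (defaults `"+"`).
#' @export
confirm_element <- function(window, candidate, tsd_len = 4L) {
  n <- nchar(window)
  s <- candidate$left[1]; e <- candidate$right[2]
  tsd_left <- if (s - tsd_len >= 0) substr(window, s - tsd_len + 1L, s) else ""
  tsd_right <- if (e + tsd_len <= n) substr(window, e + 1L, e + tsd_len) else ""
  confirmed <- nchar(tsd_left) == tsd_len && nchar(tsd_right) == tsd_len &&
    tsd_left == tsd_right && !grepl("N", tsd_left, fixed = TRUE)
  if (!confirmed && (nchar(tsd_left) < tsd_len || nchar(tsd_right) < tsd_len)) {
    rb_log("TSD unconfirmed: candidate at window edge", level = "DEBUG")
  }
  structure(list(
    contig_id = NA_character_, interval = iv(s, e), strand = "+",
    ltr5_interval = candidate$left, ltr3_interval = candidate$right,
    internal_interval = iv(candidate$left[2], candidate$right[1]),
    tsd_left = tsd_left, tsd_right = tsd_right, tsd_confirmed = confirmed,
    ltr_identity = candidate$identity), class = "ltr_element")
}

#' LTR-pair identity of a delimited element
#'
#' Identity of the two LTRs under the shared global-alignment scorer
#' ([pairwise_identity()]); high values (> 0.99 is common for recently
#' transposed copies) indicate young insertions.
#'
#' @param element An `ltr_element`.
#' @param contig DNA string the element's intervals refer to.
#' @return Identity fraction.
#' @export
ltr_pair_identity <- function(element, contig) {
  pairwise_identity(substr0(contig, element$ltr5_interval),
                    substr0(contig, element$ltr3_interval))
}

## longest ATG-initiated ORF length on the three sense frames (bp); helper
## for strand calling
longest_orf_len <- function(seq, min_len = 300L) {
  o <- find_orf(seq, min_len = min_len)
  if (is.null(o)) 0L else iv_len(o$interval)
}

#' Annotate full-unit elements around seed loci in a genome
#'
#' Per seed: a ~15 kb window is extracted, LTR-pair candidates are searched,
#' and the best candidate containing the anchor is confirmed. Candidates with
#' confirmed TSDs are preferred (the TSD is the hallmark of a genuine
#' insertion); among equals, higher identity, then longer, then leftmost
#' wins. Contigs shorter than `config$min_contig_len` (10 kb) are skipped as
#' potential assembly chimeras. Elements sharing > 50% reciprocal overlap are
#' deduplicated. Element strand is assigned by ORF orientation of the
#' internal region.
#'
#' @param contigs Named character vector of contig sequences.
#' @param seeds Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open anchor intervals).
#' @param config A [pipeline_config()].
#' @param total_span Window span passed to [extract_window()].
#' @return List with `elements` (data frame: contig, start, end, strand,
#'   ltr5/ltr3 intervals, tsd, tsd_confirmed, ltr_identity), `unresolved`
#'   (seed rows yielding no candidate) and `n_skipped_contigs`.
#' @export
annotate_genome <- function(contigs, seeds, config = pipeline_config(),
                            total_span = 15000L) {
  stopifnot(all(seeds$contig %in% names(contigs)))
  skipped <- 0L
  rows <- list()
  unresolved <- list()
  for (i in seq_len(nrow(seeds))) {
    cn <- seeds$contig[i]
    contig <- contigs[[cn]]
    if (nchar(contig) < config$min_contig_len) {
      skipped <- skipped + 1L
      next
    }
    anchor <- iv(seeds$start[i], seeds$end[i])
    w <- extract_window(contig, anchor, total_span)
    cands <- find_ltr_pairs(w$seq, ltr_min_len = config$ltr_min_len,
                            ltr_max_len = config$ltr_max_len,
                            min_identity = config$ltr_min_identity,
                            max_span = config$max_unit_len,
                            termini_mismatch = config$termini_mismatch)
    mid_w <- (anchor[1] + anchor[2]) %/% 2L - w$offset
    cands <- Filter(function(x) x$left[1] <= mid_w && x$right[2] > mid_w,
                    cands)
    if (length(cands) == 0) {
      unresolved[[length(unresolved) + 1L]] <- seeds[i, , drop = FALSE]
      next
    }
    els <- lapply(cands, confirm_element, window = w$seq,
                  tsd_len = config$tsd_len)
    conf <- vapply(els, `[[`, logical(1), "tsd_confirmed")
    el <- if (any(conf)) els[[which(conf)[1]]] else els[[1]]
    int_seq <- substr0(w$seq, el$internal_interval)
    strand <- if (longest_orf_len(revcomp(int_seq)) >
                  longest_orf_len(int_seq)) "-" else "+"
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cn, start = el$interval[1] + w$offset,
      end = el$interval[2] + w$offset, strand = strand,
      ltr5_start = el$ltr5_interval[1] + w$offset,
      ltr5_end = el$ltr5_interval[2] + w$offset,
      ltr3_start = el$ltr3_interval[1] + w$offset,
      ltr3_end = el$ltr3_interval[2] + w$offset,
      tsd = el$tsd_left, tsd_confirmed = el$tsd_confirmed,
      ltr_identity = el$ltr_identity, stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    rb_log(skipped, " seed(s) on contigs < ", config$min_contig_len,
           " bp skipped", level = "INFO")
  }
  elements <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  ## deduplicate elements sharing > 50% reciprocal overlap
  if (!is.null(elements) && nrow(elements) > 1) {
    keep <- rep(TRUE, nrow(elements))
    ord <- order(-elements$tsd_confirmed, -elements$ltr_identity)
    for (a_i in seq_along(ord)) {
      ia <- ord[a_i]
      if (!keep[ia]) next
      for (b_i in seq_along(ord)[-seq_len(a_i)]) {
        ib <- ord[b_i]
        if (!keep[ib] || elements$contig[ia] != elements$contig[ib]) next
        ov <- iv_overlap(c(elements$start[ia], elements$end[ia]),
                         c(elements$start[ib], elements$end[ib]))
        la <- elements$end[ia] - elements$start[ia]
        lb <- elements$end[ib] - elements$start[ib]
        if (ov > 0.5 * la && ov > 0.5 * lb) keep[ib] <- FALSE
      }
    }
    elements <- elements[keep, , drop = FALSE]
    rownames(elements) <- NULL
  }
  list(elements = elements,
       unresolved = if (length(unresolved) > 0) do.call(rbind, unresolved)
                    else NULL,
       n_skipped_contigs = skipped)
}
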