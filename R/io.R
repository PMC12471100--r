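# FASTA / TSV ingestion and the alignment container shared by all
# downstream statistics.

#' Read a FASTA file of unaligned DNA sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Record order is
#' preserved. Duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record ids (the
#'   first whitespace-delimited token of the header), with the full header
#'   stored in the `"desc"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  desc <- names(set)
  ids <- vapply(strsplit(desc, "[ \t]+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id: ", ids[nchar(seqs) == 0][1], call. = FALSE)
  }
  names(seqs) <- ids
  attr(seqs, "desc") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a copy_id -> group TSV map
#'
#' Expects a header line with columns `copy_id` and `group`.
#'
#' @param path Path to the TSV.
#' @return Named character vector: names are copy ids, values group labels.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("copy_id", "group") %in% names(df))) {
    stop("group TSV must have columns 'copy_id' and 'group'", call. = FALSE)
  }
  stats::setNames(df$group, df$copy_id)
}

REGION_LABELS <- c("full", "LTR5", "LTR3", "Int", "RT")

#' Construct a validated copy-set alignment
#'
#' The central container for aligned retrotransposon copies: equal-length
#' gapped sequences over `A,C,G,T,N,-`, a region label, and a copy -> group
#' map (paralogous family and/or donor species).
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param region_label One of `"full"`, `"LTR5"`, `"LTR3"`, `"Int"`, `"RT"`.
#' @param groups Optional named character vector mapping copy ids to group
#'   labels; copies absent from it are assigned `"ungrouped"`.
#' @return An object of class `copy_alignment`.
#' @export
copy_alignment <- function(seqs, region_label = "full", groups = NULL) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  region_label <- match.arg(region_label, REGION_LABELS)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- names(seqs)[lens != lens[1]][1]
    stop("alignment rows differ in length (offending id: ", bad, ")",
         call. = FALSE)
  }
  bad_char <- grepl("[^ACGTN-]", seqs)
  if (any(bad_char)) {
    stop("non-ACGTN- characters in aligned sequence: ",
         names(seqs)[bad_char][1], call. = FALSE)
  }
  g <- stats::setNames(rep("ungrouped", length(seqs)), names(seqs))
  if (!is.null(groups)) {
    extra <- setdiff(names(groups), names(seqs))
    if (length(extra) > 0) {
      rb_log("group map ids absent from alignment: ",
             paste(extra, collapse = ", "), level = "WARN")
    }
    hit <- intersect(names(groups), names(seqs))
    g[hit] <- groups[hit]
  }
  structure(list(seqs = seqs, region_label = region_label, groups = g),
            class = "copy_alignment")
}

#' @export
print.copy_alignment <- function(x, ...) {
  cat(sprintf("copy_alignment: %d sequences x %d columns [%s], %d group(s)\n",
              length(x$seqs), nchar(x$seqs[[1]]), x$region_label,
              length(unique(x$groups))))
  invisible(x)
}

aln_nrow <- function(aln) length(aln$seqs)
aln_ncol <- function(aln) nchar(aln$seqs[[1]])

#' Read an aligned FASTA (plus optional group TSV) as a copy_alignment
#'
#' @param path Aligned FASTA path.
#' @param groups Optional path to a `copy_id`/`group` TSV.
#' @param region_label Region label for the alignment (see
#'   [copy_alignment()]).
#' @return A `copy_alignment`.
#' @export
read_alignment <- function(path, groups = NULL, region_label = "full") {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- stats::setNames(toupper(chartr("Uu", "Tt", as.character(set))), ids)
  gmap <- if (!is.null(groups)) read_groups_tsv(groups) else NULL
  copy_alignment(seqs, region_label = region_label, groups = gmap)
}

## drop alignment columns, returning a new copy_alignment
aln_keep_columns <- function(aln, keep) {
  m <- aln_char_matrix(aln$seqs)[, keep, drop = FALSE]
  seqs <- stats::setNames(apply(m, 1, paste, collapse = ""), names(aln$seqs))
  structure(list(seqs = seqs, region_label = aln$region_label,
                 groups = aln$groups), class = "copy_alignment")
}
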