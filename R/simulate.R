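# Synthetic LTR-retrotransposon burst generator. Produces host contigs
# carrying simulated element families with full ground truth (insertion
# records, genealogy, true alignment), plus simple neutral alignments used to
# calibrate the neutrality tests.
#
# Copies are stored internally as a "ragged template": a character vector
# with one entry per position of the founding element, where substitutions
# replace the single base, deletions set it to "", and insertions append
# extra bases. Collapsing gives the copy sequence; padding columns to a
# common width gives the true multiple alignment by construction.

#' Evolutionary parameters for the burst simulator
#'
#' @param burst_schedule List of `c(time, copies_born)` pairs, times strictly
#'   increasing. Time units are arbitrary; rates are per unit.
#' @param mu_r Per-site error rate per replication event (reverse
#'   transcription is error-prone; new copies differ from their master).
#' @param mu_h Per-site host substitution rate per time unit (post-insertion
#'   decay of resident copies).
#' @param indel_rate Per-copy indel events per time unit.
#' @param indel_mean_len Mean indel length, bp (geometric).
#' @param omega Acceptance probability of nonsynonymous ORF changes in
#'   master-competent lineages (purifying selection strength; dead copies
#'   evolve with omega = 1).
#' @param master_succession_p Probability that a newborn copy becomes a
#'   replication-competent master.
#' @param ts_tv_ratio Transition/transversion rate ratio of the substitution
#'   process.
#' @param strand_minus_p Probability a new insertion lands on the minus
#'   strand.
#' @param protect_rt If TRUE (default) indels never fall inside the RT core
#'   of the template, keeping RT alignments codon-clean.
#' @param end_time Time at which copies are sampled; defaults to the last
#'   burst time plus 10 units, giving resident copies time to diverge.
#' @param seed Integer seed.
#' @return A list of class `evo_params`.
#' @export
evo_params <- function(burst_schedule = list(c(0, 20)), mu_r = 2e-4,
                       mu_h = 1e-3, indel_rate = 0, indel_mean_len = 4,
                       omega = 0.1, master_succession_p = 0.1,
                       ts_tv_ratio = 2, strand_minus_p = 0.5,
                       protect_rt = TRUE, end_time = NULL, seed = 1L) {
  times <- vapply(burst_schedule, `[`, numeric(1), 1L)
  if (any(diff(times) <= 0)) stop("burst times must be strictly increasing",
                                  call. = FALSE)
  stopifnot(mu_r >= 0, mu_h >= 0, indel_rate >= 0, indel_mean_len >= 1,
            omega >= 0, omega <= 1, master_succession_p >= 0,
            master_succession_p <= 1, ts_tv_ratio > 0)
  if (is.null(end_time)) end_time <- max(times) + 10
  if (end_time < max(times)) stop("end_time before last burst", call. = FALSE)
  structure(list(burst_schedule = burst_schedule, mu_r = mu_r, mu_h = mu_h,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 omega = omega, master_succession_p = master_succession_p,
                 ts_tv_ratio = ts_tv_ratio, strand_minus_p = strand_minus_p,
                 protect_rt = protect_rt, end_time = end_time,
                 seed = as.integer(seed)),
            class = "evo_params")
}

#' Build an element template for the simulator
#'
#' Constructs a founding full-unit element: identical flanking LTRs starting
#' `TGT` and ending `ACA`, a primer binding site (PBS) immediately 3' of the
#' 5'-LTR that is exactly reverse-complementary to the 3' terminus of a
#' chosen tRNA, and a single Gag-Pol-style ORF (ATG-initiated, stop-free
#' body, terminal stop codon) anchored on codon boundaries. An in-frame stop
#' is planted just upstream of the ORF so the ORF interval is exactly
#' recoverable by ORF prediction.
#'
#' @param ltr_len LTR length in bp (the empirical family range is 251-521).
#' @param internal_len Internal (non-LTR) region length; full unit length is
#'   `2 * ltr_len + internal_len` (empirical range 4740-5190).
#' @param orf_len ORF interval length including the terminal stop codon;
#'   must be divisible by 3.
#' @param trna_3prime 3'-terminal segment (8-18 nt) of the priming tRNA; the
#'   PBS is its exact reverse complement.
#' @param rt_len Length of the RT (DNA/RNA polymerase domain) core used for
#'   codon-level analyses; 1311 bp by default.
#' @param seed Integer seed.
#' @return A list of class `element_template` with fields `ltr`, `internal`,
#'   `pbs`, `orf_interval`, `rt_interval` (both 0-based half-open on the full
#'   unit), `trna_3prime`, and `full_len`.
#' @export
make_template <- function(ltr_len = 300L, internal_len = 4300L,
                          orf_len = 3900L, trna_3prime = "TGGCGCCCGAACAGGGAC",
                          rt_len = 1311L, seed = 1L) {
  set.seed(seed)
  ltr_len <- as.integer(ltr_len)
  internal_len <- as.integer(internal_len)
  orf_len <- as.integer(orf_len)
  if (orf_len %% 3 != 0) stop("orf_len must be a multiple of 3",
                              call. = FALSE)
  if (ltr_len < 12) stop("ltr_len too short", call. = FALSE)
  trna_3prime <- toupper(trna_3prime)
  pbs <- revcomp(trna_3prime)
  pbs_len <- nchar(pbs)
  if (pbs_len < 8 || pbs_len > 18) stop("tRNA 3' segment must be 8-18 nt",
                                        call. = FALSE)
  spacer1 <- 60L                    # PBS ... ORF leader
  if (orf_len > internal_len - pbs_len - spacer1 - 3L) {
    stop("orf_len too long for internal_len", call. = FALSE)
  }
  if (rt_len %% 3 != 0) stop("rt_len must be a multiple of 3", call. = FALSE)
  if (rt_len > orf_len - 6L) stop("rt_len too long for orf_len",
                                  call. = FALSE)
  ltr <- paste0("TGT", random_dna(ltr_len - 6L), "ACA")
  n_codons <- orf_len %/% 3L
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L, replace = TRUE)
  orf <- paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
  ## leader ends with an in-frame TAA so no upstream in-frame ATG extends
  ## the predicted ORF
  leader <- paste0(random_dna(spacer1 - 3L), "TAA")
  tail_len <- internal_len - pbs_len - spacer1 - orf_len
  internal <- paste0(pbs, leader, orf, random_dna(tail_len))
  stopifnot(nchar(internal) == internal_len)
  orf_start <- ltr_len + pbs_len + spacer1           # 0-based, full unit
  orf_interval <- iv(orf_start, orf_start + orf_len)
  rt_codon_off <- 3L * (((orf_len - 3L - rt_len) %/% 3L) %/% 2L)
  rt_start <- orf_start + 3L + rt_codon_off          # inside the ORF body
  rt_interval <- iv(rt_start, rt_start + rt_len)
  structure(list(ltr = ltr, internal = internal, pbs = pbs,
                 orf_interval = orf_interval, rt_interval = rt_interval,
                 trna_3prime = trna_3prime,
                 full_len = 2L * ltr_len + internal_len),
            class = "element_template")
}

#' Full-unit sequence of a template
#' @param template An `element_template`.
#' @return The `5'LTR + internal + 3'LTR` DNA string.
#' @export
template_full_seq <- function(template) {
  paste0(template$ltr, template$internal, template$ltr)
}

## ---- mutation engine -------------------------------------------------------

## Propose-and-accept substitution engine on a ragged-template copy.
## tpl: character vector, one entry per founding-template position.
## Positions whose entry is a single base are mutable; ORF codons are
## selected (stop-rejected, nonsyn accepted w.p. omega) when `selected`.
## Returns list(tpl, accepted, syn, nonsyn).
propose_substitutions <- function(tpl, n_prop, omega, kappa, orf_lo, orf_hi,
                                  selected) {
  accepted <- 0L; syn <- 0L; nonsyn <- 0L
  if (n_prop == 0L) return(list(tpl = tpl, accepted = 0L, syn = 0L,
                                nonsyn = 0L))
  L <- length(tpl)
  for (k in seq_len(n_prop)) {
    pos <- sample.int(L, 1L)
    cur <- tpl[pos]
    if (nchar(cur) != 1L || cur == "") next          # indel-touched position
    new <- mutate_base(cur, kappa)
    in_orf <- pos > orf_lo && pos <= orf_hi
    if (in_orf) {
      cidx <- (pos - 1L - orf_lo) %/% 3L
      cpos <- orf_lo + 3L * cidx + (1:3)
      cod <- tpl[cpos]
      if (all(nchar(cod) == 1L)) {                   # codon still clean
        old_codon <- paste(cod, collapse = "")
        cod[(pos - 1L - orf_lo) %% 3L + 1L] <- new
        new_codon <- paste(cod, collapse = "")
        old_aa <- GENETIC_CODE_TABLE[[old_codon]]
        new_aa <- GENETIC_CODE_TABLE[[new_codon]]
        if (selected) {
          if (new_aa == "*" && old_aa != "*") next   # stop-gain rejected
          if (new_aa != old_aa && stats::runif(1) > omega) next
        }
        if (new_aa == old_aa) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      }
    }
    tpl[pos] <- new
    accepted <- accepted + 1L
  }
  list(tpl = tpl, accepted = accepted, syn = syn, nonsyn = nonsyn)
}

## Apply indel events to a ragged-template copy.
apply_indels <- function(tpl, n_events, mean_len, protected) {
  for (k in seq_len(n_events)) {
    len <- stats::rgeom(1L, 1 / mean_len) + 1L
    pos <- sample.int(length(tpl), 1L)
    if (pos %in% protected) next
    if (stats::runif(1) < 0.5) {                     # deletion
      span <- pos:min(length(tpl), pos + len - 1L)
      span <- setdiff(span, protected)
      span <- span[nchar(tpl[span]) == 1L]
      tpl[span] <- ""
    } else {                                         # insertion after pos
      tpl[pos] <- paste0(tpl[pos], random_dna(len))
    }
  }
  tpl
}

## ---- burst simulation ------------------------------------------------------

#' Simulate a retrotransposon family burst into host contigs
#'
#' Implements a master-lineage expansion model: replication-competent master
#' copies spawn progeny with Poisson(`mu_r` * L) replication errors; all
#' resident copies then decay under host substitutions (`mu_h`) and indels.
#' Purifying selection (acceptance probability `omega` for nonsynonymous ORF
#' changes, rejection of stop gains) acts on master-competent lineages only.
#' Each insertion duplicates the 4-bp target site, so every copy is flanked
#' by identical TSDs, and both LTRs are identical at birth.
#'
#' @param template An `element_template`.
#' @param n_contigs Number of host contigs.
#' @param contig_len Initial length of each host contig (>= 10x the full
#'   element length).
#' @param evo An `evo_params` object.
#' @param seed Integer seed (overrides `evo$seed` if given).
#' @return A list of class `burst_sim` with elements `contigs` (named
#'   character vector of final host sequences), `truth` (data frame of
#'   insertion records; intervals 0-based half-open, excluding TSDs),
#'   `genealogy` (Newick string over all copy ids), `aligned` (the true
#'   multiple alignment of all copies on the element sense strand, a
#'   `copy_alignment`), and `template`.
#' @export
simulate_expansion <- function(template, n_contigs = 5L, contig_len = 60000L,
                               evo = evo_params(), seed = evo$seed) {
  set.seed(seed)
  full <- template_full_seq(template)
  L0 <- nchar(full)
  if (contig_len < 10L * L0) {
    stop("contig_len must be >= 10x the full element length", call. = FALSE)
  }
  kappa <- evo$ts_tv_ratio
  orf_lo <- template$orf_interval[1]; orf_hi <- template$orf_interval[2]
  protected <- if (evo$protect_rt) {
    (template$rt_interval[1] + 1L):template$rt_interval[2]
  } else integer(0)

  ## contigs as ordered part lists: host strings or copy ids
  contigs <- lapply(seq_len(n_contigs), function(i) {
    list(list(type = "host", seq = random_dna(contig_len)))
  })
  names(contigs) <- sprintf("contig%02d", seq_len(n_contigs))

  copies <- list()      # id -> state list
  masters <- character(0)
  root_tpl <- seq_chars(full)
  n_born <- 0L

  advance_copy <- function(cp, t) {
    dt <- t - cp$last_update
    if (dt <= 0) return(cp)
    Lc <- sum(nchar(cp$tpl))
    n_sub <- stats::rpois(1L, evo$mu_h * Lc * dt)
    res <- propose_substitutions(cp$tpl, n_sub, evo$omega, kappa,
                                 orf_lo, orf_hi, selected = cp$is_master)
    cp$tpl <- res$tpl
    if (evo$indel_rate > 0) {
      n_ind <- stats::rpois(1L, evo$indel_rate * dt)
      prot <- if (cp$is_master) {
        union(protected, (orf_lo + 1L):orf_hi)
      } else protected
      cp$tpl <- apply_indels(cp$tpl, n_ind, evo$indel_mean_len, prot)
    }
    cp$last_update <- t
    cp
  }

  insert_copy <- function(id, t) {
    ## pick a host part with room, weighted by length
    sites <- list()
    for (cn in names(contigs)) {
      for (pi in seq_along(contigs[[cn]])) {
        p <- contigs[[cn]][[pi]]
        if (p$type == "host" && nchar(p$seq) >= 12L) {
          sites[[length(sites) + 1L]] <- list(contig = cn, part = pi,
                                              len = nchar(p$seq))
        }
      }
    }
    if (length(sites) == 0) {
      stop("burst schedule demands more copies than available insertion sites",
           call. = FALSE)
    }
    w <- vapply(sites, `[[`, numeric(1), "len")
    s <- sites[[sample.int(length(sites), 1L, prob = w)]]
    host <- contigs[[s$contig]][[s$part]]$seq
    hl <- nchar(host)
    pos <- sample(4:(hl - 4L), 1L)                  # TSD = host[pos-3 .. pos]
    tsd <- substr(host, pos - 3L, pos)
    left <- substr(host, 1L, pos)
    right <- substr(host, pos - 3L, hl)             # re-includes the 4-mer
    newparts <- list(list(type = "host", seq = left),
                     list(type = "copy", id = id),
                     list(type = "host", seq = right))
    contigs[[s$contig]] <<- append(contigs[[s$contig]][-s$part], newparts,
                                   after = s$part - 1L)
    list(contig = s$contig, tsd = tsd)
  }

  for (ev in evo$burst_schedule) {
    t <- ev[1]; k <- as.integer(ev[2])
    for (j in seq_len(k)) {
      n_born <- n_born + 1L
      id <- sprintf("copy%03d", n_born)
      if (length(masters) == 0) {
        parent_id <- "root"
        parent_tpl <- root_tpl
        is_master <- TRUE                           # founder must replicate
      } else {
        parent_id <- sample(masters, 1L)
        copies[[parent_id]] <- advance_copy(copies[[parent_id]], t)
        parent_tpl <- copies[[parent_id]]$tpl
        is_master <- stats::runif(1) < evo$master_succession_p
      }
      ## reverse transcription regenerates both LTRs from one template:
      ## the daughter's LTR pair is identical at birth
      ltr_len <- nchar(template$ltr)
      child_tpl <- parent_tpl
      child_tpl[(L0 - ltr_len + 1L):L0] <- child_tpl[seq_len(ltr_len)]
      Lp <- sum(nchar(child_tpl))
      n_prop <- stats::rpois(1L, evo$mu_r * Lp)
      res <- propose_substitutions(child_tpl, n_prop, evo$omega, kappa,
                                   orf_lo, orf_hi, selected = is_master)
      site <- insert_copy(id, t)
      strand <- if (stats::runif(1) < evo$strand_minus_p) "-" else "+"
      copies[[id]] <- list(id = id, tpl = res$tpl, birth_time = t,
                           parent_id = parent_id, is_master = is_master,
                           strand = strand, contig = site$contig,
                           tsd = site$tsd, n_sub_birth = res$accepted,
                           last_update = t)
      if (is_master) masters <- c(masters, id)
    }
  }

  for (id in names(copies)) {
    copies[[id]] <- advance_copy(copies[[id]], evo$end_time)
  }

  ## materialize contigs and final coordinates
  truth <- list()
  final <- character(length(contigs))
  names(final) <- names(contigs)
  for (cn in names(contigs)) {
    pos <- 0L
    pieces <- character(0)
    for (p in contigs[[cn]]) {
      if (p$type == "host") {
        pieces <- c(pieces, p$seq)
        pos <- pos + nchar(p$seq)
      } else {
        cp <- copies[[p$id]]
        s <- paste(cp$tpl, collapse = "")
        if (cp$strand == "-") s <- revcomp(s)
        truth[[p$id]] <- data.frame(
          copy_id = p$id, contig_id = cn, start = pos, end = pos + nchar(s),
          strand = cp$strand, tsd = cp$tsd, parent_id = cp$parent_id,
          birth_time = cp$birth_time,
          n_substitutions_at_birth = cp$n_sub_birth,
          is_master = cp$is_master, stringsAsFactors = FALSE)
        pieces <- c(pieces, s)
        pos <- pos + nchar(s)
      }
    }
    final[[cn]] <- paste(pieces, collapse = "")
  }
  truth <- do.call(rbind, truth[order(names(truth))])
  rownames(truth) <- NULL

  ## true alignment on the sense strand, by ragged-template construction
  ids <- truth$copy_id
  widths <- rep(1L, L0)
  for (id in ids) widths <- pmax(widths, nchar(copies[[id]]$tpl))
  aligned <- vapply(ids, function(id) {
    tp <- copies[[id]]$tpl
    pad <- widths - nchar(tp)
    paste(paste0(tp, strrep("-", pad)), collapse = "")
  }, character(1))
  names(aligned) <- ids
  aln <- if (length(ids) >= 2) copy_alignment(aligned, "full") else NULL

  structure(list(contigs = final, truth = truth,
                 genealogy = genealogy_newick(truth, evo$end_time),
                 aligned = aln, template = template),
            class = "burst_sim")
}

## Newick genealogy from parent links; every copy is a tip sampled at
## end_time, with internal nodes at the birth of each child. Children of one
## parent may share a birth time (one burst), giving zero-length internal
## branches.
genealogy_newick <- function(truth, end_time) {
  kids <- split(truth[, c("copy_id", "birth_time")], truth$parent_id)
  kids <- lapply(kids, function(k) k[order(k$birth_time), , drop = FALSE])
  lineage <- function(id, from, remaining) {
    if (is.null(remaining) || nrow(remaining) == 0) {
      return(sprintf("%s:%g", id, end_time - from))
    }
    t1 <- remaining$birth_time[1]
    child <- remaining$copy_id[1]
    sprintf("(%s,%s):%g",
            lineage(id, t1, remaining[-1, , drop = FALSE]),
            lineage(child, t1, kids[[child]]),
            t1 - from)
  }
  founders <- kids[["root"]]
  t0 <- founders$birth_time[1]
  parts <- vapply(seq_len(nrow(founders)), function(i) {
    id <- founders$copy_id[i]
    lineage(id, t0, kids[[id]])
  }, character(1))
  if (length(parts) == 1) {
    ## single founder: its lineage already forms the whole tree
    paste0(sub(":[0-9.eE+-]+$", "", parts), ";")
  } else {
    paste0("(", paste(parts, collapse = ","), ");")
  }
}

#' Write simulator outputs to disk
#'
#' Writes `genome.fasta`, `truth.json`, `truth.bed` (BED3 + name + score +
#' strand), `genealogy.nwk` and `copies_aligned.fasta` into `out_dir`.
#'
#' @param sim A `burst_sim`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
save_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$contigs, file.path(out_dir, "genome.fasta"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  bed <- data.frame(chrom = sim$truth$contig_id, start = sim$truth$start,
                    end = sim$truth$end, name = sim$truth$copy_id,
                    score = 0L, strand = sim$truth$strand)
  utils::write.table(bed, file.path(out_dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sim$genealogy, file.path(out_dir, "genealogy.nwk"))
  if (!is.null(sim$aligned)) {
    write_fasta(sim$aligned$seqs, file.path(out_dir, "copies_aligned.fasta"))
  }
  invisible(out_dir)
}

## ---- neutral alignments ----------------------------------------------------

#' Simulate a neutral alignment on a star or coalescent genealogy
#'
#' Infinite-sites-style mutations (each mutation hits a previously unmutated
#' site) are placed on either a star genealogy (all tips radiate from the
#' ancestor, the signature of a transposition burst) or a Kingman coalescent
#' (the neutral-panmixia calibration control). Time is scaled in 2N units so
#' the expected number of segregating sites is `theta * a1(n)` in both modes;
#' the star tree's total branch length matches the coalescent expectation.
#'
#' @param n Number of sequences (>= 2).
#' @param L Alignment length in bp.
#' @param genealogy `"star"` or `"coalescent"`.
#' @param theta Population-scaled mutation rate per locus.
#' @param seed Integer seed.
#' @return A `copy_alignment` of `n` ungapped sequences of length `L`.
#' @export
simulate_neutral_alignment <- function(n, L, genealogy = c("star",
                                                           "coalescent"),
                                       theta, seed = 1L) {
  genealogy <- match.arg(genealogy)
  stopifnot(n >= 2, L >= 1, theta > 0)
  set.seed(seed)
  a1 <- sum(1 / seq_len(n - 1))
  ## branch lengths per tip-set carrying each mutation
  if (genealogy == "star") {
    bl <- rep(2 * a1 / n, n)
    carriers <- as.list(seq_len(n))
  } else {
    lineages <- as.list(seq_len(n))
    t <- 0
    bl <- numeric(0)
    carriers <- list()
    born <- rep(0, n)                      # time each active lineage started
    repeat {
      k <- length(lineages)
      if (k == 1) break
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
      pick <- sample.int(k, 2)
      for (i in pick) {
        bl <- c(bl, t - born[i])
        carriers[[length(carriers) + 1L]] <- lineages[[i]]
      }
      merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
      lineages <- c(lineages[-pick], list(merged))
      born <- c(born[-pick], t)
    }
  }
  n_mut <- stats::rpois(length(bl), theta / 2 * bl)
  S <- sum(n_mut)
  if (S > L) stop("more mutations than sites; increase L", call. = FALSE)
  anc <- sample(DNA_BASES, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  sites <- sample.int(L, S)
  si <- 1L
  for (b in seq_along(n_mut)) {
    for (j in seq_len(n_mut[b])) {
      s <- sites[si]; si <- si + 1L
      derived <- sample(setdiff(DNA_BASES, anc[s]), 1L)
      m[carriers[[b]], s] <- derived
    }
  }
  seqs <- stats::setNames(apply(m, 1, paste, collapse = ""),
                          sprintf("t%02d", seq_len(n)))
  copy_alignment(seqs, "full")
}

#' Simulate a star-genealogy codon family under purifying selection
#'
#' Lightweight companion to [simulate_expansion()] for selection-recovery
#' experiments: each of `n` copies independently accumulates
#' Poisson(`subs_per_copy`) proposed substitutions on the given in-frame ORF
#' segment, filtered by the same acceptance rule the burst simulator applies
#' to master-competent lineages (stop gains rejected; nonsynonymous changes
#' accepted with probability `omega`).
#'
#' @param orf_seq In-frame, stop-free DNA string (length divisible by 3).
#' @param n Number of copies.
#' @param subs_per_copy Expected number of proposed substitutions per copy.
#' @param omega Nonsynonymous acceptance probability in `[0, 1]`.
#' @param ts_tv_ratio Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return A `copy_alignment` with `region_label = "RT"`.
#' @export
simulate_codon_family <- function(orf_seq, n, subs_per_copy, omega = 1,
                                  ts_tv_ratio = 2, seed = 1L) {
  stopifnot(nchar(orf_seq) %% 3 == 0, n >= 2)
  if (any(codon_split(orf_seq) %in% STOP_CODONS)) {
    stop("orf_seq must be stop-free", call. = FALSE)
  }
  set.seed(seed)
  Lb <- nchar(orf_seq)
  seqs <- vapply(seq_len(n), function(i) {
    res <- propose_substitutions(seq_chars(orf_seq),
                                 stats::rpois(1L, subs_per_copy),
                                 omega, ts_tv_ratio, orf_lo = 0L,
                                 orf_hi = Lb, selected = TRUE)
    paste(res$tpl, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("copy%03d", seq_len(n))
  copy_alignment(seqs, "RT")
}
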