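# Subcommand pipeline chaining the stages, plus the `rbd` CLI entry point.

#' Run a pipeline stage
#'
#' Deterministic given `config$seed`; every stage logs its parameters and
#' writes its artifacts into `out_dir`.
#'
#' Subcommands and their required `inputs` entries:
#' \describe{
#'   \item{simulate}{`families`, `copies` (per family); optional
#'     `n_contigs`, `contig_len`. Writes `genome.fasta`, per-family truth
#'     and alignments.}
#'   \item{annotate}{`genome` (FASTA), `seeds` (BED). Writes
#'     `elements.tsv`.}
#'   \item{consensus}{`alignment` (aligned FASTA); optional `groups` (TSV),
#'     `trna` (FASTA). Writes `consensus.fasta`, `orf_protein.fasta`,
#'     `families.tsv`, `pbs.tsv`.}
#'   \item{stats}{`alignment`; optional `groups`. Writes
#'     `stats_pairwise.tsv`, `stats_neutrality.tsv`, `stats_saturation.tsv`,
#'     `pdist_matrix.tsv`, `window_profile.tsv`.}
#'   \item{dnds}{`alignment` (codon alignment); optional `groups`. Writes
#'     `dnds_pairs.tsv`, `dnds_groups.tsv`, `dnds_tests.tsv`.}
#'   \item{tree}{`alignment`; optional `groups`. Writes `tree.nwk`,
#'     `monophyly.tsv`.}
#'   \item{all}{Runs simulate, then annotate/consensus/stats/dnds/tree on
#'     the simulated data.}
#' }
#'
#' @param config A [pipeline_config()].
#' @param subcommand One of the stages above.
#' @param inputs Named list of stage inputs.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, subcommand, inputs = list(),
                         out_dir = ".") {
  sub_ok <- c("simulate", "annotate", "consensus", "stats", "dnds", "tree",
              "all")
  if (!subcommand %in% sub_ok) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(sub_ok, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key, flag) {
    if (is.null(inputs[[key]])) {
      stop("missing required input --", flag, " for '", subcommand, "'",
           call. = FALSE)
    }
    inputs[[key]]
  }
  rb_log("stage ", subcommand, " (seed ", config$seed, ") -> ", out_dir)
  arts <- list()

  if (subcommand %in% c("simulate", "all")) {
    fam <- as.integer(inputs$families %||% 2L)
    copies <- as.integer(inputs$copies %||% 10L)
    n_contigs <- as.integer(inputs$n_contigs %||% 5L)
    contig_len <- as.integer(inputs$contig_len %||% 60000L)
    contigs <- character(0)
    truth <- list()
    for (f in seq_len(fam)) {
      fseed <- config$seed * 1000L + f
      tpl <- make_template(seed = fseed)
      ev <- evo_params(burst_schedule = list(c(0, copies)), seed = fseed)
      sim <- simulate_expansion(tpl, n_contigs = n_contigs,
                                contig_len = contig_len, evo = ev)
      if (f == 1L) rt_iv <- tpl$rt_interval
      names(sim$contigs) <- sprintf("fam%d_%s", f, names(sim$contigs))
      sim$truth$contig_id <- sprintf("fam%d_%s", f, sim$truth$contig_id)
      sim$truth$copy_id <- sprintf("fam%d_%s", f, sim$truth$copy_id)
      sim$truth$family <- sprintf("F%d", f)
      contigs <- c(contigs, sim$contigs)
      truth[[f]] <- sim$truth
      names(sim$aligned$seqs) <- sprintf("fam%d_%s", f,
                                         names(sim$aligned$seqs))
      write_fasta(sim$aligned$seqs,
                  file.path(out_dir, sprintf("fam%d_aligned.fasta", f)))
      writeLines(sim$genealogy,
                 file.path(out_dir, sprintf("fam%d_genealogy.nwk", f)))
    }
    truth <- do.call(rbind, truth)
    write_fasta(contigs, file.path(out_dir, "genome.fasta"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    bed <- data.frame(chrom = truth$contig_id, start = truth$start,
                      end = truth$end, name = truth$copy_id, score = 0L,
                      strand = truth$strand)
    utils::write.table(bed, file.path(out_dir, "truth.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    rb_log("simulated ", nrow(truth), " copies in ", fam, " family(ies)")
    arts$genome <- file.path(out_dir, "genome.fasta")
    arts$truth_bed <- file.path(out_dir, "truth.bed")
  }

  if (subcommand %in% c("annotate", "all")) {
    if (subcommand == "all") {
      genome <- read_fasta(arts$genome)
      bed <- utils::read.delim(arts$truth_bed, header = FALSE)
      seeds <- data.frame(contig = bed[[1]],
                          start = (bed[[2]] + bed[[3]]) %/% 2L,
                          end = (bed[[2]] + bed[[3]]) %/% 2L + 1L)
    } else {
      genome <- read_fasta(need("genome", "genome"))
      bed <- utils::read.delim(need("seeds", "seeds"), header = FALSE)
      seeds <- data.frame(contig = bed[[1]], start = bed[[2]], end = bed[[3]])
    }
    ann <- annotate_genome(genome, seeds, config)
    out <- ann$elements
    if (is.null(out)) out <- data.frame()
    write_tsv_report(out, file.path(out_dir, "elements.tsv"))
    rb_log(if (is.null(ann$elements)) 0 else nrow(ann$elements),
           " element(s) annotated; ",
           if (is.null(ann$unresolved)) 0 else nrow(ann$unresolved),
           " unresolved seed(s)")
    arts$elements <- file.path(out_dir, "elements.tsv")
  }

  if (subcommand %in% c("consensus", "stats", "dnds", "tree", "all")) {
    aln <- if (subcommand == "all") {
      read_alignment(file.path(out_dir, "fam1_aligned.fasta"))
    } else {
      read_alignment(need("alignment", "alignment"),
                     groups = inputs$groups,
                     region_label = inputs$region_label %||% "full")
    }

    if (subcommand %in% c("consensus", "all")) {
      cons <- build_consensus(aln)
      write_fasta(c(consensus = cons), file.path(out_dir, "consensus.fasta"))
      orf <- find_orf(cons)
      if (!is.null(orf)) {
        write_fasta(c(orf_protein = orf$protein),
                    file.path(out_dir, "orf_protein.fasta"))
      }
      copies <- stats::setNames(gsub("-", "", aln$seqs), names(aln$seqs))
      fams <- cluster_families(copies, threshold = config$family_threshold)
      write_tsv_report(data.frame(copy_id = names(fams$families),
                                  family = unname(fams$families)),
                       file.path(out_dir, "families.tsv"))
      trna_path <- inputs$trna %||% system.file("extdata",
                                                "trna_synthetic.fasta",
                                                package = "retroburst")
      ## PBS sits just 3' of the 5'-LTR: delimit the LTR pair on the
      ## consensus itself to anchor the scan
      ccand <- find_ltr_pairs(cons, termini_mismatch = config$termini_mismatch)
      ltr5_end <- if (length(ccand) > 0) ccand[[1]]$left[2] else 0L
      pbs <- locate_pbs(cons, ltr5_end = ltr5_end, trna_lib = trna_path)
      pbs_df <- if (is.null(pbs)) {
        data.frame(trna_id = NA_character_, offset = NA_integer_,
                   length = NA_integer_, mismatches = NA_integer_)
      } else as.data.frame(pbs)
      write_tsv_report(pbs_df, file.path(out_dir, "pbs.tsv"))
      arts$consensus <- file.path(out_dir, "consensus.fasta")
    }

    if (subcommand %in% c("stats", "all")) {
      set.seed(config$seed)
      pw <- pairwise_stats(aln)
      write_tsv_report(pw, file.path(out_dir, "stats_pairwise.tsv"))
      neut <- list()
      for (gl in unique(aln$groups)) {
        mem <- names(aln$groups)[aln$groups == gl]
        if (length(mem) < 4) next
        sub <- copy_alignment(aln$seqs[mem], aln$region_label)
        td <- tajimas_d(sub)
        fl <- fu_li(sub)
        neut[[gl]] <- data.frame(group = gl, n = length(mem),
                                 tajima_D = td$D, tajima_p = td$p_beta,
                                 fuli_D = fl$D, fuli_F = fl$F)
      }
      write_tsv_report(if (length(neut)) do.call(rbind, neut) else
                       data.frame(), file.path(out_dir,
                                               "stats_neutrality.tsv"))
      is_obs <- iss(aln, seed = config$seed)
      sat <- lapply(c("sym", "asym"), function(tp) {
        cr <- tryCatch(iss_critical(aln_nrow(aln), aln_ncol(aln), tp,
                                    reps = 100L, seed = config$seed,
                                    observed = is_obs),
                       error = function(e) NULL)
        if (is.null(cr)) return(data.frame(topology = tp, iss = is_obs$iss,
                                           iss_c = NA_real_, p = NA_real_))
        data.frame(topology = tp, iss = is_obs$iss, iss_c = cr$iss_c,
                   p = cr$p)
      })
      write_tsv_report(do.call(rbind, sat),
                       file.path(out_dir, "stats_saturation.tsv"))
      gp <- group_p_distance(aln, site_coverage = config$site_coverage,
                             boot = config$bootstrap_reps,
                             seed = config$seed)
      write_tsv_report(gp$table, file.path(out_dir, "pdist_matrix.tsv"))
      if (aln_ncol(aln) >= config$window) {
        wp <- sliding_divergence(aln, window = config$window,
                                 step = config$step)
        write_tsv_report(as.data.frame(wp),
                         file.path(out_dir, "window_profile.tsv"))
      }
      arts$stats <- file.path(out_dir, "stats_pairwise.tsv")
    }

    if (subcommand %in% c("dnds", "all")) {
      dnds_aln <- aln
      if (subcommand == "all") {
        ## RT core slice of the true alignment: codon-clean by construction
        dnds_aln <- aln_keep_columns(aln, (rt_iv[1] + 1L):rt_iv[2])
        dnds_aln$region_label <- "RT"
      }
      fam <- family_dnds(dnds_aln)
      write_tsv_report(fam$pairs, file.path(out_dir, "dnds_pairs.tsv"))
      write_tsv_report(fam$groups, file.path(out_dir, "dnds_groups.tsv"))
      write_tsv_report(dnds_group_tests(fam),
                       file.path(out_dir, "dnds_tests.tsv"))
      arts$dnds <- file.path(out_dir, "dnds_groups.tsv")
    }

    if (subcommand %in% c("tree", "all")) {
      bs <- bootstrap_support(aln, reps = min(config$bootstrap_reps, 200L),
                              seed = config$seed)
      ape::write.tree(bs$tree, file.path(out_dir, "tree.nwk"))
      mono <- check_monophyly(bs$tree, aln$groups)
      write_tsv_report(as.data.frame(mono),
                       file.path(out_dir, "monophyly.tsv"))
      arts$tree <- file.path(out_dir, "tree.nwk")
    }
  }
  invisible(arts)
}

#' Command-line entry point (`rbd`)
#'
#' Parses `rbd <subcommand> [--flag value ...]` argument vectors. Global
#' flags: `--config` (flat key = value file), `--seed`, `--out-dir`,
#' `--log-level`. Remaining flags become stage inputs (e.g. `--genome`,
#' `--seeds`, `--alignment`, `--groups`, `--families`, `--copies`).
#'
#' @param argv Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
rbd_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: rbd simulate|annotate|consensus|stats|dnds|tree|",
                  "all [--config FILE] [--seed N] [--out-dir DIR] ",
                  "[--log-level LEVEL] [--<input> VALUE ...]")
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv) == 0) 2L else 0L))
  }
  subcommand <- argv[1]
  rest <- argv[-1]
  if (length(rest) %% 2 != 0) {
    message("flags must come in --flag value pairs\n", usage)
    return(invisible(2L))
  }
  flags <- list()
  for (i in if (length(rest) >= 2) seq(1, length(rest) - 1, by = 2) else
       integer(0)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--")) {
      message("expected a --flag, got '", rest[i], "'\n", usage)
      return(invisible(2L))
    }
    flags[[gsub("-", "_", key)]] <- rest[i + 1]
  }
  status <- tryCatch({
    cfg <- if (!is.null(flags$config)) read_config(flags$config) else
      pipeline_config()
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    if (!is.null(flags$log_level)) {
      options(retroburst.log_level = flags$log_level)
    }
    out_dir <- flags$out_dir %||% "."
    inputs <- flags[setdiff(names(flags),
                            c("config", "seed", "out_dir", "log_level"))]
    set.seed(cfg$seed)
    run_pipeline(cfg, subcommand, inputs, out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
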