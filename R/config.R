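# Pipeline configuration: one flat key = value file (TOML syntax subset);
# every CLI flag overrides the file.

#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by the pipeline stages. All
#' fractions must lie in `[0, 1]`.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param tsd_len Target-site-duplication length in bp (canonical 4).
#' @param ltr_min_len,ltr_max_len LTR length search bounds in bp.
#' @param ltr_min_identity Minimum LTR-pair identity for a candidate repeat.
#' @param family_threshold Identity threshold for family designation (0.70,
#'   the conventional cutoff for retrotransposon families).
#' @param site_coverage Minimum fraction of non-missing rows for an alignment
#'   column to be retained in distance calculations (0.90).
#' @param bootstrap_reps Bootstrap replicates for SEs and tree support.
#' @param window,step Sliding-window size and step in bp.
#' @param alpha Significance level for reported tests.
#' @param max_unit_len Maximum full-unit element span considered by the
#'   annotator, bp.
#' @param termini_mismatch Mismatches tolerated across the 12 canonical
#'   terminal bases (TGT/ACA on both LTRs) during LTR-pair detection;
#'   decayed copies may have mutated termini.
#' @param min_contig_len Contigs shorter than this are skipped by the
#'   annotator (10 kb, guarding against assembly chimeras).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, tsd_len = 4L, ltr_min_len = 100L,
                            ltr_max_len = 1000L, ltr_min_identity = 0.8,
                            family_threshold = 0.70, site_coverage = 0.90,
                            bootstrap_reps = 1000L, window = 300L, step = 50L,
                            alpha = 0.05, max_unit_len = 8000L,
                            termini_mismatch = 1L, min_contig_len = 10000L) {
  cfg <- list(seed = as.integer(seed), tsd_len = as.integer(tsd_len),
              ltr_min_len = as.integer(ltr_min_len),
              ltr_max_len = as.integer(ltr_max_len),
              ltr_min_identity = ltr_min_identity,
              family_threshold = family_threshold,
              site_coverage = site_coverage,
              bootstrap_reps = as.integer(bootstrap_reps),
              window = as.integer(window), step = as.integer(step),
              alpha = alpha, max_unit_len = as.integer(max_unit_len),
              termini_mismatch = as.integer(termini_mismatch),
              min_contig_len = as.integer(min_contig_len))
  for (f in c("ltr_min_identity", "family_threshold", "site_coverage",
              "alpha")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$bootstrap_reps < 1) stop("bootstrap_reps must be >= 1",
                                   call. = FALSE)
  if (!(cfg$window >= cfg$step && cfg$step >= 1)) {
    stop("need window >= step >= 1", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key = value configuration file (TOML syntax subset)
#'
#' Only flat scalar assignments are supported: `key = value` with `#`
#' comments, quoted strings, numbers and booleans. Unknown keys are an error
#' so typos do not pass silently.
#'
#' @param path Config file path.
#' @param base A `pipeline_config` providing defaults for unset keys.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, base = pipeline_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      suppressWarnings(as.numeric(raw))
    }
    if (is.na(val[1]) && !is.character(val)) {
      stop("cannot parse config value for ", key, ": ", raw, call. = FALSE)
    }
    vals[[key]] <- val
  }
  unknown <- setdiff(names(vals), names(unclass(base)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- utils::modifyList(unclass(base), vals)
  do.call(pipeline_config, args)
}
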