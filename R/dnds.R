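# Uncorrected counting dN/dS on codon alignments: synonymous and
# nonsynonymous changes are tallied directly from codon differences
# (pathway-averaged for multi-hit codons, stop-avoiding), with pairwise
# removal of gap/stop codons, no multiple-hit correction and no site
# normalization.

## memoised 61x61 pathway-count table, built lazily
.dnds_cache <- new.env(parent = emptyenv())

codon_counts_pathways <- function(a, b, skip_multi_hit = FALSE) {
  achars <- seq_chars(a)
  bchars <- seq_chars(b)
  diffpos <- which(achars != bchars)
  h <- length(diffpos)
  if (h == 0) return(c(sd = 0, nd = 0))
  if (h == 1) {
    syn <- GENETIC_CODE_TABLE[[a]] == GENETIC_CODE_TABLE[[b]]
    return(if (syn) c(sd = 1, nd = 0) else c(sd = 0, nd = 1))
  }
  if (skip_multi_hit) return(c(sd = NA_real_, nd = NA_real_))
  ## enumerate all orderings of the differing positions; each ordering is a
  ## minimal mutational pathway
  perms <- if (h == 2) list(diffpos, rev(diffpos)) else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
    lapply(idx, function(o) diffpos[o])
  }
  walk <- function(order) {
    cur <- achars
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- bchars[pos]
      c_from <- paste(cur, collapse = "")
      c_to <- paste(nxt, collapse = "")
      aa_from <- GENETIC_CODE_TABLE[[c_from]]
      aa_to <- GENETIC_CODE_TABLE[[c_to]]
      if (aa_to == "*" && !identical(pos, order[length(order)])) {
        return(NULL)                        # pathway through a stop codon
      }
      if (aa_to == "*" || aa_from == "*") {
        ## endpoint stops only arise in fallback mode; count as nonsyn
        nd <- nd + 1
      } else if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(res) == 0) {
    ## all pathways pass through stops: fall back to all pathways
    res <- lapply(perms, function(order) {
      cur <- achars; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- bchars[pos]
        aa_from <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
        aa_to <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
        if (aa_from == aa_to && aa_from != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Synonymous/nonsynonymous change counts for one codon pair
#'
#' Counting is conceptually that of Nei & Gojobori: a single difference is
#' classified by the genetic code; for 2-3 differences the synonymous and
#' nonsynonymous step counts are averaged over all minimal mutational
#' pathways, each weighted equally, excluding pathways that pass through a
#' stop codon (all pathways are used if every one hits a stop). The counts
#' are left uncorrected: no multiple-hit correction and no normalization by
#' synonymous/nonsynonymous site numbers.
#'
#' @param a,b Sense codons (3-mers over A,C,G,T; no stop codons).
#' @param skip_multi_hit If TRUE, codon pairs with 2-3 differences return NA
#'   instead of pathway-averaged counts (the strict alternative).
#' @return Named numeric `c(sd, nd)`; `sd + nd` equals the nucleotide
#'   difference count of the pair.
#' @export
codon_change_counts <- function(a, b, skip_multi_hit = FALSE) {
  stopifnot(nchar(a) == 3, nchar(b) == 3)
  if (a %in% STOP_CODONS || b %in% STOP_CODONS) {
    stop("stop codons must be removed before counting", call. = FALSE)
  }
  key <- paste0(a, b, if (skip_multi_hit) "s" else "")
  hit <- .dnds_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_counts_pathways(a, b, skip_multi_hit)
  assign(key, val, envir = .dnds_cache)
  val
}

#' Pairwise dN/dS counts for two codon rows
#'
#' Codon positions where either row has a gap, `N`, or a stop codon are
#' excluded for that pair only (pairwise deletion of disrupted codons);
#' remaining codon pairs are summed with [codon_change_counts()]. The ratio
#' is the raw count quotient `nd/sd`, undefined when `sd = 0`.
#'
#' @param row_a,row_b Equal-length in-frame aligned sequences (length
#'   divisible by 3).
#' @param skip_multi_hit Passed to [codon_change_counts()].
#' @return List with `nd`, `sd`, `ratio` (NA when undefined),
#'   `codons_compared`, `excluded_codons`, `empty` flag.
#' @export
pair_dnds <- function(row_a, row_b, skip_multi_hit = FALSE) {
  stopifnot(nchar(row_a) == nchar(row_b), nchar(row_a) %% 3 == 0)
  ca <- codon_split(row_a)
  cb <- codon_split(row_b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
           !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  excluded <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) == 0) {
    return(list(nd = NA_real_, sd = NA_real_, ratio = NA_real_,
                codons_compared = 0L, excluded_codons = excluded,
                empty = TRUE))
  }
  nd <- 0; sd <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    cc <- codon_change_counts(ca[i], cb[i], skip_multi_hit)
    if (anyNA(cc)) next                     # skipped multi-hit codon
    sd <- sd + cc[["sd"]]
    nd <- nd + cc[["nd"]]
  }
  list(nd = nd, sd = sd, ratio = if (sd > 0) nd / sd else NA_real_,
       codons_compared = length(ca), excluded_codons = excluded,
       empty = FALSE)
}

#' Per-family dN/dS ratio distributions
#'
#' All intra-group pairwise `nd/sd` ratios are pooled per group (as in
#' box-plot summaries of paralogous copy sets); pairs with `sd = 0` are
#' excluded from the distribution and reported as a count.
#'
#' @param alignment A `copy_alignment` with `region_label = "RT"` (or any
#'   in-frame codon alignment).
#' @param groups Optional group map (defaults to the alignment's).
#' @param skip_multi_hit Passed to [pair_dnds()].
#' @return List with `pairs` (data frame of all intra-group pairs) and
#'   `groups` (data frame: group, n_pairs, n_undefined, median, q1, q3,
#'   flagged when no ratio is defined).
#' @export
family_dnds <- function(alignment, groups = NULL, skip_multi_hit = FALSE) {
  stopifnot(inherits(alignment, "copy_alignment"))
  groups <- groups %||% alignment$groups
  ids <- names(alignment$seqs)
  g <- groups[ids]
  rows <- list()
  for (gl in sort(unique(g))) {
    mem <- ids[g == gl]
    if (length(mem) < 2) next
    for (i in 1:(length(mem) - 1)) {
      for (j in (i + 1):length(mem)) {
        pd <- pair_dnds(alignment$seqs[[mem[i]]], alignment$seqs[[mem[j]]],
                        skip_multi_hit)
        rows[[length(rows) + 1L]] <- data.frame(
          group = gl, id_a = mem[i], id_b = mem[j], nd = pd$nd, sd = pd$sd,
          ratio = pd$ratio, codons_compared = pd$codons_compared,
          excluded_codons = pd$excluded_codons, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group = character(0), id_a = character(0),
               id_b = character(0), nd = numeric(0), sd = numeric(0),
               ratio = numeric(0), codons_compared = integer(0),
               excluded_codons = integer(0))
  gs <- lapply(split(pairs, pairs$group), function(df) {
    def <- df$ratio[!is.na(df$ratio)]
    q <- if (length(def) > 0) stats::quantile(def, c(0.25, 0.5, 0.75),
                                              names = FALSE) else rep(NA_real_, 3)
    data.frame(group = df$group[1], n_pairs = nrow(df),
               n_undefined = sum(is.na(df$ratio)), median = q[2], q1 = q[1],
               q3 = q[3], all_undefined = length(def) == 0,
               stringsAsFactors = FALSE)
  })
  groups_df <- if (length(gs) > 0) do.call(rbind, gs) else
    data.frame(group = character(0), n_pairs = integer(0),
               n_undefined = integer(0), median = numeric(0), q1 = numeric(0),
               q3 = numeric(0), all_undefined = logical(0))
  rownames(groups_df) <- NULL
  list(pairs = pairs, groups = groups_df)
}

#' Mann-Whitney U test for two ratio distributions
#'
#' Exact enumeration (via the null U distribution) when both samples have at
#' most 10 observations and there are no ties; otherwise the normal
#' approximation with tie correction. Two-sided throughout.
#'
#' @param ratios_a,ratios_b Non-empty numeric vectors.
#' @return List of class `mwu_result`: `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(ratios_a, ratios_b) {
  if (length(ratios_a) == 0 || length(ratios_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ratios_a <- ratios_a[!is.na(ratios_a)]
  ratios_b <- ratios_b[!is.na(ratios_b)]
  if (length(ratios_a) == 0 || length(ratios_b) == 0) {
    stop("both groups must contain defined values", call. = FALSE)
  }
  n1 <- length(ratios_a); n2 <- length(ratios_b)
  all_v <- c(ratios_a, ratios_b)
  r <- rank(all_v)
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2              # U of sample a
  ties <- any(duplicated(all_v))
  if (!ties && n1 <= 10 && n2 <= 10) {
    ## exact: two-sided via the null distribution of U
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(all_v)
    nn <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0 || U == mu) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-with-ties"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "mwu_result")
}

#' Pairwise group comparisons of dN/dS distributions
#'
#' Runs [mann_whitney()] on every pair of groups with defined ratios and
#' attaches significance tiers (`*` 0.05-0.01, `**` 0.01-0.001, `***`
#' < 0.001).
#'
#' @param fam Output of [family_dnds()].
#' @return Data frame: group_a, group_b, U, p, stars.
#' @export
dnds_group_tests <- function(fam) {
  sp <- split(fam$pairs$ratio, fam$pairs$group)
  sp <- lapply(sp, function(v) v[!is.na(v)])
  sp <- sp[lengths(sp) > 0]
  gl <- names(sp)
  rows <- list()
  if (length(gl) >= 2) {
    for (i in 1:(length(gl) - 1)) {
      for (j in (i + 1):length(gl)) {
        mw <- mann_whitney(sp[[gl[i]]], sp[[gl[j]]])
        stars <- if (mw$p < 0.001) "***" else if (mw$p < 0.01) "**" else
                 if (mw$p < 0.05) "*" else ""
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = gl[i], group_b = gl[j], U = mw$U, p = mw$p,
          stars = stars, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group_a = character(0), group_b = character(0),
               U = numeric(0), p = numeric(0), stars = character(0))
}
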