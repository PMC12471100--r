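# Entropy-based index of substitution saturation (Iss) and Monte-Carlo
# critical values (Iss.c) under symmetrical and extremely asymmetrical tree
# topologies.

## expected per-site entropy (bits) of a fully saturated column: n draws
## from a multinomial over the base frequencies.
## Exact enumeration over compositions for n <= 12, Monte Carlo otherwise.
full_saturation_entropy <- function(n, freqs, mc_draws = 10000L, seed = 1L) {
  freqs <- freqs / sum(freqs)
  col_entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  if (n <= 12L) {
    tot <- 0
    for (a in 0:n) for (c in 0:(n - a)) for (g in 0:(n - a - c)) {
      t <- n - a - c - g
      cnt <- c(a, c, g, t)
      pr <- stats::dmultinom(cnt, prob = freqs)
      tot <- tot + pr * col_entropy(cnt)
    }
    tot
  } else {
    set.seed(seed)
    draws <- stats::rmultinom(mc_draws, n, freqs)
    mean(apply(draws, 2, col_entropy))
  }
}

#' Entropy-based index of substitution saturation (Iss)
#'
#' Per-site entropies `H = -sum p_i log2 p_i` over the A/C/G/T counts of each
#' column (gaps and `N` excluded) are averaged and scaled by the expected
#' per-site entropy at full saturation (`H_fss`) given `n` and the
#' alignment's global base frequencies. An invariant alignment has Iss = 0;
#' a fully randomized one has Iss ~ 1. Iss significantly below its critical
#' value Iss.c (see [iss_critical()]) indicates substitutions are not
#' saturated and the alignment retains phylogenetic signal.
#'
#' @param alignment A `copy_alignment` (>= 2 rows; >= 4 recommended).
#' @param mc_draws Monte-Carlo draws for `H_fss` when `n > 12`.
#' @param seed Seed for the Monte-Carlo `H_fss` estimate.
#' @return List with `iss`, `h_mean`, `h_fss`, `se` (SE of Iss over sites),
#'   `site_entropy` (per-site vector), `n`, `L`.
#' @export
iss <- function(alignment, mc_draws = 10000L, seed = 1L) {
  stopifnot(inherits(alignment, "copy_alignment"))
  im <- aln_int_matrix(alignment$seqs)
  n <- nrow(im)
  L <- ncol(im)
  h <- column_entropies(im)
  freqs <- vapply(1:4, function(k) sum(im == k, na.rm = TRUE), numeric(1))
  freqs <- freqs / sum(freqs)
  hfss <- full_saturation_entropy(n, freqs, mc_draws = mc_draws, seed = seed)
  iss_val <- mean(h) / hfss
  list(iss = iss_val, h_mean = mean(h), h_fss = hfss,
       se = stats::sd(h) / sqrt(L) / hfss, site_entropy = h, n = n, L = L)
}

## simulate a Jukes-Cantor alignment (integer matrix) on a tree given as an
## edge list; returns n x L integer matrix
jc_sim_matrix <- function(topology = c("sym", "asym"), n_tips, L, b) {
  topology <- match.arg(topology)
  evolve <- function(seq, t) {
    p_sub <- 0.75 * (1 - exp(-4 * t / 3))
    hit <- stats::runif(L) < p_sub
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      seq[hit] <- (seq[hit] - 1L + shift) %% 4L + 1L
    }
    seq
  }
  root <- sample.int(4L, L, replace = TRUE)
  tips <- matrix(0L, n_tips, L)
  if (topology == "sym") {
    ## balanced ultrametric tree, every edge of length b
    grow <- function(seq, k) {
      if (k == 1L) return(list(seq))
      c(grow(evolve(seq, b), k %/% 2L), grow(evolve(seq, b), k %/% 2L))
    }
    res <- grow(root, n_tips)
    for (i in seq_len(n_tips)) tips[i, ] <- res[[i]]
  } else {
    ## extremely asymmetrical: ultrametric caterpillar with internal edges
    ## of length b; early-diverging tips carry long terminal branches, so
    ## topology recovery degrades sooner than on the balanced tree
    spine <- root
    for (i in seq_len(n_tips - 1L)) {
      spine <- evolve(spine, b)
      tips[i, ] <- evolve(spine, (n_tips - i) * b)
    }
    tips[n_tips, ] <- evolve(spine, b)
  }
  tips
}

## per-column entropies of an integer-coded alignment (NA = missing);
## columns with < 2 observed states contribute 0
column_entropies <- function(m) {
  cnt <- vapply(1:4, function(k) colSums(m == k, na.rm = TRUE),
                numeric(ncol(m)))
  tot <- rowSums(cnt)
  p <- cnt / pmax(tot, 1)
  lp <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(lp)
  h[tot < 2] <- 0
  h
}

## integer-matrix alignment -> Iss (shared with iss(); hfss passed in)
iss_of_matrix <- function(m, hfss) {
  mean(column_entropies(m)) / hfss
}

## true and inferred splits for recovery scoring
matrix_splits <- function(phy) {
  phy <- ape::unroot(phy)
  sp <- ape::prop.part(phy)
  labs <- attr(sp, "labels")
  anchor <- min(labs)
  keys <- vapply(sp, function(x) {
    side <- sort(labs[x])
    if (anchor %in% side) side <- sort(setdiff(labs, side))
    paste(side, collapse = ",")
  }, character(1))
  setdiff(unique(keys), "")
}

#' Monte-Carlo critical value of Iss (Iss.c)
#'
#' Alignments are simulated under Jukes-Cantor on a balanced (`sym`) or
#' pectinate, extremely asymmetrical (`asym`) topology across a grid of
#' branch lengths. At each divergence level the observed Iss and the
#' proportion of replicates in which neighbor-joining recovers the true
#' topology are recorded; Iss.c is the Iss level at which recovery drops
#' below 95%, linearly interpolated on the grid. The returned test compares
#' an observed Iss against Iss.c with a two-tailed t statistic.
#'
#' @param n Number of sequences in the alignment being assessed (>= 4). The
#'   simulation uses the largest power of two <= min(n, 16) taxa.
#' @param L Alignment length.
#' @param topology `"sym"` or `"asym"`.
#' @param reps Replicates per grid point (>= 100).
#' @param seed Integer seed.
#' @param observed Optional list from [iss()] (fields `iss` and `se`); when
#'   given, the t-test of Iss against Iss.c is included.
#' @param grid Branch-length grid; default spans near-zero to saturated.
#' @return List with `iss_c`, `se`, `topology`, `grid` (data frame of branch
#'   length, mean Iss, recovery), and when `observed` is given `t`, `p` and
#'   `saturated` (TRUE when observed Iss >= Iss.c).
#' @export
iss_critical <- function(n, L, topology = c("sym", "asym"), reps = 200L,
                         seed = 1L, observed = NULL,
                         grid = exp(seq(log(0.05), log(3), length.out = 10))) {
  topology <- match.arg(topology)
  stopifnot(n >= 4, reps >= 100)
  set.seed(seed)
  n_tips <- 2L^max(2L, min(floor(log2(min(n, 16L))), 4L))
  hfss <- full_saturation_entropy(n_tips, rep(0.25, 4))
  true_phy <- if (topology == "sym") {
    counter <- 0L
    bal <- function(k) {
      if (k == 1L) {
        counter <<- counter + 1L
        return(sprintf("t%d", counter))
      }
      paste0("(", bal(k %/% 2L), ",", bal(k %/% 2L), ")")
    }
    ape::read.tree(text = paste0(bal(n_tips), ";"))
  } else {
    txt <- sprintf("t%d", n_tips)
    for (i in (n_tips - 1L):1L) txt <- sprintf("(t%d,%s)", i, txt)
    ape::read.tree(text = paste0(txt, ";"))
  }
  true_splits <- matrix_splits(true_phy)
  res <- lapply(grid, function(b) {
    iss_vals <- numeric(reps)
    rec <- logical(reps)
    for (r in seq_len(reps)) {
      m <- jc_sim_matrix(topology, n_tips, L, b)
      iss_vals[r] <- iss_of_matrix(m, hfss)
      p <- vapply(seq_len(n_tips), function(i) vapply(seq_len(n_tips),
        function(j) mean(m[i, ] != m[j, ]), numeric(1)), numeric(n_tips))
      ## JC correction, capped where saturated
      dmat <- ifelse(p >= 0.7499, 5, -0.75 * log(1 - 4 * pmin(p, 0.7499) / 3))
      dimnames(dmat) <- list(sprintf("t%d", 1:n_tips),
                             sprintf("t%d", 1:n_tips))
      phy <- neighbor_joining(dmat)
      rec[r] <- setequal(matrix_splits(phy), true_splits)
    }
    c(iss = mean(iss_vals), iss_sd = stats::sd(iss_vals),
      recovery = mean(rec))
  })
  gr <- data.frame(b = grid, t(vapply(res, identity, numeric(3))))
  below <- which(gr$recovery < 0.95)
  if (length(below) == 0 || below[1] == 1) {
    stop("recovery criterion not bracketed; widen the branch-length grid",
         call. = FALSE)
  }
  i2 <- below[1]; i1 <- i2 - 1L
  w <- (0.95 - gr$recovery[i1]) / (gr$recovery[i2] - gr$recovery[i1])
  iss_c <- gr$iss[i1] + w * (gr$iss[i2] - gr$iss[i1])
  se_c <- (gr$iss_sd[i1] + gr$iss_sd[i2]) / 2 / sqrt(reps)
  out <- list(iss_c = iss_c, se = se_c, topology = topology, grid = gr)
  if (!is.null(observed)) {
    tstat <- (observed$iss - iss_c) / sqrt(observed$se^2 + se_c^2)
    out$t <- tstat
    out$p <- 2 * stats::pt(-abs(tstat), df = max(2, L - 1))
    out$saturated <- observed$iss >= iss_c
  }
  out
}
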