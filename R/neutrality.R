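# Site-frequency statistics and neutrality tests. Convention: neutrality
# tests use complete deletion of gapped/ambiguous columns (the DnaSP
# default), unlike the distance machinery which uses pairwise deletion.

## harmonic-number constants used by Tajima's and Fu & Li's statistics
neutrality_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  ## Fu & Li (1993) constants, with the Simonsen et al. (1995) corrections
  an1 <- a1 + 1 / n                                  # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
        (a1^2 + a2)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
         4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
  dn <- cn + (n - 2) / (n - 1)^2 +
        2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
          2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uDs <- n / (n - 1) * (a1 - n / (n - 1)) - vDs
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
          2 / (n - 1) * (4 * a2 - 6 + 8 / n)) / (a1^2 + a2)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 2 * 2 / (n * (n - 1)) +
          2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vFs
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1,
       e2 = e2, an1 = an1, cn = cn, dn = dn, uD = uD, vD = vD, uF = uF,
       vF = vF, uDs = uDs, vDs = vDs, uFs = uFs, vFs = vFs)
}

#' Site-frequency summary of an alignment
#'
#' Applies complete deletion (columns with any gap or `N` are dropped), then
#' tallies segregating sites `S`, total mutations `eta` (alleles minus one,
#' summed over sites), singleton mutations `eta_s` (variants carried by
#' exactly one sequence), and the mean number of pairwise differences `pi`.
#'
#' @param alignment A `copy_alignment`.
#' @return List with `n`, `L` (sites analyzed), `S`, `eta`, `eta_s`, `pi`,
#'   `theta_w` (Watterson's estimator, per locus) and the constant set.
#' @export
site_frequency_summary <- function(alignment) {
  stopifnot(inherits(alignment, "copy_alignment"))
  im <- aln_int_matrix(alignment$seqs)
  keep <- colSums(is.na(im)) == 0
  im <- im[, keep, drop = FALSE]
  n <- nrow(im)
  L <- ncol(im)
  S <- 0L; eta <- 0L; eta_s <- 0L; pi_sum <- 0
  npairs <- n * (n - 1) / 2
  for (j in seq_len(L)) {
    cnt <- tabulate(im[, j], 4L)
    k <- sum(cnt > 0)
    if (k < 2) next
    S <- S + 1L
    eta <- eta + (k - 1L)
    eta_s <- eta_s + min(sum(cnt == 1L), k - 1L)
    pi_sum <- pi_sum + (npairs - sum(choose(cnt, 2))) / npairs
  }
  cons <- neutrality_constants(n)
  list(n = n, L = L, S = S, eta = eta, eta_s = eta_s, pi = pi_sum,
       theta_w = S / cons$a1, constants = cons)
}

## Simulate the null distribution of a statistic under the standard neutral
## coalescent conditional on S: S mutations are placed multinomially over
## branches proportional to length; the statistic is computed from the
## resulting frequency counts. stat_fn(n, counts) -> numeric.
coalescent_null <- function(n, S, reps, stat_fn, seed = 1L) {
  set.seed(seed)
  vals <- vector("list", reps)
  for (r in seq_len(reps)) {
    ## Kingman coalescent: per-branch lengths and subtended tip counts
    sizes <- rep(1L, n)
    blen <- numeric(0)
    bsize <- integer(0)
    active_start <- rep(0, n)
    t <- 0
    while (length(sizes) > 1) {
      k <- length(sizes)
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
      pick <- sample.int(k, 2)
      blen <- c(blen, t - active_start[pick])
      bsize <- c(bsize, sizes[pick])
      merged <- sum(sizes[pick])
      sizes <- c(sizes[-pick], merged)
      active_start <- c(active_start[-pick], t)
    }
    if (S == 0) { vals[[r]] <- stat_fn(n, integer(0)); next }
    hits <- stats::rmultinom(1, S, blen)[, 1]
    counts <- rep(bsize, hits)                 # derived-allele counts
    vals[[r]] <- stat_fn(n, counts)
  }
  if (all(lengths(vals) == 1L)) unlist(vals) else vals
}

## two-sided empirical p-value of obs within null draws
empirical_two_sided <- function(obs, null) {
  null <- null[is.finite(null)]
  if (length(null) == 0 || !is.finite(obs)) return(NA_real_)
  lo <- mean(null <= obs)
  hi <- mean(null >= obs)
  min(1, 2 * min(lo, hi))
}

tajima_d_from_counts <- function(n, counts) {
  S <- length(counts)
  if (S == 0) return(NA_real_)
  cons <- neutrality_constants(n)
  npairs <- n * (n - 1) / 2
  pi <- sum(counts * (n - counts)) / npairs
  (pi - S / cons$a1) / sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
}

#' Tajima's D with beta-approximation and coalescent p-values
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` contrasts mean pairwise
#' diversity with Watterson's estimator. Negative values signal an excess of
#' rare variants - the signature of recent expansion (for retrotransposon
#' copy sets, a recent transposition burst) or purifying selection. The
#' p-value is computed from Tajima's beta approximation and, optionally, by
#' neutral coalescent simulation conditional on S.
#'
#' @param alignment A `copy_alignment` (n >= 4 recommended).
#' @param coalescent_reps Replicates for the simulated p-value (0 disables).
#' @param seed Seed for the coalescent simulation.
#' @return List with `D`, `p_beta`, `p_coalescent` (NA when disabled),
#'   and the [site_frequency_summary()] under `summary`. `D` is NA with a
#'   note when `S = 0`.
#' @export
tajimas_d <- function(alignment, coalescent_reps = 0L, seed = 1L) {
  sfs <- site_frequency_summary(alignment)
  if (sfs$S == 0) {
    return(list(D = NA_real_, p_beta = NA_real_, p_coalescent = NA_real_,
                note = "no segregating sites", summary = sfs))
  }
  cons <- sfs$constants
  D <- (sfs$pi - sfs$S / cons$a1) /
       sqrt(cons$e1 * sfs$S + cons$e2 * sfs$S * (sfs$S - 1))
  ## beta approximation (bounded support, mean 0, variance 1)
  n <- sfs$n
  dmin <- (2 / n - 1 / cons$a1) / sqrt(cons$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / cons$a1) / sqrt(cons$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  x <- (D - dmin) / (dmax - dmin)
  cdf <- stats::pbeta(min(max(x, 0), 1), beta, alpha)
  p_beta <- min(1, 2 * min(cdf, 1 - cdf))
  p_co <- NA_real_
  if (coalescent_reps > 0) {
    null <- coalescent_null(sfs$n, sfs$S, coalescent_reps,
                            tajima_d_from_counts, seed = seed)
    p_co <- empirical_two_sided(D, null)
  }
  list(D = D, p_beta = p_beta, p_coalescent = p_co, summary = sfs)
}

fu_li_from_counts <- function(n, counts, starred = TRUE) {
  S <- length(counts)
  if (S == 0) return(c(D = NA_real_, F = NA_real_))
  cons <- neutrality_constants(n)
  eta <- S
  npairs <- n * (n - 1) / 2
  pi <- sum(counts * (n - counts)) / npairs
  if (starred) {
    eta_s <- sum(counts == 1 | counts == n - 1)
    Dv <- (n / (n - 1) * eta - cons$a1 * eta_s) /
          sqrt(cons$uDs * eta + cons$vDs * eta^2)
    Fv <- (pi - (n - 1) / n * eta_s) /
          sqrt(cons$uFs * eta + cons$vFs * eta^2)
  } else {
    eta_e <- sum(counts == 1)                  # derived singletons
    Dv <- (eta - cons$a1 * eta_e) / sqrt(cons$uD * eta + cons$vD * eta^2)
    Fv <- (pi - eta_e) / sqrt(cons$uF * eta + cons$vF * eta^2)
  }
  c(D = Dv, F = Fv)
}

#' Fu & Li's D and F neutrality statistics
#'
#' Without an outgroup the starred variants D* and F* are computed from the
#' singleton count (variants carried by exactly one sequence); with an
#' outgroup the original variants use derived-mutation counts polarized
#' against the outgroup allele. Like Tajima's D, negative values reflect a
#' singleton excess. P-values are obtained by neutral coalescent simulation
#' conditional on the number of mutations.
#'
#' @param alignment A `copy_alignment`.
#' @param outgroup Optional outgroup sequence (same length as the alignment
#'   rows) used to polarize mutations.
#' @param coalescent_reps Replicates for simulated p-values (0 disables).
#' @param seed Seed for the coalescent simulation.
#' @return List with `D`, `F`, `variant` ("starred" or "outgroup"),
#'   `p_D`, `p_F`, and the site-frequency `summary`.
#' @export
fu_li <- function(alignment, outgroup = NULL, coalescent_reps = 0L,
                  seed = 1L) {
  stopifnot(inherits(alignment, "copy_alignment"))
  im <- aln_int_matrix(alignment$seqs)
  n <- nrow(im)
  sfs <- site_frequency_summary(alignment)
  if (sfs$S == 0) {
    return(list(D = NA_real_, F = NA_real_,
                variant = if (is.null(outgroup)) "starred" else "outgroup",
                p_D = NA_real_, p_F = NA_real_,
                note = "no segregating sites", summary = sfs))
  }
  cons <- sfs$constants
  if (is.null(outgroup)) {
    eta <- sfs$eta
    eta_s <- sfs$eta_s
    pi <- sfs$pi
    Dv <- (n / (n - 1) * eta - cons$a1 * eta_s) /
          sqrt(cons$uDs * eta + cons$vDs * eta^2)
    Fv <- (pi - (n - 1) / n * eta_s) /
          sqrt(cons$uFs * eta + cons$vFs * eta^2)
    variant <- "starred"
    starred <- TRUE
  } else {
    og <- seq_ints(toupper(outgroup))
    stopifnot(length(og) == ncol(im))
    keep <- colSums(is.na(im)) == 0 & !is.na(og)
    imk <- im[, keep, drop = FALSE]
    ogk <- og[keep]
    eta <- 0L; eta_e <- 0L; pi <- 0
    npairs <- n * (n - 1) / 2
    for (j in seq_len(ncol(imk))) {
      cnt <- tabulate(imk[, j], 4L)
      k <- sum(cnt > 0)
      if (k < 2) next
      eta <- eta + (k - 1L)
      pi <- pi + (npairs - sum(choose(cnt, 2))) / npairs
      derived <- which(cnt == 1L)
      derived <- derived[derived != ogk[j]]
      eta_e <- eta_e + length(derived)
    }
    Dv <- (eta - cons$a1 * eta_e) / sqrt(cons$uD * eta + cons$vD * eta^2)
    Fv <- (pi - eta_e) / sqrt(cons$uF * eta + cons$vF * eta^2)
    variant <- "outgroup"
    starred <- FALSE
  }
  p_D <- p_F <- NA_real_
  if (coalescent_reps > 0) {
    null <- coalescent_null(n, sfs$S, coalescent_reps, function(nn, counts) {
      fu_li_from_counts(nn, counts, starred = starred)
    }, seed = seed)
    nullm <- do.call(rbind, null)              # one c(D, F) row per rep
    p_D <- empirical_two_sided(Dv, nullm[, 1])
    p_F <- empirical_two_sided(Fv, nullm[, 2])
  }
  list(D = Dv, F = Fv, variant = variant, p_D = p_D, p_F = p_F,
       summary = sfs)
}
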