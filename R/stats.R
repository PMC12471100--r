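# Alignment-level statistics: pairwise transition/transversion counts,
# p- and F84 distances, group p-distances with bootstrap SEs, sliding-window
# divergence, and the transition/transversion saturation regression.

#' Pairwise transition/transversion statistics
#'
#' For every unordered pair of rows, columns with a gap or `N` in either row
#' are excluded (pairwise deletion); differences are split into transitions
#' (A<->G, C<->T) and transversions. The F84 distance is computed from the
#' observed transition/transversion proportions and the pooled base
#' frequencies of the pair (see [f84_distance()]).
#'
#' @param alignment A `copy_alignment` (>= 2 rows).
#' @return Data frame with one row per pair: `id_a`, `id_b`,
#'   `compared_sites`, `ts`, `tv`, `p_dist`, `f84_dist`, `f84_saturated`.
#' @export
pairwise_stats <- function(alignment) {
  stopifnot(inherits(alignment, "copy_alignment"))
  im <- aln_int_matrix(alignment$seqs)
  ids <- rownames(im)
  n <- nrow(im)
  rows <- vector("list", n * (n - 1) / 2)
  ri <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- im[i, ]; b <- im[j, ]
      ok <- !is.na(a) & !is.na(b)
      cs <- sum(ok)
      if (cs == 0) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(id_a = ids[i], id_b = ids[j],
                                 compared_sites = 0L, ts = NA_integer_,
                                 tv = NA_integer_, p_dist = NA_real_,
                                 f84_dist = NA_real_, f84_saturated = NA)
        next
      }
      aa <- a[ok]; bb <- b[ok]
      diff <- aa != bb
      ## transitions: A(1)<->G(3), C(2)<->T(4): both purine or both pyrimidine
      ts <- sum(diff & (aa %% 2L == bb %% 2L))
      tv <- sum(diff) - ts
      p <- (ts + tv) / cs
      freqs <- (tabulate(aa, 4L) + tabulate(bb, 4L)) / (2 * cs)
      f84 <- f84_distance(ts / cs, tv / cs, freqs)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(id_a = ids[i], id_b = ids[j],
                               compared_sites = cs, ts = ts, tv = tv,
                               p_dist = p, f84_dist = f84$distance,
                               f84_saturated = f84$saturated)
    }
  }
  do.call(rbind, rows)
}

#' F84 evolutionary distance (closed form)
#'
#' The F84 model allows unequal base frequencies and a
#' transition/transversion bias. With `P` and `Q` the observed transition and
#' transversion proportions and base frequencies `pi`, the distance is
#'
#' `d = -2A log(1 - P/(2A) - (A - B) Q / (2 A C)) + 2 (A - B - C) log(1 - Q/(2C))`
#'
#' with `A = piA piG / piR + piC piT / piY`, `B = piA piG + piC piT`,
#' `C = piR piY`. At equal frequencies this reduces to the Kimura
#' two-parameter distance. When a log argument is non-positive the distance
#' is undefined ("saturated"); when a purine or pyrimidine class frequency is
#' zero the p-distance is returned with a warning.
#'
#' @param P Transition difference proportion.
#' @param Q Transversion difference proportion.
#' @param freqs Numeric length-4 vector of base frequencies (A, C, G, T).
#' @return List with `distance` (NA when saturated) and `saturated` flag.
#' @export
f84_distance <- function(P, Q, freqs) {
  stopifnot(length(freqs) == 4, all(freqs >= 0))
  freqs <- freqs / sum(freqs)
  piA <- freqs[1]; piC <- freqs[2]; piG <- freqs[3]; piT <- freqs[4]
  piR <- piA + piG; piY <- piC + piT
  if (piR == 0 || piY == 0 || piA * piG + piC * piT == 0) {
    warning("degenerate base frequencies; falling back to p-distance")
    return(list(distance = P + Q, saturated = FALSE))
  }
  A <- piA * piG / piR + piC * piT / piY
  B <- piA * piG + piC * piT
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(distance = NA_real_, saturated = TRUE))
  }
  d <- -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
  list(distance = d, saturated = FALSE)
}

#' Within/between-group mean p-distances with bootstrap SEs
#'
#' Columns non-missing in at least `site_coverage` of rows are retained (the
#' MEGA-style partial-deletion filter); p-distances are computed with
#' pairwise deletion on the surviving columns, averaged over all intra-group
#' (within) or cross-group (between) pairs, and standard errors are obtained
#' by bootstrapping columns. Groups represented by a single copy get `NA`
#' within-distance, reported as `"NC"` (not calculated).
#'
#' @param alignment A `copy_alignment`.
#' @param groups Optional named group map (defaults to the alignment's).
#' @param site_coverage Minimum fraction of non-missing rows per column.
#' @param boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return List with `table` (data frame: group_a, group_b, type, mean, se,
#'   n_pairs, note), `mean_matrix`, `se_matrix`, and `n_sites_used`.
#' @export
group_p_distance <- function(alignment, groups = NULL, site_coverage = 0.90,
                             boot = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "copy_alignment"))
  groups <- groups %||% alignment$groups
  im <- aln_int_matrix(alignment$seqs)
  n <- nrow(im)
  cover <- colMeans(!is.na(im))
  keep <- cover >= site_coverage
  if (!any(keep)) {
    hist <- table(cut(cover, seq(0, 1, 0.1), include.lowest = TRUE))
    stop("no columns reach ", site_coverage, " site coverage; coverage ",
         "histogram: ", paste(names(hist), hist, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  im <- im[, keep, drop = FALSE]
  L <- ncol(im)
  ids <- rownames(im)
  g <- groups[ids]
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  ## per-pair per-column difference indicators (NA under pairwise deletion)
  dm <- matrix(NA_real_, np, L)
  for (p in seq_len(np)) {
    a <- im[pairs[1L, p], ]; b <- im[pairs[2L, p], ]
    d <- as.numeric(a != b)
    dm[p, ] <- d
  }
  ga <- g[pairs[1L, ]]; gb <- g[pairs[2L, ]]
  glev <- sort(unique(g))
  pair_sets <- list()
  for (i in seq_along(glev)) {
    for (j in i:length(glev)) {
      sel <- (ga == glev[i] & gb == glev[j]) | (ga == glev[j] & gb == glev[i])
      pair_sets[[paste(glev[i], glev[j], sep = "|")]] <- which(sel)
    }
  }
  mean_of <- function(cols, sel) {
    if (length(sel) == 0) return(NA_real_)
    mean(dm[sel, cols, drop = FALSE], na.rm = TRUE)
  }
  all_cols <- seq_len(L)
  est <- vapply(pair_sets, function(sel) mean_of(all_cols, sel), numeric(1))
  set.seed(seed)
  bootm <- matrix(NA_real_, boot, length(pair_sets))
  for (r in seq_len(boot)) {
    cols <- sample.int(L, L, replace = TRUE)
    bootm[r, ] <- vapply(pair_sets, function(sel) mean_of(cols, sel),
                         numeric(1))
  }
  se <- apply(bootm, 2, stats::sd, na.rm = TRUE)
  key <- strsplit(names(pair_sets), "|", fixed = TRUE)
  tab <- data.frame(
    group_a = vapply(key, `[`, character(1), 1L),
    group_b = vapply(key, `[`, character(1), 2L),
    type = ifelse(vapply(key, `[`, character(1), 1L) ==
                  vapply(key, `[`, character(1), 2L), "within", "between"),
    mean = unname(est), se = unname(se),
    n_pairs = vapply(pair_sets, length, integer(1)),
    note = "", stringsAsFactors = FALSE)
  single <- tab$type == "within" & tab$n_pairs == 0
  tab$note[single] <- "NC"
  k <- length(glev)
  mm <- sem <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  for (r in seq_len(nrow(tab))) {
    mm[tab$group_a[r], tab$group_b[r]] <- mm[tab$group_b[r], tab$group_a[r]] <-
      tab$mean[r]
    sem[tab$group_a[r], tab$group_b[r]] <-
      sem[tab$group_b[r], tab$group_a[r]] <- tab$se[r]
  }
  list(table = tab, mean_matrix = mm, se_matrix = sem, n_sites_used = L)
}

#' Sliding-window mean pairwise divergence
#'
#' Screens an alignment for localized divergence peaks, the footprint of
#' recombinant tracts: per window the mean pairwise p-distance (pairwise
#' deletion) is computed and windows exceeding
#' `mean + peak_z * SD` of the profile are flagged.
#'
#' @param alignment A `copy_alignment` with length >= `window`.
#' @param window Window size, bp.
#' @param step Step size, bp.
#' @param peak_z Peak threshold in profile scale units.
#' @param robust If TRUE (default) the peak baseline is the profile median
#'   and the scale is 1.4826 x MAD, so a genuine recombinant tract does not
#'   inflate its own detection threshold; FALSE uses the naive mean/SD.
#' @param min_fold Additional effect-size gate: a window is only a peak if
#'   its divergence also exceeds `min_fold` times the baseline, suppressing
#'   pure sampling-noise excursions in short homogeneous alignments.
#' @return Data frame of class `window_profile`: `start` (0-based),
#'   `divergence`, `peak`.
#' @export
sliding_divergence <- function(alignment, window = 300L, step = 50L,
                               peak_z = 3, robust = TRUE, min_fold = 1.5) {
  stopifnot(inherits(alignment, "copy_alignment"))
  im <- aln_int_matrix(alignment$seqs)
  L <- ncol(im)
  stopifnot(L >= window)
  n <- nrow(im)
  pairs <- utils::combn(n, 2L)
  diffs <- matrix(NA_real_, ncol(pairs), L)
  for (p in seq_len(ncol(pairs))) {
    diffs[p, ] <- as.numeric(im[pairs[1L, p], ] != im[pairs[2L, p], ])
  }
  starts <- seq(0L, L - window, by = step)
  div <- vapply(starts, function(s) {
    mean(diffs[, (s + 1L):(s + window), drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  if (robust) {
    mu <- stats::median(div, na.rm = TRUE)
    sdv <- 1.4826 * stats::mad(div, constant = 1, na.rm = TRUE)
  } else {
    mu <- mean(div, na.rm = TRUE)
    sdv <- stats::sd(div, na.rm = TRUE)
  }
  peak <- if (length(div) < 2 || is.na(sdv) || sdv == 0) {
    rep(FALSE, length(div))
  } else div > pmax(mu + peak_z * sdv, min_fold * mu)
  structure(data.frame(start = starts, divergence = div, peak = peak),
            class = c("window_profile", "data.frame"))
}

#' Transition/transversion saturation regression
#'
#' Ordinary least squares of the transition and transversion proportions
#' against the F84 distance, the classic saturation diagnostic: both classes
#' grow linearly at low divergence, and transitions plateau when multiple
#' hits accumulate. The plateau flag is a significantly negative quadratic
#' term when the fit is repeated with a squared-distance term.
#'
#' @param pw Output of [pairwise_stats()].
#' @param alpha Significance level for the quadratic (plateau) term.
#' @return Data frame with one row per class (`ts`, `tv`): slope, intercept,
#'   r_squared, plateau flag and quadratic p-value.
#' @export
saturation_regression <- function(pw, alpha = 0.05) {
  d <- pw$f84_dist
  use <- !is.na(d) & pw$compared_sites > 0
  if (sum(use) < 3) stop("need >= 3 pairs with defined distances",
                         call. = FALSE)
  if (stats::sd(d[use]) == 0) {
    stop("all distances equal; regression undefined", call. = FALSE)
  }
  out <- lapply(c(ts = "ts", tv = "tv"), function(cl) {
    y <- pw[[cl]][use] / pw$compared_sites[use]
    x <- d[use]
    fit <- stats::lm(y ~ x)
    fit2 <- stats::lm(y ~ x + I(x^2))
    co <- summary(fit2)$coefficients
    has_q <- "I(x^2)" %in% rownames(co)
    qp <- if (has_q) co["I(x^2)", "Pr(>|t|)"] else NA_real_
    qest <- if (has_q) co["I(x^2)", "Estimate"] else NA_real_
    data.frame(class = cl, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               plateau = isTRUE(!is.na(qp) && qest < 0 && qp < alpha),
               quad_p = qp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
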