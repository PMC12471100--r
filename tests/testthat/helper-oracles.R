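# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results from first principles (exhaustive
# enumeration, closed forms, published formulas) without touching the
# package's own implementation paths.

ORACLE_GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(ORACLE_GC)[ORACLE_GC == "*"]
ORACLE_SENSE <- names(ORACLE_GC)[ORACLE_GC != "*"]
BASES <- c("A", "C", "G", "T")

## random sequence / in-place mutator used by many fixtures
rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

mutate_seq <- function(s, p) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

## ---- codon-counting oracle: exhaustive pathway enumeration -----------------

oracle_codon_counts <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  dp <- which(ac != bc)
  h <- length(dp)
  if (h == 0) return(c(sd = 0, nd = 0))
  perms <- if (h == 1) list(dp) else if (h == 2) list(dp, rev(dp)) else {
    g <- expand.grid(1:3, 1:3, 1:3)
    g <- g[apply(g, 1, function(x) length(unique(x)) == 3), ]
    lapply(seq_len(nrow(g)), function(r) dp[as.integer(g[r, ])])
  }
  run_path <- function(ord, allow_stop) {
    cur <- ac; sd <- 0; nd <- 0
    for (t in seq_along(ord)) {
      nxt <- cur
      nxt[ord[t]] <- bc[ord[t]]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (!allow_stop && ORACLE_GC[[to]] == "*" && t < length(ord)) {
        return(NULL)
      }
      if (ORACLE_GC[[from]] == ORACLE_GC[[to]] && ORACLE_GC[[from]] != "*") {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, run_path, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms, run_path, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

## brute-force pair counter over whole codon rows (pairwise codon deletion)
oracle_pair_counts <- function(row_a, row_b) {
  ca <- substring(row_a, seq(1, nchar(row_a), 3), seq(3, nchar(row_a), 3))
  cb <- substring(row_b, seq(1, nchar(row_b), 3), seq(3, nchar(row_b), 3))
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% ORACLE_STOPS) & !(cb %in% ORACLE_STOPS)
  sd <- 0; nd <- 0
  for (i in which(keep)) {
    cc <- oracle_codon_counts(ca[i], cb[i])
    sd <- sd + cc[["sd"]]
    nd <- nd + cc[["nd"]]
  }
  c(sd = sd, nd = nd)
}

## ---- neutrality-test formula oracles (published formulas, re-derived) ------

oracle_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  list(a1 = a1, a2 = a2)
}

## Tajima's D directly from the alignment matrix (complete deletion)
oracle_tajima <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- apply(m, 2, function(col) all(col %in% BASES))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0; pi_tot <- 0
  for (j in seq_len(ncol(m))) {
    if (length(unique(m[, j])) > 1) S <- S + 1
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      if (m[x, j] != m[y, j]) pi_tot <- pi_tot + 1
    }
  }
  pi <- pi_tot / choose(n, 2)
  if (S == 0) return(NA_real_)
  k <- oracle_constants(n)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / k$a1
  c2 <- b2 - (n + 2) / (k$a1 * n) + k$a2 / k$a1^2
  e1 <- c1 / k$a1; e2 <- c2 / (k$a1^2 + k$a2)
  (pi - S / k$a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Fu & Li D*/F* (no outgroup; Simonsen et al. corrected constants) and
## D/F (with outgroup), from explicit per-site tallies
oracle_fu_li <- function(seqs, outgroup = NULL) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- apply(m, 2, function(col) all(col %in% BASES))
  og <- NULL
  if (!is.null(outgroup)) {
    og <- strsplit(outgroup, "", fixed = TRUE)[[1]]
    keep <- keep & og %in% BASES
    og <- og[keep]
  }
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  eta <- 0; eta_s <- 0; eta_e <- 0; pi_tot <- 0
  for (j in seq_len(ncol(m))) {
    tabj <- table(m[, j])
    k <- length(tabj)
    if (k < 2) next
    eta <- eta + (k - 1)
    eta_s <- eta_s + min(sum(tabj == 1), k - 1)
    if (!is.null(og)) {
      der <- names(tabj)[tabj == 1 & names(tabj) != og[j]]
      eta_e <- eta_e + length(der)
    }
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      if (m[x, j] != m[y, j]) pi_tot <- pi_tot + 1
    }
  }
  if (eta == 0) return(c(D = NA_real_, F = NA_real_))
  pi <- pi_tot / choose(n, 2)
  k <- oracle_constants(n)
  a1 <- k$a1; a2 <- k$a2
  an1 <- a1 + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  if (is.null(outgroup)) {
    dn <- cn + (n - 2) / (n - 1)^2 +
      2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vDs <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
            2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
    uDs <- n / (n - 1) * (a1 - n / (n - 1)) - vDs
    vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            2 / (n - 1) * (4 * a2 - 6 + 8 / n)) / (a1^2 + a2)
    uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vFs
    D <- (n / (n - 1) * eta - a1 * eta_s) / sqrt(uDs * eta + vDs * eta^2)
    F <- (pi - (n - 1) / n * eta_s) / sqrt(uFs * eta + vFs * eta^2)
  } else {
    vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
    uD <- a1 - 1 - vD
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
      (a1^2 + a2)
    uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
    D <- (eta - a1 * eta_e) / sqrt(uD * eta + vD * eta^2)
    F <- (pi - eta_e) / sqrt(uF * eta + vF * eta^2)
  }
  c(D = D, F = F)
}

## ---- F84 maximum-likelihood oracle -----------------------------------------

## F84 rate matrix (Felsenstein's K parameter), rows/cols A,C,G,T
f84_rate_matrix <- function(K, freqs) {
  piR <- freqs[1] + freqs[3]; piY <- freqs[2] + freqs[4]
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- freqs[j]
    both_pur <- i %in% c(1, 3) && j %in% c(1, 3)
    both_pyr <- i %in% c(2, 4) && j %in% c(2, 4)
    if (both_pur) rate <- rate * (1 + K / piR)
    if (both_pyr) rate <- rate * (1 + K / piY)
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  ## scale so mean rate = 1 substitution per unit time
  Q / sum(freqs * -diag(Q))
}

## expected transition / transversion difference proportions at distance t
f84_PQ <- function(t, K, freqs) {
  Q <- f84_rate_matrix(K, freqs)
  eg <- eigen(Q)
  P <- eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
  ts_pairs <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))
  p_ts <- sum(freqs[ts_pairs[, 1]] *
              P[cbind(ts_pairs[, 1], ts_pairs[, 2])])
  p_diff <- 1 - sum(freqs * diag(P))
  c(P = Re(p_ts), Q = Re(p_diff - p_ts))
}

## numerical ML fit of (t, K) to observed (match, ts, tv) trinomial counts
oracle_f84_ml <- function(n_match, n_ts, n_tv, freqs) {
  nll <- function(par) {
    t <- exp(par[1]); K <- exp(par[2])
    pq <- f84_PQ(t, K, freqs)
    p <- c(1 - pq[1] - pq[2], pq[1], pq[2])
    if (any(p <= 0)) return(1e10)
    -sum(c(n_match, n_ts, n_tv) * log(p))
  }
  fit <- stats::optim(c(log(0.1), log(1)), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  exp(fit$par[1])
}

## ---- simulator-facing fixtures ---------------------------------------------

## mutation-opportunity N/S ratio of an ORF under the simulator's process:
## per codon, every single-base change weighted by the ts/tv ratio,
## stop-gaining changes excluded (they are always rejected)
oracle_opportunity_ratio <- function(orf, kappa) {
  cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
  Sw <- 0; Nw <- 0
  for (cod in cods) {
    cc <- strsplit(cod, "", fixed = TRUE)[[1]]
    for (p in 1:3) {
      for (alt in setdiff(BASES, cc[p])) {
        w <- if ((cc[p] %in% c("A", "G") && alt %in% c("A", "G")) ||
                 (cc[p] %in% c("C", "T") && alt %in% c("C", "T"))) kappa else 1
        nc <- cc; nc[p] <- alt
        nco <- paste(nc, collapse = "")
        if (ORACLE_GC[[nco]] == "*") next
        if (ORACLE_GC[[nco]] == ORACLE_GC[[cod]]) Sw <- Sw + w else
          Nw <- Nw + w
      }
    }
  }
  Nw / Sw
}

## mutate an in-frame ORF without creating stop codons
mutate_orf_nostop <- function(orf, p) {
  cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
  for (i in seq_along(cods)) {
    cc <- strsplit(cods[i], "", fixed = TRUE)[[1]]
    for (j in 1:3) {
      if (stats::runif(1) >= p) next
      alt <- sample(setdiff(BASES, cc[j]))
      for (a in alt) {
        nc <- cc; nc[j] <- a
        if (ORACLE_GC[[paste(nc, collapse = "")]] != "*") { cc <- nc; break }
      }
    }
    cods[i] <- paste(cc, collapse = "")
  }
  paste(cods, collapse = "")
}

## evolve a sequence for time t under a Kimura 2-parameter process
## (transition rate alpha, transversion rate beta per target); per-site
## multiple hits are implicit in the closed-form transition probabilities
k80_evolve <- function(anc, t, alpha = 0.6, beta = 0.3) {
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * t)
  ch <- strsplit(anc, "", fixed = TRUE)[[1]]
  u <- stats::runif(length(ch))
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_along(ch)) {
    if (u[i] < p_ts) {
      ch[i] <- ts_partner[[ch[i]]]
    } else if (u[i] < p_ts + p_tv) {
      ch[i] <- sample(setdiff(BASES, c(ch[i], ts_partner[[ch[i]]])), 1)
    }
  }
  paste(ch, collapse = "")
}

## two well-separated families as one labelled alignment of RT regions
make_two_family_alignment <- function(n_per = 5, subs = 30, seed = 1,
                                      rt_len = 600) {
  set.seed(seed)
  tplA <- make_template(orf_len = rt_len + 600, rt_len = rt_len,
                        seed = seed * 7 + 1)
  tplB <- make_template(orf_len = rt_len + 600, rt_len = rt_len,
                        seed = seed * 7 + 2)
  rtA <- substr(template_full_seq(tplA), tplA$rt_interval[1] + 1,
                tplA$rt_interval[2])
  rtB <- substr(template_full_seq(tplB), tplB$rt_interval[1] + 1,
                tplB$rt_interval[2])
  famA <- simulate_codon_family(rtA, n_per, subs, omega = 1,
                                seed = seed * 11 + 1)
  famB <- simulate_codon_family(rtB, n_per, subs, omega = 1,
                                seed = seed * 11 + 2)
  seqs <- c(stats::setNames(famA$seqs, paste0("A", seq_len(n_per))),
            stats::setNames(famB$seqs, paste0("B", seq_len(n_per))))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per), names(seqs))
  copy_alignment(seqs, "RT", groups = groups)
}
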