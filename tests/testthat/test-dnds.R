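test_that("codon_change_counts classifies the canonical examples", {
  expect_equal(codon_change_counts("TTT", "TTT"), c(sd = 0, nd = 0))
  ## AAA and AAG both encode Lys: one synonymous step
  expect_equal(codon_change_counts("AAA", "AAG"), c(sd = 1, nd = 0))
  ## TTG -> CTA: both minimal pathways stay Leu throughout
  expect_equal(codon_change_counts("TTG", "CTA"), c(sd = 2, nd = 0))
  ## mixed: averaged over equally weighted pathways
  cc <- codon_change_counts("TTT", "GTA")
  expect_equal(unname(sum(cc)), 2)                     # step conservation
  expect_error(codon_change_counts("TAA", "TAC"), "stop")
  ## strict multi-hit mode returns NA for 2-3 difference codons
  expect_true(anyNA(codon_change_counts("TTG", "CTA", skip_multi_hit = TRUE)))
  expect_equal(codon_change_counts("AAA", "AAG", skip_multi_hit = TRUE),
               c(sd = 1, nd = 0))
})

test_that("codon_change_counts is symmetric and conserves steps (sample)", {
  set.seed(30)
  picks <- cbind(sample(ORACLE_SENSE, 80, TRUE), sample(ORACLE_SENSE, 80, TRUE))
  for (r in seq_len(nrow(picks))) {
    a <- picks[r, 1]; b <- picks[r, 2]
    ab <- codon_change_counts(a, b)
    ba <- codon_change_counts(b, a)
    expect_equal(ab, ba)
    h <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(ab)), h)
  }
})

test_that("pair_dnds applies pairwise codon deletion and the count ratio", {
  a <- "ATGAAACCCGGG"
  expect_true(is.na(pair_dnds(a, a)$ratio))            # identical: undefined
  b <- "ATGAAGCCCGGG"                                  # one synonymous change
  pd <- pair_dnds(a, b)
  expect_equal(pd$sd, 1)
  expect_equal(pd$nd, 0)
  expect_equal(pd$ratio, 0)

  ## gap and stop codons excluded pairwise; locality of exclusion
  c1 <- "ATGAAACCCTAAGGG"                              # stop codon inside
  c2 <- "ATGAAGCCC---GGG"
  pd2 <- pair_dnds(c1, c2)
  expect_identical(pd2$excluded_codons, 1L)
  expect_equal(pd2$sd, 1)                              # other codons intact
  expect_identical(pd2$codons_compared, 4L)

  allgap <- strrep("-", 12)
  expect_true(pair_dnds(allgap, allgap)$empty)
})

test_that("pair_dnds equals the brute-force oracle on random mutated pairs", {
  set.seed(31)
  for (r in 1:30) {
    base <- paste(sample(ORACLE_SENSE, 40, replace = TRUE), collapse = "")
    row_a <- mutate_seq(base, 0.05)
    row_b <- mutate_seq(base, 0.05)
    got <- pair_dnds(row_a, row_b)
    want <- oracle_pair_counts(row_a, row_b)
    expect_equal(got$sd, unname(want["sd"]))
    expect_equal(got$nd, unname(want["nd"]))
  }
})

test_that("family_dnds pools intra-group ratios and flags degenerate groups", {
  aln <- make_two_family_alignment(n_per = 4, subs = 25, seed = 6)
  fam <- family_dnds(aln)
  expect_setequal(fam$groups$group, c("A", "B"))
  expect_identical(fam$groups$n_pairs, c(6L, 6L))
  expect_false(any(fam$groups$all_undefined))

  ident <- copy_alignment(
    stats::setNames(rep(paste(sample(ORACLE_SENSE, 50, TRUE), collapse = ""),
                        3), paste0("c", 1:3)), "RT",
    groups = stats::setNames(rep("g", 3), paste0("c", 1:3)))
  fam2 <- family_dnds(ident)
  expect_true(fam2$groups$all_undefined)
  expect_identical(fam2$groups$n_undefined, 3L)
})

test_that("mann_whitney matches exact enumeration and symmetry", {
  ## disjoint samples: U = 0, exact two-sided p = 2 / C(6,3) * 1 = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_identical(mw$method, "exact")

  ## identical distributions: U = n1 n2 / 2 and p = 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)
  expect_equal(mw2$p, 1)

  ## exact p agrees with full rank enumeration on a random instance
  set.seed(32)
  a <- sample(100, 5); b <- sample(200 + seq_len(100), 6)
  mw3 <- mann_whitney(a, b)
  combos <- utils::combn(11, 5)
  pooled <- c(a, b)
  u_of <- function(idx) sum(rank(pooled)[idx]) - 5 * 6 / 2
  null_u <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - 5 * 6 / 2
  })
  obs <- u_of(1:5)
  p_exact <- min(1, 2 * min(mean(null_u <= obs), mean(null_u >= obs)))
  expect_equal(mw3$p, p_exact)

  ## shift monotonicity under the normal approximation
  set.seed(33)
  x <- stats::rnorm(30)
  p_small <- mann_whitney(x, x + 0.5)$p
  p_large <- mann_whitney(x, x + 2)$p
  expect_lt(p_large, p_small)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("dnds_group_tests reports tiers for separated groups", {
  set.seed(34)
  fam <- list(pairs = data.frame(
    group = rep(c("lo", "hi"), each = 12),
    ratio = c(stats::runif(12, 0, 0.1), stats::runif(12, 0.5, 1))))
  tests <- dnds_group_tests(fam)
  expect_identical(nrow(tests), 1L)
  expect_lt(tests$p, 0.001)
  expect_identical(tests$stars, "***")
})
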