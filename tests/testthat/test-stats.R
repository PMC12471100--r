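test_that("pairwise_stats counts transitions, transversions and sites", {
  aln <- copy_alignment(c(a = "ACGT", b = "ACGT"))
  pw <- pairwise_stats(aln)
  expect_identical(pw$ts, 0L)
  expect_identical(pw$tv, 0L)
  expect_equal(pw$p_dist, 0)

  aln2 <- copy_alignment(c(a = "AAAA", b = "GAAA"))
  pw2 <- suppressWarnings(pairwise_stats(aln2))   # degenerate frequencies
  expect_identical(pw2$ts, 1L)                         # A<->G transition
  expect_identical(pw2$tv, 0L)
  expect_equal(pw2$p_dist, 0.25)

  aln3 <- copy_alignment(c(a = "AC-T", b = "ACGT"))
  expect_identical(pairwise_stats(aln3)$compared_sites, 3L)

  aln4 <- copy_alignment(c(a = "ACNT", b = "AGTT"))    # N excluded
  pw4 <- pairwise_stats(aln4)
  expect_identical(pw4$compared_sites, 3L)
  expect_identical(pw4$tv, 1L)                         # C<->G
})

test_that("f84_distance handles the degenerate and saturated regimes", {
  expect_equal(f84_distance(0, 0, rep(0.25, 4))$distance, 0)
  ## saturation: log argument non-positive
  res <- f84_distance(0.5, 0.3, rep(0.25, 4))
  expect_true(res$saturated)
  expect_true(is.na(res$distance))
  ## zero pyrimidine class: p-distance fallback with warning
  expect_warning(fb <- f84_distance(0.1, 0.05, c(0.5, 0, 0.5, 0)))
  expect_equal(fb$distance, 0.15)
})

test_that("F84 reduces to Kimura 2-parameter at uniform frequencies", {
  set.seed(8)
  for (r in 1:10) {
    P <- stats::runif(1, 0, 0.18); Q <- stats::runif(1, 0, 0.12)
    f <- f84_distance(P, Q, rep(0.25, 4))$distance
    k80 <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    expect_lt(abs(f - k80), 1e-9)
  }
})

test_that("group_p_distance separates constructed groups and honours NC", {
  set.seed(10)
  base <- rand_seq(500)
  other <- mutate_seq(base, 0.10)
  seqs <- c(g1a = base, g1b = base, g2a = other, g2b = other, solo = base)
  groups <- c(g1a = "G1", g1b = "G1", g2a = "G2", g2b = "G2", solo = "G3")
  aln <- copy_alignment(seqs, groups = groups)
  res <- group_p_distance(aln, boot = 50, seed = 1)
  tab <- res$table
  w1 <- tab$mean[tab$group_a == "G1" & tab$group_b == "G1"]
  b12 <- tab$mean[tab$group_a == "G1" & tab$group_b == "G2"]
  expect_equal(w1, 0)
  expect_equal(b12, mean(strsplit(base, "")[[1]] != strsplit(other, "")[[1]]))
  ## singleton group: within not calculated
  g3 <- tab[tab$group_a == "G3" & tab$group_b == "G3", ]
  expect_identical(g3$note, "NC")
  expect_true(is.na(g3$mean))
})

test_that("group_p_distance site-coverage filter drops gappy columns", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC",
            d = "ACG-ACG-AC", e = "ACG-ACG-AC")
  aln <- copy_alignment(seqs)
  res <- group_p_distance(aln, site_coverage = 0.90, boot = 10, seed = 1)
  expect_identical(res$n_sites_used, 8L)               # 2 columns at 60%
  allgap <- copy_alignment(c(a = "----", b = "----", c = "AAAA"))
  expect_error(group_p_distance(allgap, site_coverage = 0.90, boot = 10),
               "coverage")
})

test_that("sliding_divergence flags constructed recombinant tracts only", {
  set.seed(11)
  base <- rand_seq(4000)
  seqs <- stats::setNames(vapply(1:6, function(i) mutate_seq(base, 0.02),
                                 character(1)), paste0("s", 1:6))
  aln <- copy_alignment(seqs)
  wp <- sliding_divergence(aln)
  expect_identical(sum(wp$peak), 0L)                   # homogeneous

  donor <- mutate_seq(substr(base, 1501, 1900), 0.30)
  seqs2 <- seqs
  seqs2[3] <- paste0(substr(seqs2[3], 1, 1500), donor,
                     substr(seqs2[3], 1901, 4000))
  wp2 <- sliding_divergence(copy_alignment(seqs2))
  hits <- wp2$start[wp2$peak]
  expect_gte(length(hits), 1)
  expect_true(all(hits >= 1200 & hits <= 1900))        # inside the tract

  ## degenerate: window = L gives a single window and no peak
  wp3 <- sliding_divergence(aln, window = 4000L, step = 4000L)
  expect_identical(nrow(wp3), 1L)
  expect_false(any(wp3$peak))
})

test_that("saturation_regression fits lines and flags error cases", {
  pw <- data.frame(ts = c(10, 20, 30, 40), tv = c(5, 10, 15, 20),
                   compared_sites = rep(1000, 4),
                   f84_dist = c(0.015, 0.030, 0.045, 0.060))
  res <- suppressWarnings(saturation_regression(pw))  # perfect-fit warnings
  expect_equal(res$r_squared, c(1, 1), tolerance = 1e-12)
  expect_false(any(res$plateau))
  expect_gt(res$slope[res$class == "ts"], res$slope[res$class == "tv"])

  expect_error(saturation_regression(pw[1:2, ]), ">= 3")
  pw_flat <- pw; pw_flat$f84_dist <- rep(0.05, 4)
  expect_error(saturation_regression(pw_flat), "undefined")
})
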