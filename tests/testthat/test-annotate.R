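test_that("extract_window centers, truncates, and round-trips coordinates", {
  set.seed(1)
  contig <- rand_seq(40000)
  w <- extract_window(contig, c(20000L, 20001L), total_span = 15000L)
  expect_identical(nchar(w$seq), 15000L)
  expect_identical(w$offset, 20000L - 7500L)

  w2 <- extract_window(contig, c(1000L, 1001L), total_span = 15000L)
  expect_identical(w2$offset, 0L)                      # truncated at start
  expect_identical(nchar(w2$seq), 15000L)

  ## round-trip: window coords + offset == contig coords
  expect_identical(substr(w$seq, 1, 50),
                   substr(contig, w$offset + 1, w$offset + 50))
  expect_error(extract_window(contig, c(50000L, 50001L)), "outside")
})

test_that("find_ltr_pairs pinpoints a constructed repeat pair", {
  set.seed(42)
  ltr <- paste0("TGT", rand_seq(294), "ACA")
  window <- paste0(rand_seq(3000), ltr, rand_seq(4000), ltr, rand_seq(3000))
  cands <- find_ltr_pairs(window)
  expect_length(cands, 1)
  expect_identical(unname(cands[[1]]$left), c(3000L, 3300L))
  expect_identical(unname(cands[[1]]$right), c(3000L + 4300L, 3300L + 4300L))
  expect_equal(cands[[1]]$identity, 1)
  expect_true(cands[[1]]$termini_ok)

  ## right repeat ending ACC violates the terminus rule
  ltr_bad <- paste0(substr(ltr, 1, 297), "ACC")
  win_bad <- paste0(rand_seq(3000), ltr, rand_seq(4000), ltr_bad,
                    rand_seq(3000))
  expect_length(find_ltr_pairs(win_bad), 0)
  ## ... but a one-mismatch allowance readmits it
  expect_gte(length(find_ltr_pairs(win_bad, termini_mismatch = 1)), 1)
})

test_that("confirm_element applies 'if possible' TSD semantics", {
  set.seed(7)
  ltr <- paste0("TGT", rand_seq(194), "ACA")
  tsd <- "ACGT"
  window <- paste0(rand_seq(500), tsd, ltr, rand_seq(2000), ltr, tsd,
                   rand_seq(500))
  cand <- find_ltr_pairs(window, ltr_min_len = 100)[[1]]
  el <- confirm_element(window, cand)
  expect_true(el$tsd_confirmed)
  expect_identical(el$tsd_left, tsd)

  ## unequal flanks: element still returned, flagged unconfirmed
  window2 <- paste0(rand_seq(500), "ACGT", ltr, rand_seq(2000), ltr, "ACGA",
                    rand_seq(500))
  cand2 <- find_ltr_pairs(window2, ltr_min_len = 100)[[1]]
  el2 <- confirm_element(window2, cand2)
  expect_s3_class(el2, "ltr_element")
  expect_false(el2$tsd_confirmed)
})

test_that("ltr_pair_identity matches direct arithmetic on gapless pairs", {
  set.seed(3)
  ltr <- paste0("TGT", rand_seq(294), "ACA")
  ch <- strsplit(ltr, "")[[1]]
  for (i in c(50, 150, 250)) ch[i] <- setdiff(BASES, ch[i])[1]
  ltr2 <- paste(ch, collapse = "")
  contig <- paste0(ltr, rand_seq(1000), ltr2)
  el <- structure(list(ltr5_interval = c(0L, 300L),
                       ltr3_interval = c(1300L, 1600L)),
                  class = "ltr_element")
  expect_equal(ltr_pair_identity(el, contig), 0.99)    # 3/300 mismatches
  el_id <- structure(list(ltr5_interval = c(0L, 300L),
                          ltr3_interval = c(0L, 300L)),
                     class = "ltr_element")
  expect_equal(ltr_pair_identity(el_id, contig), 1)
})

test_that("annotate_genome skips short contigs and deduplicates seeds", {
  tpl <- make_template(seed = 11)
  ev <- evo_params(burst_schedule = list(c(0, 3)), mu_r = 0, mu_h = 0,
                   indel_rate = 0, end_time = 0)
  sim <- simulate_expansion(tpl, n_contigs = 2, contig_len = 60000,
                            evo = ev, seed = 5)
  tr <- sim$truth
  contigs <- c(sim$contigs, short = rand_seq(8000))
  seeds <- data.frame(
    contig = c(tr$contig_id, tr$contig_id[1], "short"),
    start = c((tr$start + tr$end) %/% 2, tr$start[1] + 500L, 4000L),
    end = c((tr$start + tr$end) %/% 2 + 1, tr$start[1] + 501L, 4001L))
  res <- annotate_genome(contigs, seeds)
  expect_identical(res$n_skipped_contigs, 1L)          # 8 kb contig skipped
  ## two seeds inside copy 1 yield one element after dedup
  expect_identical(nrow(res$elements), nrow(tr))
  expect_setequal(paste(res$elements$contig, res$elements$start),
                  paste(tr$contig_id, tr$start))
})

test_that("annotated elements satisfy the structural invariants", {
  tpl <- make_template(seed = 12)
  ev <- evo_params(burst_schedule = list(c(0, 6)), mu_h = 5e-4, end_time = 8,
                   indel_rate = 0)
  sim <- simulate_expansion(tpl, n_contigs = 3, contig_len = 60000,
                            evo = ev, seed = 9)
  tr <- sim$truth
  seeds <- data.frame(contig = tr$contig_id,
                      start = (tr$start + tr$end) %/% 2,
                      end = (tr$start + tr$end) %/% 2 + 1)
  el <- annotate_genome(sim$contigs, seeds)$elements
  for (i in seq_len(nrow(el))) {
    g <- sim$contigs[[el$contig[i]]]
    expect_identical(el$ltr5_start[i], el$start[i])    # LTRs at boundaries
    expect_identical(el$ltr3_end[i], el$end[i])
    expect_identical(substr(g, el$start[i] + 1, el$start[i] + 3), "TGT")
    expect_identical(substr(g, el$end[i] - 2, el$end[i]), "ACA")
    if (el$tsd_confirmed[i]) {
      expect_identical(substr(g, el$start[i] - 3, el$start[i]),
                       substr(g, el$end[i] + 1, el$end[i] + 4))
    }
    expect_true(el$ltr_identity[i] >= 0 && el$ltr_identity[i] <= 1)
  }
})

test_that("older copies have lower expected LTR-pair identity", {
  ## two bursts far apart: rank correlation between birth time and
  ## LTR-pair identity must be positive (older birth = lower identity)
  tpl <- make_template(seed = 13)
  ev <- evo_params(burst_schedule = list(c(0, 15), c(40, 15)), mu_r = 0,
                   mu_h = 1e-3, indel_rate = 0, master_succession_p = 0.3,
                   end_time = 41)
  sim <- simulate_expansion(tpl, n_contigs = 10, contig_len = 60000,
                            evo = ev, seed = 17)
  tr <- sim$truth
  seeds <- data.frame(contig = tr$contig_id,
                      start = (tr$start + tr$end) %/% 2,
                      end = (tr$start + tr$end) %/% 2 + 1)
  el <- annotate_genome(sim$contigs, seeds)$elements
  m <- merge(el, tr, by.x = c("contig", "start"),
             by.y = c("contig_id", "start"))
  expect_gte(nrow(m), 25)
  ## age = end_time - birth_time, so identity must rise with birth_time
  rho <- stats::cor(m$birth_time, m$ltr_identity, method = "spearman")
  expect_gt(rho, 0)
})
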