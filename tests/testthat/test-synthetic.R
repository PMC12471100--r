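test_that("make_template satisfies the element invariants for any seed", {
  for (seed in 1:5) {
    tpl <- make_template(ltr_len = 300, internal_len = 4300, orf_len = 3900,
                         seed = seed)
    expect_identical(substr(tpl$ltr, 1, 3), "TGT")
    expect_identical(substr(tpl$ltr, 298, 300), "ACA")
    expect_identical(tpl$full_len, 2L * 300L + 4300L)
    expect_identical(revcomp(tpl$pbs), tpl$trna_3prime)  # exact PBS match
    orf_len <- tpl$orf_interval[2] - tpl$orf_interval[1]
    expect_identical(as.integer(orf_len %% 3), 0L)
    full <- template_full_seq(tpl)
    orf_seq <- substr(full, tpl$orf_interval[1] + 1, tpl$orf_interval[2])
    cods <- substring(orf_seq, seq(1, orf_len, 3), seq(3, orf_len, 3))
    expect_false(any(cods[-length(cods)] %in% ORACLE_STOPS))
    expect_true(cods[length(cods)] %in% ORACLE_STOPS)
  }
  expect_error(make_template(orf_len = 1000), "multiple of 3")
})

test_that("the predicted ORF recovers the template ORF interval exactly", {
  for (seed in c(2, 9)) {
    tpl <- make_template(seed = seed)
    o <- find_orf(template_full_seq(tpl))
    expect_identical(unname(o$interval), unname(tpl$orf_interval))
  }
})

test_that("zero-mutation expansion yields template-identical, TSD-flanked copies", {
  tpl <- make_template(seed = 3)
  full <- template_full_seq(tpl)
  ev <- evo_params(burst_schedule = list(c(0, 6)), mu_r = 0, mu_h = 0,
                   indel_rate = 0, end_time = 0)
  sim <- simulate_expansion(tpl, n_contigs = 2, contig_len = 60000,
                            evo = ev, seed = 7)
  tr <- sim$truth
  expect_identical(nrow(tr), 6L)
  for (i in seq_len(nrow(tr))) {
    g <- sim$contigs[[tr$contig_id[i]]]
    s <- tr$start[i]; e <- tr$end[i]
    ## TSD mechanics: identical 4-mers flank the interval
    expect_identical(substr(g, s - 3, s), tr$tsd[i])
    expect_identical(substr(g, e + 1, e + 4), tr$tsd[i])
    seq_i <- substr(g, s + 1, e)
    if (tr$strand[i] == "-") seq_i <- revcomp(seq_i)
    expect_identical(seq_i, full)                      # no-mutation limit
  }
  ## all LTR-pair identities = 1 at birth
  el <- annotate_genome(sim$contigs,
                        data.frame(contig = tr$contig_id,
                                   start = (tr$start + tr$end) %/% 2,
                                   end = (tr$start + tr$end) %/% 2 + 1))
  expect_true(all(el$elements$ltr_identity == 1))
  ## genome length conservation: initial + n * (full + 4)
  expect_identical(sum(nchar(sim$contigs)),
                   2L * 60000L + 6L * (tpl$full_len + 4L))
})

test_that("genealogy Newick contains exactly the simulated copy ids", {
  tpl <- make_template(seed = 4)
  ev <- evo_params(burst_schedule = list(c(0, 5), c(3, 4)), mu_h = 5e-4,
                   master_succession_p = 0.5, end_time = 6)
  sim <- simulate_expansion(tpl, n_contigs = 3, contig_len = 60000,
                            evo = ev, seed = 13)
  phy <- ape::read.tree(text = sim$genealogy)
  expect_setequal(phy$tip.label, sim$truth$copy_id)
})

test_that("star-burst mean pairwise difference matches 2 t mu_h", {
  ## star genealogy: each copy diverges independently for t units, so the
  ## expected pairwise difference proportion is ~ 2 t mu_h (small-divergence
  ## regime). Monte-Carlo check across replicate simulations.
  tpl <- make_template(seed = 5)
  mu_h <- 1e-3; t_age <- 10
  vals <- vapply(1:8, function(r) {
    ev <- evo_params(burst_schedule = list(c(0, 8)), mu_r = 0, mu_h = mu_h,
                     indel_rate = 0, master_succession_p = 0,
                     omega = 1, end_time = t_age)
    sim <- simulate_expansion(tpl, n_contigs = 3, contig_len = 60000,
                              evo = ev, seed = 100 + r)
    mean(pairwise_stats(sim$aligned)$p_dist)
  }, numeric(1))
  expected <- 2 * t_age * mu_h
  expect_lt(abs(mean(vals) - expected),
            3 * stats::sd(vals) / sqrt(length(vals)) + 0.1 * expected)
})

test_that("omega = 0 masters accept no nonsynonymous ORF changes", {
  tpl <- make_template(seed = 6)
  full <- template_full_seq(tpl)
  orf0 <- substr(full, tpl$orf_interval[1] + 1, tpl$orf_interval[2])
  ev <- evo_params(burst_schedule = list(c(0, 10)), mu_r = 2e-3, mu_h = 2e-3,
                   indel_rate = 0, omega = 0, master_succession_p = 1,
                   end_time = 5)
  sim <- simulate_expansion(tpl, n_contigs = 3, contig_len = 60000,
                            evo = ev, seed = 21)
  prot0 <- ORACLE_GC[substring(orf0, seq(1, nchar(orf0), 3),
                               seq(3, nchar(orf0), 3))]
  for (id in sim$truth$copy_id) {
    row <- gsub("-", "", sim$aligned$seqs[[id]])
    orf_i <- substr(row, tpl$orf_interval[1] + 1, tpl$orf_interval[2])
    prot <- ORACLE_GC[substring(orf_i, seq(1, nchar(orf_i), 3),
                                seq(3, nchar(orf_i), 3))]
    expect_identical(unname(prot), unname(prot0))
  }
})

test_that("neutral alignments behave at the theta extremes", {
  a <- simulate_neutral_alignment(6, 500, "coalescent", theta = 1e-9,
                                  seed = 1)
  expect_identical(site_frequency_summary(a)$S, 0L)
  expect_error(simulate_neutral_alignment(6, 2, "star", theta = 500,
                                          seed = 1), "more mutations")
})

test_that("simulator truth and outputs survive a disk round-trip", {
  tpl <- make_template(seed = 8)
  ev <- evo_params(burst_schedule = list(c(0, 4)), end_time = 2)
  sim <- simulate_expansion(tpl, n_contigs = 2, contig_len = 55000,
                            evo = ev, seed = 3)
  out <- withr::local_tempdir()
  save_simulation(sim, out)
  expect_true(all(file.exists(file.path(out, c(
    "genome.fasta", "truth.json", "truth.bed", "genealogy.nwk",
    "copies_aligned.fasta")))))
  tj <- jsonlite::read_json(file.path(out, "truth.json"),
                            simplifyVector = TRUE)
  expect_identical(tj$copy_id, sim$truth$copy_id)
  expect_identical(tj$start, sim$truth$start)
  back <- read_alignment(file.path(out, "copies_aligned.fasta"))
  expect_identical(unname(back$seqs), unname(sim$aligned$seqs))
})
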