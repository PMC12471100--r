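test_that("build_consensus applies majority, gap-drop and tie rules", {
  aln <- copy_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_identical(build_consensus(aln), "ACGT")       # idempotence

  aln2 <- copy_alignment(c(a = "AAAA", b = "AAAA", c = "GAAA"))
  expect_identical(substr(build_consensus(aln2), 1, 1), "A")  # majority

  aln3 <- copy_alignment(c(a = "ATT", b = "-TT", c = "-TT"))
  expect_identical(build_consensus(aln3), "TT")        # gap plurality drops

  aln4 <- copy_alignment(c(a = "GT", b = "AT"))        # tie: A < G
  expect_identical(build_consensus(aln4), "AT")

  aln5 <- copy_alignment(c(a = "NT", b = "NT"))        # all-N column
  expect_identical(build_consensus(aln5), "NT")
})

test_that("find_orf returns the longest ATG-initiated frame or NULL", {
  set.seed(5)
  body <- paste(sample(setdiff(ORACLE_SENSE, "ATG"), 999, replace = TRUE),
                collapse = "")
  seq <- paste0(rand_seq(47), "TAA", "ATG", body, "TGA", rand_seq(50))
  ## frame guard: in-frame TAA before ATG so the ORF starts exactly there
  o <- find_orf(seq)
  expect_identical(unname(o$interval), c(50L, 50L + 3L + 2997L + 3L))
  expect_identical(substr(o$protein, 1, 1), "M")
  expect_false(grepl("\\*", o$protein))

  stops_only <- strrep("TAA", 200)
  expect_null(find_orf(stops_only))
})

test_that("cluster_families separates simulated families at 70%", {
  aln <- make_two_family_alignment(n_per = 4, subs = 25, seed = 3)
  copies <- aln$seqs
  res <- cluster_families(copies, threshold = 0.70)
  expect_identical(length(unique(res$families)), 2L)
  ## cluster assignment matches the generating family labels
  expect_identical(length(unique(res$families[paste0("A", 1:4)])), 1L)
  expect_identical(length(unique(res$families[paste0("B", 1:4)])), 1L)
  ## inter-family identity sits in the sub-threshold regime
  expect_lt(max(res$identity[paste0("A", 1:4), paste0("B", 1:4)]), 0.70)

  ## degenerate cases
  same <- c(x = "ACGTACGTCC", y = "ACGTACGTCC", z = "ACGTACGTCC")
  expect_identical(length(unique(cluster_families(same)$families)), 1L)
  one <- cluster_families(c(solo = "ACGTACGT"))
  expect_identical(unname(one$families), "F1")
})

test_that("cluster_families is invariant to input order", {
  aln <- make_two_family_alignment(n_per = 3, subs = 20, seed = 4)
  copies <- aln$seqs
  r1 <- cluster_families(copies)
  r2 <- cluster_families(rev(copies))
  expect_identical(r1$families, r2$families[names(r1$families)])
})

test_that("locate_pbs finds the priming tRNA by reverse complement", {
  trna_lib <- read_fasta(system.file("extdata", "trna_synthetic.fasta",
                                     package = "retroburst"))
  tpl <- make_template(seed = 2)      # built on the tRNA-Lys 3' terminus
  full <- template_full_seq(tpl)
  hit <- locate_pbs(full, ltr5_end = nchar(tpl$ltr), trna_lib = trna_lib)
  expect_identical(hit$trna_id, "trna-Lys_synthetic")
  expect_identical(hit$offset, 0L)
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$length, 18L)

  ## library without the true tRNA: best match below min_match
  expect_null(locate_pbs(full, nchar(tpl$ltr),
                         trna_lib[names(trna_lib) != "trna-Lys_synthetic"]))

  ## one substituted PBS base still matches with max_mismatch = 1
  ch <- strsplit(full, "")[[1]]
  pos <- nchar(tpl$ltr) + 9
  ch[pos] <- setdiff(BASES, ch[pos])[1]
  hit2 <- locate_pbs(paste(ch, collapse = ""), nchar(tpl$ltr), trna_lib)
  expect_identical(hit2$trna_id, "trna-Lys_synthetic")
  expect_identical(hit2$mismatches, 1L)
})
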