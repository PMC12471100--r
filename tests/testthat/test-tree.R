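test_that("neighbor_joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- neighbor_joining(d)
  bl <- stats::setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("neighbor_joining recovers additive-matrix topologies", {
  ## tree ((a:1,b:2):1,(c:3,d:1)) with internal branch 1
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 3
  dm["a", "c"] <- dm["c", "a"] <- 6
  dm["a", "d"] <- dm["d", "a"] <- 4
  dm["b", "c"] <- dm["c", "b"] <- 7
  dm["b", "d"] <- dm["d", "b"] <- 5
  dm["c", "d"] <- dm["d", "c"] <- 4
  phy <- neighbor_joining(dm)
  expect_true(ape::is.monophyletic(ape::root(phy, "d"), c("a", "b")))
  ## branch lengths reproduce the additive tree (path a-b = 3, c-d = 4)
  pd <- ape::cophenetic.phylo(phy)
  expect_equal(pd["a", "b"], 3)
  expect_equal(pd["c", "d"], 4)
  expect_equal(pd["b", "c"], 7)

  expect_error(neighbor_joining(matrix(NA_real_, 3, 3,
                                       dimnames = list(1:3, 1:3))),
               "missing distance")

  ## degenerate equal distances: all branch lengths non-negative
  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  expect_true(all(neighbor_joining(eq)$edge.length >= 0))
})

test_that("bootstrap_support is deterministic and bounded", {
  aln <- make_two_family_alignment(n_per = 4, subs = 25, seed = 8)
  b1 <- bootstrap_support(aln, reps = 25, seed = 5)
  b2 <- bootstrap_support(aln, reps = 25, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  ## reps = 1: supports are all-or-nothing
  b3 <- bootstrap_support(aln, reps = 1, seed = 6)
  expect_true(all(b3$support %in% c(0, 100)))
  ## the family split must be strongly supported
  fam_split <- names(b1$support)[vapply(strsplit(names(b1$support), "\r"),
    function(x) setequal(x, paste0("B", 1:4)) || setequal(x, paste0("A", 1:4)),
    logical(1))]
  expect_gte(min(b1$support[fam_split]), 95)
  ## Newick round-trip keeps topology and supports
  p <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(b1$tree, p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, names(aln$seqs))
})

test_that("check_monophyly classifies constructed topologies", {
  tree <- ape::read.tree(
    text = "((a1:1,a2:1):1,((b1:1,b2:1):1,((c1:1,c2:1):2,b3:1):1):1);")
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B",
         c1 = "C", c2 = "C")
  rep <- check_monophyly(tree, g)
  expect_identical(rep$classification[rep$group == "A"], "monophyletic")
  expect_identical(rep$classification[rep$group == "B"], "paraphyletic")
  expect_identical(rep$classification[rep$group == "C"], "monophyletic")

  ## polyphyly: interleaved groups
  t2 <- ape::read.tree(text = "((x1:1,y1:1):1,(x2:1,y2:1):1,(x3:1,y3:1):1);")
  g2 <- c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y", y2 = "Y", y3 = "Y")
  rep2 <- check_monophyly(t2, g2)
  expect_true(all(rep2$classification == "polyphyletic"))

  ## trivial groups: all leaves, single leaf
  g3 <- c(x1 = "all", x2 = "all", x3 = "all", y1 = "all", y2 = "all",
          y3 = "all")
  expect_identical(check_monophyly(t2, g3)$classification, "monophyletic")
  expect_error(check_monophyly(t2, character(0)))

  ## Newick text input is accepted directly
  rep3 <- check_monophyly("((a:1,b:1):1,(c:1,d:1):1);",
                          c(a = "g1", b = "g1", c = "g2", d = "g2"))
  expect_true(all(rep3$classification == "monophyletic"))
})
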