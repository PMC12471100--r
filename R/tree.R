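# Distance-based tree building with bootstrap support, and
# monophyly/paraphyly classification of copy groups. Neighbor-joining plus
# column bootstrap is the fully self-contained stand-in for external
# maximum-likelihood tree inference; external Newick trees can be fed
# straight into check_monophyly().

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Saitou & Nei). Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling edge. Ties in the
#' Q-criterion are broken by row-major order, making the topology
#' deterministic for a given label order.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames
#'   (>= 3 taxa), or a `dist` object.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3,
            !is.null(rownames(d)))
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("missing distance for pair ", rownames(d)[bad[1]], " / ",
         colnames(d)[bad[2]], call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  labs <- rownames(d)
  nodes <- as.list(labs)                    # newick fragment per active node
  D <- d
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (length(nodes) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); j <- max(ij)
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    sub <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(vi), nodes[[j]], fmt(vj))
    dk <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    nodes <- c(nodes[keep], sub)
    D <- D2
  }
  ## final three: closed-form leaf branch lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1]], fmt(la), nodes[[2]],
                 fmt(lb), nodes[[3]], fmt(lc))
  ape::read.tree(text = txt)
}

## distance matrix from an integer-coded alignment
aln_dist_matrix <- function(im, method = c("p", "f84"), saturated_value = 5) {
  method <- match.arg(method)
  n <- nrow(im)
  d <- matrix(0, n, n, dimnames = list(rownames(im), rownames(im)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- im[i, ]; b <- im[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
      aa <- a[ok]; bb <- b[ok]
      if (method == "p") {
        d[i, j] <- d[j, i] <- mean(aa != bb)
      } else {
        cs <- length(aa)
        diff <- aa != bb
        ts <- sum(diff & (aa %% 2L == bb %% 2L))
        tv <- sum(diff) - ts
        freqs <- (tabulate(aa, 4L) + tabulate(bb, 4L)) / (2 * cs)
        f <- f84_distance(ts / cs, tv / cs, freqs)
        d[i, j] <- d[j, i] <- if (f$saturated) saturated_value else f$distance
      }
    }
  }
  d
}

## canonical bipartition keys of the non-trivial splits of an unrooted tree;
## named by the internal node defining each split
tree_split_keys <- function(phy, ref_labels = sort(phy$tip.label)) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  anchor <- ref_labels[1]
  keys <- character(0)
  nodes <- integer(0)
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(ntip))
  for (nd in internal) {
    tips <- phy$tip.label[phangorn::Descendants(phy, nd, "tips")[[1]]]
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next
    side <- sort(tips)
    if (anchor %in% side) side <- sort(setdiff(phy$tip.label, side))
    keys <- c(keys, paste(side, collapse = "\r"))
    nodes <- c(nodes, nd)
  }
  stats::setNames(nodes, keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the alignment under the chosen distance (F84 by
#' default, matching the distance model used for saturation analysis), then
#' resamples alignment columns with replacement `reps` times; support of an
#' internal edge is the percentage of replicate trees containing the same
#' bipartition.
#'
#' @param alignment A `copy_alignment`.
#' @param method `"f84"` or `"p"` distances.
#' @param reps Bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return List with `tree` (an `ape::phylo` whose `node.label` carries the
#'   support percentages) and `support` (named vector, bipartition key ->
#'   percentage).
#' @export
bootstrap_support <- function(alignment, method = c("f84", "p"),
                              reps = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "copy_alignment"), reps >= 1)
  method <- match.arg(method)
  im <- aln_int_matrix(alignment$seqs)
  phy <- neighbor_joining(aln_dist_matrix(im, method))
  ref <- sort(phy$tip.label)
  orig <- tree_split_keys(phy, ref)
  hits <- stats::setNames(numeric(length(orig)), names(orig))
  set.seed(seed)
  L <- ncol(im)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    bphy <- neighbor_joining(aln_dist_matrix(im[, cols, drop = FALSE],
                                             method))
    bk <- names(tree_split_keys(bphy, ref))
    seen <- names(hits) %in% bk
    hits[seen] <- hits[seen] + 1
  }
  support <- 100 * hits / reps
  ntip <- length(phy$tip.label)
  nlab <- rep("", phy$Nnode)
  nlab[unname(orig) - ntip] <- formatC(support, format = "f", digits = 0)
  phy$node.label <- nlab
  list(tree = phy, support = support)
}

#' Classify copy groups as mono-, para- or polyphyletic
#'
#' On the unrooted topology: a group is monophyletic iff some edge
#' bipartitions exactly that group from all other taxa (singletons and the
#' full taxon set are trivially monophyletic). A non-monophyletic group is
#' paraphyletic when it becomes a bipartition side after adding one nested
#' foreign clade - i.e. there are splits `Y` and `X` with `X` disjoint from
#' the group and `Y = group + X` (the classic signature of a derived
#' sublineage arising inside a parental family). Anything else is
#' polyphyletic.
#'
#' @param tree An `ape::phylo` (or Newick string / file path).
#' @param groups Named character vector: tip label -> group label.
#' @return Data frame of class `monophyly_report`: group, n_tips,
#'   classification, supporting edge node (NA unless monophyletic).
#' @export
check_monophyly <- function(tree, groups) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (length(groups) == 0) stop("empty group map", call. = FALSE)
  tips <- tree$tip.label
  missing <- setdiff(names(groups), tips)
  groups <- groups[names(groups) %in% tips]
  if (length(missing) > 0) {
    rb_log("group members absent from tree: ",
           paste(missing, collapse = ", "), level = "WARN")
  }
  phy <- ape::unroot(tree)
  ntip <- length(tips)
  ## all bipartition sides (as sorted label vectors), non-trivial
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(ntip))
  sides <- list()
  side_node <- integer(0)
  for (nd in internal) {
    tps <- sort(tips[phangorn::Descendants(phy, nd, "tips")[[1]]])
    if (length(tps) < 1 || length(tps) >= ntip) next
    sides[[length(sides) + 1L]] <- tps
    side_node <- c(side_node, nd)
    sides[[length(sides) + 1L]] <- sort(setdiff(tips, tps))
    side_node <- c(side_node, nd)
  }
  ## single tips are also split sides
  for (tp in tips) {
    sides[[length(sides) + 1L]] <- tp
    side_node <- c(side_node, match(tp, tips))
    sides[[length(sides) + 1L]] <- sort(setdiff(tips, tp))
    side_node <- c(side_node, match(tp, tips))
  }
  side_keys <- vapply(sides, paste, character(1), collapse = "\r")
  rows <- list()
  for (gl in sort(unique(groups))) {
    mem <- sort(names(groups)[groups == gl])
    if (length(mem) == 0) stop("group of size 0: ", gl, call. = FALSE)
    key <- paste(mem, collapse = "\r")
    cls <- NA_character_
    edge_node <- NA_integer_
    if (length(mem) == 1 || length(mem) == ntip) {
      cls <- "monophyletic"
    } else if (key %in% side_keys) {
      cls <- "monophyletic"
      edge_node <- side_node[match(key, side_keys)]
    } else {
      ## paraphyly: some split side Y contains the group and Y \ group is
      ## itself a split side (the nested foreign clade)
      para <- FALSE
      for (si in seq_along(sides)) {
        Y <- sides[[si]]
        if (length(Y) <= length(mem) || !all(mem %in% Y)) next
        X <- sort(setdiff(Y, mem))
        if (paste(X, collapse = "\r") %in% side_keys) { para <- TRUE; break }
      }
      cls <- if (para) "paraphyletic" else "polyphyletic"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = gl, n_tips = length(mem), classification = cls,
      edge_node = edge_node, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("monophyly_report", "data.frame")
  out
}
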