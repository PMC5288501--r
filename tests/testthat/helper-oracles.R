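# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package's own code paths.

# naive O(n^3) complete-linkage agglomeration; returns the sorted merge
# heights and the cophenetic matrix
naive_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        h <- max(d[groups[[a]], groups[[b]]])
        if (h < best[1L]) best <- c(h, a, b)
      }
    }
    ga <- groups[[best[2L]]]; gb <- groups[[best[3L]]]
    coph[ga, gb] <- best[1L]; coph[gb, ga] <- best[1L]
    heights <- c(heights, best[1L])
    groups[[best[2L]]] <- c(ga, gb)
    groups[[best[3L]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# non-trivial bipartitions of an unrooted ape tree, as canonical strings
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n_tip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > n_tip
  splits <- character(0)
  desc <- phangorn::Descendants(tree, tree$edge[internal, 2L], type = "tips")
  for (d in desc) {
    side <- sort(tree$tip.label[d])
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    splits <- c(splits, paste(canon, collapse = ","))
  }
  unique(splits)
}

# RF distance by explicit bipartition enumeration
naive_rf <- function(t1, t2) {
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# all 15 unrooted binary topologies on 5 leaves
all_five_leaf_trees <- function() {
  newicks <- c(
    "((A,B),(C,D),E);", "((A,B),(C,E),D);", "((A,B),(D,E),C);",
    "((A,C),(B,D),E);", "((A,C),(B,E),D);", "((A,C),(D,E),B);",
    "((A,D),(B,C),E);", "((A,D),(B,E),C);", "((A,D),(C,E),B);",
    "((A,E),(B,C),D);", "((A,E),(B,D),C);", "((A,E),(C,D),B);",
    "(((A,B),C),D,E);", "(((A,B),D),C,E);", "(((A,B),E),C,D);")
  lapply(newicks, function(x) ape::read.tree(text = x))
}

# brute-force Pearson r over explicitly enumerated strain pairs
brute_pair_pearson <- function(m1, m2, ids) {
  x <- c(); y <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      x <- c(x, m1[ids[i], ids[j]])
      y <- c(y, m2[ids[i], ids[j]])
    }
  }
  keep <- !is.na(x) & !is.na(y)
  cor(x[keep], y[keep])
}

# random binary tree with positive branch lengths
random_binary_tree <- function(n, min_edge = 0.1, max_edge = 1) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), min_edge, max_edge)
  tr
}

# tiny two-gene alignment fixture with known properties
toy_alignment <- function() {
  gene_alignment(
    "toy",
    c("s1", "s2", "s3", "s4"),
    c("MKLV", "MKLV", "MRLV", "MRLI"),
    codon_rows = c("ATGAAATTAGTT", "ATGAAATTGGTT",
                   "ATGAGATTAGTT", "ATGAGATTAATT"))
}
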