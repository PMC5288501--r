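# Tree-level concordance: neighbor joining from distance matrices, patristic
# distances, Robinson-Foulds distance, alignment concatenation, and
# matrix-vs-matrix Pearson correlation.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}). Negative branch lengths, which
#' NJ can produce on non-additive matrices, are clamped to 0 with the
#' deficit transferred to the sibling edge (floored at 0); the number of
#' clamped edges is messaged.
#'
#' @param dist A [distance_matrix()] with at least 3 taxa and no `NA`.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  if (anyNA(dist)) stop("distance matrix has NA entries; cannot run NJ")
  if (nrow(dist) < 3L) stop("NJ needs at least 3 taxa")
  tr <- ape::nj(as.dist(unclass(dist)))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    for (e in neg) {
      parent <- tr$edge[e, 1L]
      sib <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      if (length(sib))
        tr$edge.length[sib[1L]] <- max(0, tr$edge.length[sib[1L]] + deficit)
    }
    message(length(neg), " negative NJ branch length(s) clamped to 0")
  }
  tr
}

#' Patristic distances between tree leaves
#'
#' `d(i, j)` is the sum of branch lengths along the i-j path.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A [distance_matrix()] of kind `"patristic"`.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  distance_matrix(ape::cophenetic.phylo(tree), kind = "patristic")
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets, in the unrooted convention (rooted inputs are unrooted
#' first).
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  extra1 <- setdiff(t1$tip.label, t2$tip.label)
  extra2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(extra1) || length(extra2))
    stop("leaf sets differ; only in tree 1: {",
         paste(extra1, collapse = ", "), "}; only in tree 2: {",
         paste(extra2, collapse = ", "), "}")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Concatenate gene alignments
#'
#' Column-wise concatenation of alignments over an identical strain set
#' (rows reordered to the first alignment's order); per-gene protein-column
#' offsets are recorded in the `offsets` attribute so individual genes can
#' be sliced back out.
#'
#' @param alns List of [gene_alignment()] objects.
#' @param gene_id Identifier of the concatenated alignment.
#' @return A [gene_alignment()] with attribute `offsets` (data.frame
#'   `gene_id`, `start`, `end`, 1-based closed protein columns).
#' @export
concat_alignments <- function(alns, gene_id = "concat") {
  if (!length(alns)) stop("no alignments to concatenate")
  ids <- alns[[1L]]$strain_ids
  for (a in alns[-1L]) {
    if (!setequal(a$strain_ids, ids))
      stop("gene '", a$gene_id, "': strain set differs from '",
           alns[[1L]]$gene_id, "'")
  }
  prot <- rep("", length(ids))
  codon <- rep("", length(ids))
  have_codon <- all(vapply(alns, function(a) !is.null(a$codon_rows),
                           logical(1L)))
  offsets <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  at <- 0L
  for (a in alns) {
    ord <- match(ids, a$strain_ids)
    len <- nchar(a$protein_rows[1L])
    prot <- paste0(prot, a$protein_rows[ord])
    if (have_codon) codon <- paste0(codon, a$codon_rows[ord])
    offsets <- rbind(offsets, data.frame(gene_id = a$gene_id,
                                         start = at + 1L, end = at + len,
                                         stringsAsFactors = FALSE))
    at <- at + len
  }
  out <- gene_alignment(gene_id, ids, prot,
                        codon_rows = if (have_codon) codon else NULL)
  attr(out, "offsets") <- offsets
  out
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the upper-triangle vectors of the two matrices over their
#' shared ids (pairs with `NA` in either dropped); the two-sided p-value
#' uses the t transform with `n_pairs - 2` degrees of freedom. Each strain
#' pair is one observation, as in gene-by-gene association scans.
#'
#' @param d1,d2 [distance_matrix()]-like square matrices with dimnames.
#' @return List: `r`, `p_value`, `n_pairs` (`r = NA` under zero variance).
#' @export
matrix_correlation <- function(d1, d2) {
  shared <- intersect(rownames(d1), rownames(d2))
  if (length(shared) < 4L) stop("need at least 4 shared ids")
  pt <- pair_table(a = unclass(d1)[shared, shared, drop = FALSE],
                   b = unclass(d2)[shared, shared, drop = FALSE])
  pt <- pt[!is.na(pt$a) & !is.na(pt$b), , drop = FALSE]
  if (nrow(pt) < 3L || var(pt$a) == 0 || var(pt$b) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_pairs = nrow(pt)))
  ct <- cor.test(pt$a, pt$b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(pt))
}
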