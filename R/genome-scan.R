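# Genome-wide machinery: identity-by-state distances with LD pruning and
# complete-linkage clustering; per-gene protein distances, allele counts and
# synonymous/non-synonymous tallies; the gene-by-gene distance-vs-segregation
# scan under a Sidak familywise threshold; candidate co-location.

#' Identity-by-state genomic distance
#'
#' For each strain pair, IBS is the fraction of co-observed (pairwise
#' deletion of missing data) sites carrying identical alleles; the distance
#' is `1 - IBS`.
#'
#' @param snp An [snp_matrix()].
#' @return A [distance_matrix()] of kind `"genomic-IBS"`; pairs with zero
#'   co-observed sites are `NA` with a warning.
#' @export
ibs_distance <- function(snp) {
  g <- snp$genotypes
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  n_empty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      obs <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(obs)) {
        d[i, j] <- d[j, i] <- NA_real_
        n_empty <- n_empty + 1L
      } else {
        d[i, j] <- d[j, i] <- 1 - mean(g[i, obs] == g[j, obs])
      }
    }
  }
  if (n_empty > 0L)
    warning(n_empty, " strain pair(s) share no co-observed sites (NA)")
  distance_matrix(d, kind = "genomic-IBS")
}

#' Prune SNP sites in linkage disequilibrium
#'
#' Greedy left-to-right scan within each chromosome (sites in position
#' order): a site is dropped when its squared allelic correlation with any
#' already-retained site inside the trailing window reaches `r2_threshold`.
#' The default threshold 1.0 removes only perfect duplicates; a threshold
#' above 1 removes nothing. Deterministic given site order.
#'
#' @param snp An [snp_matrix()].
#' @param r2_threshold Squared-correlation threshold (default 1.0).
#' @param window_sites Trailing window size in sites (default `Inf`, the
#'   whole chromosome).
#' @return An [snp_matrix()] with the retained sites.
#' @export
ld_prune <- function(snp, r2_threshold = 1.0, window_sites = Inf) {
  g <- snp$genotypes
  chroms <- if (is.null(snp$chromosome)) rep("chr0", ncol(g)) else
    snp$chromosome
  pos <- if (is.null(snp$position)) seq_len(ncol(g)) else snp$position
  # numeric coding: first observed allele -> 0, others -> 1, 2, ...
  num <- apply(g, 2L, function(col) {
    lev <- unique(col[!is.na(col)])
    as.numeric(match(col, lev)) - 1
  })
  keep <- logical(ncol(g))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)[order(pos[chroms == chr])]
    retained <- integer(0)
    for (j in idx) {
      recent <- utils::tail(retained, n = if (is.finite(window_sites))
        window_sites else length(retained))
      drop <- FALSE
      for (k in rev(recent)) {
        r <- suppressWarnings(cor(num[, j], num[, k],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 >= r2_threshold) { drop <- TRUE; break }
      }
      if (!drop) { retained <- c(retained, j); keep[j] <- TRUE }
    }
  }
  snp_matrix(g[, keep, drop = FALSE],
             chromosome = if (is.null(snp$chromosome)) NULL else
               snp$chromosome[keep],
             position = if (is.null(snp$position)) NULL else
               snp$position[keep])
}

#' Complete-linkage hierarchical clustering
#'
#' Standard complete-linkage agglomeration of a distance matrix; merge
#' heights are non-decreasing by construction.
#'
#' @param dist A [distance_matrix()] (no `NA` entries).
#' @return An [stats::hclust] dendrogram.
#' @export
complete_linkage <- function(dist) {
  if (anyNA(dist)) stop("distance matrix has NA entries; cannot cluster")
  hclust(as.dist(unclass(dist)), method = "complete")
}

#' Cophenetic distances from a dendrogram
#'
#' `d(i, j)` is the merge height at which i and j first join; the result is
#' ultrametric.
#'
#' @param dendro An [stats::hclust] object.
#' @return A [distance_matrix()] of kind `"cophenetic"`.
#' @export
cophenetic_distances <- function(dendro) {
  distance_matrix(as.matrix(cophenetic(dendro)), kind = "cophenetic")
}

#' Uncorrected protein p-distance
#'
#' Pairwise mismatch fraction over compared columns. Gap handling:
#' `"complete-deletion"` (default) removes every column containing a gap in
#' any row before comparison; `"pairwise-deletion"` compares, per pair, the
#' columns where neither sequence is gapped.
#'
#' @param aln A [gene_alignment()].
#' @param gap_mode Gap handling mode.
#' @return A [distance_matrix()] of kind `"per-gene-protein"`; pairs with
#'   zero comparable columns are `NA` with a warning.
#' @export
protein_distance <- function(aln, gap_mode = c("complete-deletion",
                                               "pairwise-deletion")) {
  gap_mode <- match.arg(gap_mode)
  m <- aln_matrix(aln, "protein")
  gap <- m == "-" | m == "."
  n <- nrow(m)
  if (gap_mode == "complete-deletion") {
    keep <- colSums(gap) == 0L
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  # one-hot residue encoding: matches(i,j) = OH_i . OH_j with gap columns
  # zeroed; compared(i,j) = ok_i . ok_j (pairwise deletion of gaps)
  ok <- !gap
  states <- unique(as.vector(m[ok]))
  oh <- matrix(0L, n, ncol(m) * length(states))
  for (s in seq_along(states)) {
    hit <- (m == states[s]) & ok
    oh[, (s - 1L) * ncol(m) + seq_len(ncol(m))] <- hit
  }
  matches <- tcrossprod(oh)
  compared <- tcrossprod(ok * 1L)
  d <- 1 - matches / compared
  d[compared == 0L] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  n_empty <- sum(is.na(d[upper.tri(d)]))
  if (n_empty > 0L)
    warning("gene '", aln$gene_id, "': ", n_empty,
            " pair(s) share no comparable columns (NA)")
  distance_matrix(d, kind = "per-gene-protein")
}

#' Number of distinct protein alleles
#'
#' Counts distinct aligned protein row strings; with `strip_gaps = TRUE`
#' gap characters are removed before comparison.
#'
#' @param aln A [gene_alignment()].
#' @param strip_gaps Remove gaps before comparing (default `FALSE`).
#' @return Integer allele count.
#' @export
count_protein_alleles <- function(aln, strip_gaps = FALSE) {
  rows <- aln$protein_rows
  if (strip_gaps) rows <- gsub("[-.]", "", rows)
  length(unique(rows))
}

#' Synonymous / non-synonymous variant site counts
#'
#' For each polymorphic codon column-triple of the codon alignment, the
#' consensus codon is the most frequent valid codon (ties broken
#' alphabetically). Every distinct non-consensus codon variant is classified
#' synonymous iff it translates (standard genetic code) to the same amino
#' acid as the consensus, and contributes its number of variant nucleotide
#' positions to the corresponding tally. Codons containing gaps or ambiguity
#' codes are skipped and counted.
#'
#' @param aln A [gene_alignment()] with codon rows.
#' @return List: `n_syn`, `n_nonsyn`, `n_total`, `n_skipped_codons`.
#' @export
count_syn_nonsyn <- function(aln) {
  if (is.null(aln$codon_rows))
    stop("gene '", aln$gene_id, "': codon rows are required")
  len <- nchar(aln$codon_rows[1L])
  if (len %% 3L != 0L)
    stop("gene '", aln$gene_id, "': codon alignment length ", len,
         " is not divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  n_syn <- 0L; n_nonsyn <- 0L; n_skipped <- 0L
  n_codons <- len %/% 3L
  cods <- vapply(seq_len(n_codons), function(cidx)
    substr(aln$codon_rows, 3L * cidx - 2L, 3L * cidx),
    character(length(aln$codon_rows)))
  if (is.null(dim(cods))) cods <- matrix(cods, nrow = 1L)
  poly <- colSums(cods != matrix(cods[1L, ], nrow(cods), ncol(cods),
                                 byrow = TRUE)) > 0L
  valid_all <- matrix(grepl("^[ACGT]{3}$", cods), nrow(cods), ncol(cods))
  n_skipped <- sum(!valid_all[, !poly, drop = FALSE])
  for (cidx in which(poly)) {
    codons <- cods[, cidx]
    valid <- valid_all[, cidx]
    n_skipped <- n_skipped + sum(!valid)
    codons <- codons[valid]
    if (length(codons) < 2L) next
    tab <- table(codons)
    consensus <- names(tab)[order(-tab, names(tab))][1L]
    variants <- setdiff(names(tab), consensus)
    if (!length(variants)) next
    cons_split <- strsplit(consensus, "")[[1L]]
    for (v in variants) {
      ndiff <- sum(strsplit(v, "")[[1L]] != cons_split)
      if (gc[[v]] == gc[[consensus]]) n_syn <- n_syn + ndiff
      else n_nonsyn <- n_nonsyn + ndiff
    }
  }
  list(n_syn = n_syn, n_nonsyn = n_nonsyn, n_total = n_syn + n_nonsyn,
       n_skipped_codons = n_skipped)
}

#' Sidak-corrected per-test alpha
#'
#' `alpha' = 1 - (1 - fwer)^(1/n_tests)` controls the familywise error rate
#' over `n_tests` independent tests.
#'
#' @param fwer Familywise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return Per-test significance level.
#' @examples
#' sidak_alpha(0.05, 6532)  # 7.85e-06
#' sidak_alpha(0.05, 15)    # 0.0034
#' @export
sidak_alpha <- function(fwer, n_tests) {
  if (!is.finite(fwer) || fwer <= 0 || fwer >= 1)
    stop("fwer must lie in (0,1)")
  if (!is.finite(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  1 - (1 - fwer)^(1 / n_tests)
}

#' Genome-wide gene-distance vs segregation scan
#'
#' The greenbeard association scan: for every gene, the Pearson correlation
#' between the upper-triangle vector of its pairwise protein p-distances and
#' the corresponding normalized segregation values (self-mixes excluded;
#' pairs with `NA` in either dropped), with the two-sided p-value from the t
#' transform at `n_pairs - 2` degrees of freedom. A gene passes when its p
#' falls below the Sidak-corrected alpha for the number of genes actually
#' tested (genes with zero variance in either vector are recorded with `NA`
#' and excluded from the multiplicity count, with a warning).
#'
#' @param genes List of [gene_alignment()] objects.
#' @param segmat A [segregation_matrix()].
#' @param fwer Familywise error rate (default 0.05).
#' @param gap_mode Gap handling passed to [protein_distance()].
#' @param min_strains Minimum strains shared with the matrix (default 4).
#' @param tally_sites Compute per-gene synonymous/non-synonymous variant
#'   tallies when codon rows are present (default `TRUE`).
#' @param n_perm If > 0, also compute a permutation p-value per gene by
#'   jointly permuting rows/columns of the segregation matrix.
#' @return data.frame (one row per gene, sorted by decreasing r) with
#'   columns `gene_id`, `chromosome`, `start`, `end`, `n_strains`, `n_pairs`,
#'   `r`, `p_value`, `n_alleles`, `n_snps_total`, `n_syn`, `n_nonsyn`,
#'   `pct_total`, `pct_syn`, `pct_nonsyn`, `passes_threshold` (+ `p_perm`
#'   when requested); the per-test alpha is attached as attribute
#'   `sidak_alpha`.
#' @export
greenbeard_scan <- function(genes, segmat, fwer = 0.05,
                            gap_mode = c("complete-deletion",
                                         "pairwise-deletion"),
                            min_strains = 4L, tally_sites = TRUE,
                            n_perm = 0L) {
  gap_mode <- match.arg(gap_mode)
  nsv <- unclass(segmat)
  rows <- vector("list", length(genes))
  n_skipped <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    pos <- g$position
    rec <- data.frame(
      gene_id = g$gene_id,
      chromosome = if (is.null(pos)) NA_character_ else pos$chromosome,
      start = if (is.null(pos)) NA_real_ else pos$start,
      end = if (is.null(pos)) NA_real_ else pos$end,
      n_strains = NA_integer_, n_pairs = NA_integer_,
      r = NA_real_, p_value = NA_real_,
      n_alleles = count_protein_alleles(g),
      n_snps_total = NA_integer_, n_syn = NA_integer_,
      n_nonsyn = NA_integer_, pct_total = NA_real_, pct_syn = NA_real_,
      pct_nonsyn = NA_real_, passes_threshold = NA,
      stringsAsFactors = FALSE)
    if (tally_sites && !is.null(g$codon_rows)) {
      sn <- count_syn_nonsyn(g)
      len_nt <- nchar(g$codon_rows[1L])
      rec$n_snps_total <- sn$n_total
      rec$n_syn <- sn$n_syn
      rec$n_nonsyn <- sn$n_nonsyn
      rec$pct_total <- 100 * sn$n_total / len_nt
      rec$pct_syn <- 100 * sn$n_syn / len_nt
      rec$pct_nonsyn <- 100 * sn$n_nonsyn / len_nt
    }
    shared <- intersect(g$strain_ids, rownames(nsv))
    if (length(shared) < min_strains) {
      n_skipped <- n_skipped + 1L
      rows[[gi]] <- rec
      next
    }
    D <- suppressWarnings(protein_distance(g, gap_mode))
    pt <- pair_table(dist = unclass(D)[shared, shared, drop = FALSE],
                     nsv = nsv[shared, shared, drop = FALSE])
    pt <- pt[!is.na(pt$dist) & !is.na(pt$nsv), , drop = FALSE]
    rec$n_strains <- length(shared)
    rec$n_pairs <- nrow(pt)
    if (nrow(pt) >= 3L && var(pt$dist) > 0 && var(pt$nsv) > 0) {
      ct <- cor.test(pt$dist, pt$nsv, method = "pearson")
      rec$r <- unname(ct$estimate)
      rec$p_value <- ct$p.value
      if (n_perm > 0L) {
        obs <- abs(rec$r)
        ids <- unique(c(pt$id_a, pt$id_b))
        hits <- 0L
        M <- nsv[ids, ids, drop = FALSE]
        Dm <- unclass(D)[ids, ids, drop = FALSE]
        for (b in seq_len(n_perm)) {
          perm <- sample(length(ids))
          Mp <- M[perm, perm, drop = FALSE]
          dimnames(Mp) <- list(ids, ids)
          ppt <- pair_table(dist = Dm, nsv = Mp)
          ppt <- ppt[!is.na(ppt$dist) & !is.na(ppt$nsv), , drop = FALSE]
          rp <- suppressWarnings(cor(ppt$dist, ppt$nsv))
          if (!is.na(rp) && abs(rp) >= obs) hits <- hits + 1L
        }
        rec$p_perm <- (hits + 1L) / (n_perm + 1L)
      }
    } else {
      n_skipped <- n_skipped + 1L
    }
    rows[[gi]] <- rec
  }
  out <- do.call(rbind, rows)
  n_tested <- sum(!is.na(out$r))
  if (n_skipped > 0L)
    warning(n_skipped, " gene(s) with too few strains or zero variance: ",
            "r = NA, excluded from the multiplicity count")
  alpha <- if (n_tested >= 1L) sidak_alpha(fwer, n_tested) else NA_real_
  out$passes_threshold <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[order(-out$r, out$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sidak_alpha") <- alpha
  attr(out, "n_tested") <- n_tested
  attr(out, "fwer") <- fwer
  out
}

#' Co-locate candidate genes along the genome
#'
#' Single-linkage clustering of passing scan records by genomic proximity:
#' two candidates join the same cluster when the gap between their intervals
#' on the same chromosome is at most `window_bp`.
#'
#' @param records A scan result from [greenbeard_scan()].
#' @param window_bp Maximum gap in bp (default 50000).
#' @param passing_only Cluster only genes with `passes_threshold` (default
#'   `TRUE`).
#' @return data.frame `gene_id`, `chromosome`, `start`, `end`, `cluster`
#'   (`NA` cluster for records without positions, which are reported
#'   unclustered).
#' @export
colocate_candidates <- function(records, window_bp = 50000,
                                passing_only = TRUE) {
  df <- records
  if (passing_only) df <- df[!is.na(df$passes_threshold) &
                               df$passes_threshold, , drop = FALSE]
  df <- df[, c("gene_id", "chromosome", "start", "end")]
  df$cluster <- NA_integer_
  has_pos <- !is.na(df$chromosome) & !is.na(df$start) & !is.na(df$end)
  cl <- 0L
  for (chr in unique(df$chromosome[has_pos])) {
    idx <- which(has_pos & df$chromosome == chr)
    idx <- idx[order(df$start[idx])]
    cur_end <- -Inf
    for (i in idx) {
      if (df$start[i] - cur_end > window_bp) cl <- cl + 1L
      df$cluster[i] <- cl
      cur_end <- max(cur_end, df$end[i])
    }
  }
  rownames(df) <- NULL
  df
}
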