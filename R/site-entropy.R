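# Per-column Shannon entropy of protein alignments, conserved/diversifying
# site classification, positional clustering of high-entropy sites, and
# two-group haplotype assignment.

#' Shannon entropy of one alignment column
#'
#' `H = -sum(p_a * log(p_a))` over the observed residue frequencies of the
#' column, in the requested log base. Gaps are excluded from the
#' frequencies (the published analyses removed gapped sites before
#' downstream work, so gaps are not a 21st state here).
#'
#' @param residues Character vector of column residues.
#' @param base Log base (default natural log).
#' @return Entropy, or `NA` if fewer than 2 non-gap residues remain.
#' @export
column_entropy <- function(residues, base = exp(1)) {
  res <- residues[!(residues %in% c("-", ".")) & !is.na(residues)]
  if (length(res) < 2L) return(NA_real_)
  p <- table(res) / length(res)
  -sum(p * log(p, base = base))
}

#' Per-column entropy profile of a protein alignment
#'
#' Computes Shannon entropy for every column and classifies each as
#' `monomorphic` (one residue state), `conserved` (variable, H below the
#' cutoff), `diversifying` (H above the cutoff), `at-cutoff`, or
#' `insufficient` (< 2 non-gap residues).
#'
#' @param aln A [gene_alignment()].
#' @param base Log base (default natural log).
#' @param cutoff Entropy cutoff separating conserved from diversifying
#'   variable sites (default 1.0).
#' @return data.frame (class `entropy_profile`) with columns `column`
#'   (1-based), `n_obs`, `n_states`, `H`, `class`; `gene_id`, `base` and
#'   `cutoff` are attached as attributes.
#' @export
entropy_profile <- function(aln, base = exp(1), cutoff = 1.0) {
  m <- aln_matrix(aln, "protein")
  L <- ncol(m)
  out <- data.frame(column = seq_len(L), n_obs = NA_integer_,
                    n_states = NA_integer_, H = NA_real_,
                    class = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    col <- m[, j]
    res <- col[!(col %in% c("-", ".")) & !is.na(col)]
    out$n_obs[j] <- length(res)
    out$n_states[j] <- length(unique(res))
    out$H[j] <- column_entropy(col, base = base)
    out$class[j] <-
      if (length(res) < 2L) "insufficient"
      else if (out$n_states[j] == 1L) "monomorphic"
      else if (out$H[j] < cutoff) "conserved"
      else if (out$H[j] > cutoff) "diversifying"
      else "at-cutoff"
  }
  structure(out, gene_id = aln$gene_id, base = base, cutoff = cutoff,
            class = c("entropy_profile", "data.frame"))
}

#' Count conserved and diversifying variable sites
#'
#' Variable sites are columns with at least 2 residue states; they are
#' partitioned by the entropy cutoff, with exact-cutoff columns reported
#' separately so `n_variable = n_below + n_above + n_at_cutoff`.
#'
#' @param profile An [entropy_profile()].
#' @param cutoff Optional cutoff overriding the profile's own.
#' @return List: `n_variable`, `n_below_cutoff`, `n_above_cutoff`,
#'   `n_at_cutoff`.
#' @export
classify_sites <- function(profile, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- attr(profile, "cutoff")
  variable <- !is.na(profile$n_states) & profile$n_states >= 2L &
    profile$class != "insufficient"
  H <- profile$H[variable]
  list(n_variable = sum(variable),
       n_below_cutoff = sum(H < cutoff),
       n_above_cutoff = sum(H > cutoff),
       n_at_cutoff = sum(H == cutoff))
}

#' Positional clustering of diversifying sites
#'
#' Sliding-window counts of diversifying sites along the alignment; reports
#' the maximal-density window (first window on ties) and, when a region such
#' as an N-terminal span is declared, whether that window overlaps it.
#'
#' @param profile An [entropy_profile()].
#' @param window Window width in columns.
#' @param region Optional 1-based closed interval `c(start, end)`.
#' @return List: `window_counts` (data.frame `start`, `end`, `n_diversifying`),
#'   `max_window` (row of the maximal window), `overlaps_region` (logical or
#'   `NA` when no region given).
#' @export
positional_clustering <- function(profile, window, region = NULL) {
  L <- nrow(profile)
  if (window > L)
    stop("window (", window, ") exceeds alignment length (", L, ")")
  div <- as.integer(profile$class == "diversifying")
  cs <- c(0L, cumsum(div))
  starts <- seq_len(L - window + 1L)
  counts <- cs[starts + window] - cs[starts]
  wc <- data.frame(start = starts, end = starts + window - 1L,
                   n_diversifying = counts)
  best <- wc[which.max(wc$n_diversifying), , drop = FALSE]
  overlaps <- NA
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] <= region[2L])
    overlaps <- best$start <= region[2L] && best$end >= region[1L]
  }
  list(window_counts = wc, max_window = best, overlaps_region = overlaps)
}

#' Haplotype groups by cutting the locus dendrogram
#'
#' Complete-linkage clustering of the locus distance matrix cut at `k`
#' groups; groups are labeled `A`, `B`, ... by decreasing size (ties by the
#' lexicographically smallest member).
#'
#' @param locus_dist A [distance_matrix()].
#' @param k Number of groups (default 2).
#' @return Named character vector of group labels per strain.
#' @export
haplotype_groups <- function(locus_dist, k = 2L) {
  n <- nrow(locus_dist)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of strains (", n, ")")
  hc <- complete_linkage(locus_dist)
  grp <- cutree(hc, k = k)
  size <- table(grp)
  first_member <- vapply(names(size), function(g)
    min(names(grp)[grp == as.integer(g)]), character(1L))
  ord <- order(-as.integer(size), first_member)
  relabel <- setNames(LETTERS[seq_len(k)], names(size)[ord])
  setNames(unname(relabel[as.character(grp)]), names(grp))
}
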