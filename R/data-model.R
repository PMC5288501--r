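# Core domain types. Lightweight S3: each constructor validates its
# invariants and stamps a class; downstream code relies on the invariants
# holding (readers and simulators only ever hand out validated objects).

#' Per-mix fruiting-body composition
#'
#' One clonal or chimeric developmental mix: the ordered strains it contains,
#' which strain was fluorescently labeled (the focal strain), and the percent
#' of the focal strain recorded in each fruiting body.
#'
#' @param mix_id Mix identifier.
#' @param strains Character vector of 2-3 strain identifiers (identical ids
#'   denote a self-mix).
#' @param focal_strain The labeled strain whose percentage was recorded; must
#'   be a member of `strains`.
#' @param fb_percent Numeric vector of per-fruiting-body percentages in
#'   \[0, 100\]; at least 2 fruiting bodies.
#' @return A `mix_composition` object.
#' @export
mix_composition <- function(mix_id, strains, focal_strain, fb_percent) {
  stopifnot(length(mix_id) == 1L, is.character(strains))
  if (length(strains) < 2L || length(strains) > 3L)
    stop("mix '", mix_id, "': a mix holds 2 or 3 strains, got ",
         length(strains))
  if (!focal_strain %in% strains)
    stop("mix '", mix_id, "': focal strain '", focal_strain,
         "' is not among the mixed strains")
  fb_percent <- as.numeric(fb_percent)
  if (length(fb_percent) < 2L)
    stop("mix '", mix_id, "': at least 2 fruiting bodies are required")
  bad <- which(!is.finite(fb_percent) | fb_percent < 0 | fb_percent > 100)
  if (length(bad))
    stop("mix '", mix_id, "': fruiting-body percentage outside [0,100] at ",
         "position ", bad[1L], " (value ", fb_percent[bad[1L]], ")")
  structure(
    list(mix_id = as.character(mix_id), strains = strains,
         focal_strain = focal_strain, fb_percent = fb_percent,
         is_self_mix = length(unique(strains)) == 1L),
    class = "mix_composition")
}

#' @export
print.mix_composition <- function(x, ...) {
  cat(sprintf("<mix_composition> %s: %s (focal %s), %d FBs%s\n",
              x$mix_id, paste(x$strains, collapse = " + "),
              x$focal_strain, length(x$fb_percent),
              if (x$is_self_mix) " [self-mix]" else ""))
  invisible(x)
}

#' Symmetric pairwise distance matrix
#'
#' Container for strain-by-strain distances (genomic identity-by-state,
#' per-gene protein p-distance, patristic, or cophenetic). Enforces symmetry,
#' zero diagonal and non-negativity; `NA` entries are allowed for pairs that
#' could not be compared.
#'
#' @param values Square numeric matrix with row/column names (the ids), or an
#'   unnamed matrix plus `ids`.
#' @param kind Label describing how the distances were derived.
#' @param ids Optional identifiers when `values` carries no dimnames.
#' @return A `distance_matrix` object (a named matrix with attributes).
#' @export
distance_matrix <- function(values, kind = "generic", ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) stop("distance matrix needs ids (dimnames or `ids`)")
  dimnames(values) <- list(ids, ids)
  off <- values[!is.na(values)]
  if (any(off < 0)) stop("distance matrix has negative entries")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("distance matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (any(abs(diag(values)) > 1e-8, na.rm = TRUE))
    stop("distance matrix diagonal must be zero")
  diag(values) <- 0
  structure(values, kind = kind, class = c("distance_matrix", "matrix"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> kind=%s, %d ids\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Extract upper-triangle pair values of one or more distance-like matrices
#'
#' Aligns the matrices on their shared ids and returns one row per unordered
#' pair with the corresponding entries, in a fixed (lexicographic within the
#' shared-id ordering) pair order. Used by all matrix-vs-matrix correlations
#' so that every caller enumerates pairs identically.
#'
#' @param ... Named square matrices with dimnames.
#' @return data.frame with columns `id_a`, `id_b` and one column per matrix.
#' @export
pair_table <- function(...) {
  mats <- list(...)
  if (is.null(names(mats)) || any(names(mats) == ""))
    stop("pair_table() arguments must be named")
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 2L) stop("fewer than 2 shared ids")
  idx <- which(upper.tri(diag(length(shared))), arr.ind = TRUE)
  out <- data.frame(id_a = shared[idx[, 1L]], id_b = shared[idx[, 2L]],
                    stringsAsFactors = FALSE)
  for (nm in names(mats)) {
    m <- mats[[nm]][shared, shared, drop = FALSE]
    out[[nm]] <- m[idx]
  }
  out
}

#' Strain-by-strain normalized segregation matrix
#'
#' Symmetric matrix of normalized segregation values (nsv, in percent) for
#' hetero pairs, with self-mix nsv kept apart in `self_values` (the diagonal
#' is `NA` and never enters association scans).
#'
#' @param values Symmetric numeric matrix of nsv in \[0,100\] with strain
#'   dimnames; `NA` for unmeasured pairs.
#' @param self_values Named numeric vector of per-strain self-mix nsv
#'   (`NA` where no self-mix was run).
#' @return A `segregation_matrix` object.
#' @export
segregation_matrix <- function(values, self_values = NULL) {
  values <- as.matrix(values)
  strains <- rownames(values)
  if (is.null(strains)) stop("segregation matrix needs strain dimnames")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("segregation matrix is not symmetric")
  rng <- range(values[!is.na(values)])
  if (length(rng) == 2L && (rng[1L] < 0 || rng[2L] > 100))
    stop("nsv entries must lie in [0,100]")
  diag(values) <- NA_real_
  if (is.null(self_values))
    self_values <- setNames(rep(NA_real_, length(strains)), strains)
  self_values <- self_values[strains]
  names(self_values) <- strains
  structure(values, self_values = self_values,
            class = c("segregation_matrix", "matrix"))
}

#' @export
print.segregation_matrix <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<segregation_matrix> %d strains, %d measured pairs\n",
              nrow(v), sum(!is.na(v[upper.tri(v)]))))
  invisible(x)
}

#' Per-gene multiple alignment
#'
#' Aligned protein rows (and optionally the matching codon rows) for one gene
#' across strains. All rows must have equal length; codon rows, if present,
#' must be exactly three times the protein length.
#'
#' @param gene_id Gene identifier.
#' @param strain_ids Unique strain identifiers, one per row.
#' @param protein_rows Character vector of equal-length aligned amino-acid
#'   strings (gap character `-`).
#' @param codon_rows Optional aligned nucleotide strings, length 3x protein.
#' @param position Optional list with `chromosome`, `start`, `end` (1-based,
#'   closed).
#' @return A `gene_alignment` object.
#' @export
gene_alignment <- function(gene_id, strain_ids, protein_rows,
                           codon_rows = NULL, position = NULL) {
  if (anyDuplicated(strain_ids))
    stop("gene '", gene_id, "': duplicate strain id '",
         strain_ids[duplicated(strain_ids)][1L], "'")
  if (length(strain_ids) != length(protein_rows))
    stop("gene '", gene_id, "': one protein row per strain required")
  lens <- nchar(protein_rows)
  if (length(unique(lens)) != 1L)
    stop("gene '", gene_id, "': ragged alignment; record '",
         strain_ids[which(lens != lens[1L])[1L]], "' has length ",
         lens[which(lens != lens[1L])[1L]], " (expected ", lens[1L], ")")
  if (!is.null(codon_rows)) {
    clens <- nchar(codon_rows)
    if (length(codon_rows) != length(strain_ids) ||
        any(clens != 3L * lens[1L]))
      stop("gene '", gene_id, "': codon rows must be 3x the protein length")
  }
  structure(
    list(gene_id = as.character(gene_id), strain_ids = as.character(strain_ids),
         protein_rows = toupper(protein_rows),
         codon_rows = if (is.null(codon_rows)) NULL else toupper(codon_rows),
         position = position),
    class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d strains x %d aa%s\n", x$gene_id,
              length(x$strain_ids), nchar(x$protein_rows[1L]),
              if (is.null(x$codon_rows)) "" else " (+codon)"))
  invisible(x)
}

# protein rows as a strains x columns character matrix
aln_matrix <- function(aln, what = c("protein", "codon")) {
  what <- match.arg(what)
  rows <- if (what == "protein") aln$protein_rows else aln$codon_rows
  if (is.null(rows)) stop("gene '", aln$gene_id, "': no ", what, " rows")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- aln$strain_ids
  m
}

#' Haploid SNP genotype matrix
#'
#' Strain-by-site haploid allele codes with optional genomic coordinates.
#' Sites with fewer than two observed allele states (after removing missing
#' data) are flagged monomorphic.
#'
#' @param genotypes Character matrix (strains x sites) of allele codes;
#'   `NA` encodes missing.
#' @param chromosome,position Optional per-site coordinates (1-based).
#' @return An `snp_matrix` object.
#' @export
snp_matrix <- function(genotypes, chromosome = NULL, position = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) stop("snp matrix needs strain rownames")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("site", seq_len(ncol(genotypes)))
  n_states <- apply(genotypes, 2L, function(g) length(unique(g[!is.na(g)])))
  structure(
    list(genotypes = genotypes,
         strain_ids = rownames(genotypes), site_ids = colnames(genotypes),
         chromosome = chromosome, position = position,
         monomorphic = n_states < 2L),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d strains x %d sites (%d monomorphic)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$monomorphic)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults: the
#' null-quantile level for the gamma threshold, the entropy log base and
#' cutoff, the familywise error rate for the Sidak correction, gap handling
#' for protein distances, LD pruning, and bootstrap settings.
#'
#' @param seed Integer seed used for every stochastic step.
#' @param quantile_level Gamma-null quantile defining the segregation
#'   threshold (default 0.99).
#' @param manual_threshold Optional explicit nsv cutoff overriding the fitted
#'   quantile (the published analysis used 18).
#' @param entropy_base Log base for Shannon entropy (default `exp(1)`).
#' @param entropy_cutoff Diversifying-site cutoff (default 1.0).
#' @param fwer Familywise error rate for Sidak correction (default 0.05).
#' @param gap_mode Protein-distance gap handling, `"complete-deletion"` or
#'   `"pairwise-deletion"`.
#' @param ld_r2_threshold Squared-correlation threshold for LD pruning
#'   (default 1.0: only perfect duplicates removed).
#' @param ld_window Trailing window, in sites, for LD pruning (default `Inf`:
#'   whole chromosome).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param subsample_size Fruiting bodies per bootstrap subsample (default 10).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, quantile_level = 0.99,
                            manual_threshold = NULL,
                            entropy_base = exp(1), entropy_cutoff = 1.0,
                            fwer = 0.05,
                            gap_mode = c("complete-deletion",
                                         "pairwise-deletion"),
                            ld_r2_threshold = 1.0, ld_window = Inf,
                            n_boot = 1000L, subsample_size = 10L) {
  stopifnot(quantile_level > 0, quantile_level < 1, fwer > 0, fwer < 1,
            n_boot >= 1L)
  structure(list(seed = as.integer(seed), quantile_level = quantile_level,
                 manual_threshold = manual_threshold,
                 entropy_base = entropy_base, entropy_cutoff = entropy_cutoff,
                 fwer = fwer, gap_mode = match.arg(gap_mode),
                 ld_r2_threshold = ld_r2_threshold, ld_window = ld_window,
                 n_boot = as.integer(n_boot),
                 subsample_size = as.integer(subsample_size)),
            class = "pipeline_config")
}
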