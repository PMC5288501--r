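# Readers and writers. TSV throughout, single header row, "NA"/empty for
# missing; alignment FASTA via Biostrings; trees via ape. Readers validate
# the domain invariants and name the offending record on failure.

#' Read a mix-composition table
#'
#' Parses a TSV with columns `mix_id`, `strain_a`, `strain_b`
#' (optionally `strain_c`), `focal_strain`, `fb_percent` - one row per
#' fruiting body - and groups rows by `mix_id` in stable input order.
#'
#' @param path Path to the TSV file.
#' @return List of [mix_composition()] objects, one per mix.
#' @export
read_mix_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("mix_id", "strain_a", "strain_b", "focal_strain", "fb_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mix table is missing column(s): ", paste(miss, collapse = ", "))
  pct <- suppressWarnings(as.numeric(df$fb_percent))
  bad <- which(is.na(pct) | pct < 0 | pct > 100)
  if (length(bad))
    stop("mix table row ", bad[1L] + 1L, " (mix '", df$mix_id[bad[1L]],
         "'): fb_percent '", df$fb_percent[bad[1L]],
         "' is not a number in [0,100]")
  df$fb_percent <- pct
  ids <- unique(df$mix_id)
  lapply(ids, function(id) {
    rows <- df[df$mix_id == id, , drop = FALSE]
    strains <- unlist(rows[1L, intersect(c("strain_a", "strain_b", "strain_c"),
                                         names(rows))])
    strains <- as.character(strains[!is.na(strains)])
    mix_composition(id, strains, rows$focal_strain[1L], rows$fb_percent)
  })
}

#' Write a mix-composition table
#'
#' Inverse of [read_mix_table()]: one row per fruiting body.
#'
#' @param mixes List of [mix_composition()] objects.
#' @param path Output TSV path.
#' @export
write_mix_table <- function(mixes, path) {
  rows <- lapply(mixes, function(m) {
    s <- c(m$strains, rep(NA_character_, 3L - length(m$strains)))
    data.frame(mix_id = m$mix_id, strain_a = s[1L], strain_b = s[2L],
               strain_c = s[3L], focal_strain = m$focal_strain,
               fb_percent = m$fb_percent, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a gene alignment from FASTA
#'
#' Reads an aligned protein FASTA (and optionally the matching codon FASTA)
#' into a [gene_alignment()]. Wrapped sequence lines are handled by the FASTA
#' parser; equal row length and unique ids are enforced here.
#'
#' @param path Protein alignment FASTA.
#' @param codon_path Optional codon alignment FASTA with the same ids.
#' @param gene_id Gene identifier; defaults to the file base name.
#' @param position Optional list with `chromosome`, `start`, `end`.
#' @return A [gene_alignment()].
#' @export
read_alignment_fasta <- function(path, codon_path = NULL, gene_id = NULL,
                                 position = NULL) {
  if (is.null(gene_id))
    gene_id <- sub("\\.(fa|fasta|faa|fna)$", "", basename(path))
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("'", path, "': duplicate record id '", ids[duplicated(ids)][1L], "'")
  codon <- NULL
  if (!is.null(codon_path)) {
    nt <- Biostrings::readBStringSet(codon_path)
    cid <- sub("\\s.*$", "", names(nt))
    nt <- nt[match(ids, cid)]
    if (anyNA(match(ids, cid)))
      stop("'", codon_path, "': codon records do not match protein ids")
    codon <- as.character(nt)
  }
  gene_alignment(gene_id, ids, unname(as.character(aa)),
                 codon_rows = if (is.null(codon)) NULL else unname(codon),
                 position = position)
}

#' Write a gene alignment to FASTA
#'
#' @param aln A [gene_alignment()].
#' @param path Protein FASTA output path.
#' @param codon_path Optional codon FASTA output path.
#' @export
write_alignment_fasta <- function(aln, path, codon_path = NULL) {
  writeLines(paste0(">", aln$strain_ids, "\n", aln$protein_rows), path)
  if (!is.null(codon_path)) {
    if (is.null(aln$codon_rows))
      stop("gene '", aln$gene_id, "' has no codon rows")
    writeLines(paste0(">", aln$strain_ids, "\n", aln$codon_rows), codon_path)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} so the whole pipeline shares one entry point.
#' The round trip `read_newick(write_newick(t))` preserves topology and
#' branch lengths to 1e-9.
#'
#' @param path Newick file (a single tree).
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("failed to parse Newick '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse Newick '", path, "'")
  if (inherits(tr, "multiPhylo")) stop("'", path, "': expected a single tree")
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}

#' Read a haploid SNP genotype table
#'
#' TSV with columns `site_id`, optional `chromosome` and `position`, then one
#' column per strain carrying haploid allele codes (`NA`/empty = missing).
#'
#' @param path Path to the TSV.
#' @return An [snp_matrix()].
#' @export
read_snp_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                   check.names = FALSE)
  if (!"site_id" %in% names(df)) stop("snp table needs a site_id column")
  meta <- intersect(c("site_id", "chromosome", "position"), names(df))
  strains <- setdiff(names(df), meta)
  if (length(strains) < 2L) stop("snp table needs at least 2 strain columns")
  g <- t(as.matrix(df[, strains, drop = FALSE]))
  colnames(g) <- df$site_id
  snp_matrix(g, chromosome = df$chromosome, position = df$position)
}

#' Write a haploid SNP genotype table
#'
#' @param snp An [snp_matrix()].
#' @param path Output TSV path.
#' @export
write_snp_table <- function(snp, path) {
  df <- data.frame(site_id = snp$site_ids, stringsAsFactors = FALSE)
  if (!is.null(snp$chromosome)) df$chromosome <- snp$chromosome
  if (!is.null(snp$position)) df$position <- snp$position
  df <- cbind(df, as.data.frame(t(snp$genotypes), stringsAsFactors = FALSE))
  write_tsv(df, path)
  invisible(path)
}

#' Read phenotype tables
#'
#' `read_binding_table`: TSV with columns `strain_a`, `strain_b`,
#' `replicate`, `intensity_bound`, `intensity_not_bound`, and optionally
#' `intensity_input`, `protein_amount_ug`. `read_migration_table`: TSV with
#' columns `experiment`, `strain_a`, `strain_b` (empty/`NA` for clonal rows),
#' `trail_length`.
#'
#' @param path Path to the TSV.
#' @return data.frame with validated columns.
#' @export
read_binding_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("strain_a", "strain_b", "replicate", "intensity_bound",
            "intensity_not_bound")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("binding table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$intensity_bound < 0 | df$intensity_not_bound < 0)
  if (length(bad))
    stop("binding table row ", bad[1L] + 1L, ": negative intensity")
  df
}

#' @rdname read_binding_table
#' @export
read_migration_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("experiment", "strain_a", "strain_b", "trail_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("migration table is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read / write a segregation matrix as TSV
#'
#' The matrix is stored with strains as both header and first column; a
#' final row named `self` carries the per-strain self-mix nsv.
#'
#' @param path TSV path.
#' @return `read_segregation_matrix`: a [segregation_matrix()].
#' @export
read_segregation_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = 1L)
  m <- as.matrix(df)
  self <- NULL
  if ("self" %in% rownames(m)) {
    self <- m["self", ]
    m <- m[rownames(m) != "self", , drop = FALSE]
  }
  segregation_matrix(m, self_values = self)
}

#' @rdname read_segregation_matrix
#' @param segmat A [segregation_matrix()].
#' @export
write_segregation_matrix <- function(segmat, path) {
  m <- rbind(unclass(segmat), self = attr(segmat, "self_values"))
  df <- data.frame(strain = rownames(m), format_num(m),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# single TSV writing convention: header row, tab-separated, no quoting,
# floats at 6 significant digits
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer,
                                                       logical(1L))
  df[num] <- lapply(df[num], function(x) format_num(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- NA_character_
  if (is.matrix(x)) dim(out) <- dim(x)
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  out
}
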