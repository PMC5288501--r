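# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: ~4 deep strain clusters with genome-wide phylogenetic
# signal; a linked two-gene locus with elevated N-terminal diversity and two
# deep haplotype groups decoupled from the strain phylogeny (ancient
# trans-species polymorphism); fruiting-body compositions whose dispersion
# follows locus distance; self-mix compositions giving a gamma-like null;
# binding decreasing and migration deficit increasing with segregation.

NTS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a strain phylogeny and genome-wide SNPs
#'
#' Builds a random ultrametric strain tree with `n_clusters` deep clades
#' (coalescent-style joins within clusters at shallow heights, between
#' clusters at deep heights) and drops biallelic haploid SNPs on its
#' branches under an infinite-sites model: each site mutates once, on an
#' edge chosen with probability proportional to its length, so all tips
#' below that edge carry the derived allele.
#'
#' @param n_strains Number of strains (>= 4; default 20).
#' @param n_clusters Number of deep clades (default 4).
#' @param n_sites Number of SNP sites (default 3000).
#' @param seed Optional integer seed.
#' @param within_height Maximum coalescent height inside a cluster
#'   (default 0.3); deep joins happen in `deep_range`.
#' @param deep_range Height range of between-cluster joins (default
#'   `c(0.7, 1)`).
#' @return List: `tree` ([ape::phylo]), `snps` ([snp_matrix()]), `clusters`
#'   (named integer vector of true clade memberships).
#' @export
simulate_strains <- function(n_strains = 20L, n_clusters = 4L,
                             n_sites = 3000L, seed = NULL,
                             within_height = 0.3, deep_range = c(0.7, 1)) {
  if (!is.null(seed)) set.seed(seed)
  if (n_strains < 4L) stop("need at least 4 strains")
  if (n_clusters > n_strains)
    stop("cannot place ", n_strains, " strains into ", n_clusters,
         " clusters")
  labels <- sprintf("strain%02d", seq_len(n_strains))
  sizes <- rep(1L, n_clusters)
  if (n_strains > n_clusters) {
    extra <- as.vector(stats::rmultinom(1L, n_strains - n_clusters,
                                        rep(1 / n_clusters, n_clusters)))
    sizes <- sizes + extra
  }
  clusters <- rep(seq_len(n_clusters), sizes)
  names(clusters) <- labels
  cluster_nodes <- lapply(seq_len(n_clusters), function(ci) {
    labs <- labels[clusters == ci]
    tips <- lapply(labs, function(l) list(label = l, height = 0))
    if (length(tips) == 1L) return(tips[[1L]])
    coalesce_nodes(tips, runif(length(tips) - 1L, within_height / 2,
                               within_height))
  })
  root <- if (n_clusters == 1L) cluster_nodes[[1L]] else
    coalesce_nodes(cluster_nodes,
                   runif(n_clusters - 1L, deep_range[1L], deep_range[2L]))
  tree <- ape::read.tree(text = node_to_newick(root))
  # drop SNPs: one mutation per site, edge sampled by length
  ed <- tree$edge
  elen <- tree$edge.length
  desc <- phangorn::Descendants(tree, ed[, 2L], type = "tips")
  site_edge <- sample.int(nrow(ed), n_sites, replace = TRUE, prob = elen)
  ref <- sample(NTS, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NTS, r), 1L), character(1L))
  g <- matrix(rep(ref, each = n_strains), nrow = n_strains,
              dimnames = list(tree$tip.label,
                              sprintf("snp%05d", seq_len(n_sites))))
  for (s in seq_len(n_sites)) g[desc[[site_edge[s]]], s] <- alt[s]
  snps <- snp_matrix(g, chromosome = rep("chr1", n_sites),
                     position = sort(sample.int(1e7L, n_sites)))
  list(tree = tree, snps = snps, clusters = clusters)
}

# sequential random coalescent over a list of subtree nodes at the given
# join heights (must all exceed the nodes' own heights)
coalesce_nodes <- function(nodes, heights) {
  for (h in sort(heights)) {
    pick <- sample.int(length(nodes), 2L)
    joined <- list(children = nodes[pick], height = h)
    nodes <- c(nodes[-pick], list(joined))
  }
  nodes[[1L]]
}

node_to_newick <- function(root) {
  rec <- function(node, parent_height) {
    blen <- parent_height - node$height
    if (!is.null(node$label))
      return(sprintf("%s:%.9f", node$label, blen))
    inner <- paste(vapply(node$children, rec, character(1L),
                          parent_height = node$height), collapse = ",")
    sprintf("(%s):%.9f", inner, blen)
  }
  if (!is.null(root$label)) return(sprintf("(%s:0);", root$label))
  inner <- paste(vapply(root$children, rec, character(1L),
                        parent_height = root$height), collapse = ",")
  sprintf("(%s);", inner)
}

# evolve a nucleotide sequence down the tree; rates is a per-site rate
# vector; returns tips x sites character matrix
evolve_on_tree <- function(tree, root_seq, rates) {
  tree <- stats::reorder(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_seq
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    seqs[[child]] <- mutate_seq(seqs[[par]], rates, tree$edge.length[e])
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

# Poisson mutation along one branch; mutations creating a stop codon are
# reverted so coding frames stay open
mutate_seq <- function(seq, rates, blen) {
  L <- length(seq)
  k <- rpois(1L, blen * sum(rates))
  if (k == 0L) return(seq)
  k <- min(k, L)
  uniform <- min(rates) == max(rates)
  pos <- if (uniform) sample.int(L, k) else sample.int(L, k, prob = rates)
  for (p in pos) {
    old <- seq[p]
    new <- sample(setdiff(NTS, old), 1L)
    seq[p] <- new
    cod <- (p - 1L) %/% 3L
    if (paste(seq[cod * 3L + 1:3], collapse = "") %in% STOP_CODONS)
      seq[p] <- old
  }
  seq
}

random_sense_codons <- function(n_codons) {
  all64 <- apply(expand.grid(NTS, NTS, NTS), 1L, paste, collapse = "")
  sense <- setdiff(all64, STOP_CODONS)
  unlist(strsplit(sample(sense, n_codons, replace = TRUE), "", fixed = TRUE))
}

translate_rows <- function(codon_strings) {
  gc <- Biostrings::GENETIC_CODE
  vapply(codon_strings, function(s) {
    n <- nchar(s)
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Simulate the planted two-gene greenbeard locus
#'
#' Evolves two linked codon alignments with substitution rate elevated by
#' `rate_multiplier` in the N-terminal `n_term_fraction` of columns, and a
#' forced deep haplotype split: all strains of group B receive a shared set
#' of fixed N-terminal differences covering `split_divergence` of the
#' N-terminal sites. By default (`decouple = TRUE`) the within-group
#' genealogy uses the strain tree's shape with tip labels permuted, so the
#' locus distances are decoupled from genome-wide relatedness - the ancient
#' trans-species polymorphism a polychromatic greenbeard locus is expected
#' to show; with `decouple = FALSE` the genes evolve literally on the strain
#' tree.
#'
#' @param tree Strain tree from [simulate_strains()].
#' @param rate_multiplier N-terminal rate elevation (> 1 for a planted
#'   signal; 1 with `n_term_fraction = 0` gives a background-like gene).
#' @param n_term_fraction Fraction of columns forming the fast N-terminal
#'   region (default 0.25).
#' @param deep_split Character vector of group-B strains (default: a random
#'   half of the strains).
#' @param seed Optional integer seed.
#' @param n_codons Codons per gene (default 300).
#' @param base_rate Background substitution rate per site per unit branch
#'   length (default 0.003).
#' @param split_divergence Fraction of N-terminal sites fixed between the
#'   haplotype groups (default 0.6).
#' @param decouple Permute the gene genealogy's tip labels (default `TRUE`).
#' @param gene_ids Identifiers of the two genes.
#' @return List: `genes` (two [gene_alignment()] with codon rows), `groups`
#'   (named "A"/"B" labels), `deep_split`, `n_term_columns` (protein
#'   columns in the fast region).
#' @export
simulate_locus <- function(tree, rate_multiplier = 20, n_term_fraction = 0.25,
                           deep_split = NULL, seed = NULL, n_codons = 300L,
                           base_rate = 0.003, split_divergence = 0.6,
                           decouple = TRUE,
                           gene_ids = c("tgrB1", "tgrC1")) {
  if (!is.null(seed)) set.seed(seed)
  if (rate_multiplier < 1) stop("rate_multiplier must be >= 1")
  tips <- tree$tip.label
  if (is.null(deep_split))
    deep_split <- sort(sample(tips, length(tips) %/% 2L))
  gene_tree <- tree
  if (decouple) gene_tree$tip.label <- sample(tips)
  L <- 3L * n_codons
  nterm_len <- 3L * round(n_term_fraction * n_codons)
  rates <- rep(base_rate, L)
  if (nterm_len > 0L)
    rates[seq_len(nterm_len)] <- base_rate * rate_multiplier
  genes <- vector("list", length(gene_ids))
  names(genes) <- gene_ids
  for (gid in gene_ids) {
    m <- evolve_on_tree(gene_tree, random_sense_codons(n_codons), rates)
    m <- apply_deep_split(m, deep_split, nterm_len, split_divergence)
    codon_rows <- apply(m[tips, , drop = FALSE], 1L, paste, collapse = "")
    genes[[gid]] <- gene_alignment(gid, tips, translate_rows(codon_rows),
                                   codon_rows = unname(codon_rows))
  }
  groups <- setNames(ifelse(tips %in% deep_split, "B", "A"), tips)
  list(genes = genes, groups = groups, deep_split = deep_split,
       n_term_columns = nterm_len %/% 3L)
}

# overwrite a random subset of N-terminal sites with a fixed group-B allele;
# per-row reverts that would create stops
apply_deep_split <- function(m, b_rows, nterm_len, divergence) {
  b_rows <- intersect(b_rows, rownames(m))
  n_split <- round(divergence * nterm_len)
  if (nterm_len == 0L || n_split == 0L || !length(b_rows)) return(m)
  a_rows <- setdiff(rownames(m), b_rows)
  sites <- sample.int(nterm_len, n_split)
  for (s in sites) {
    maj <- names(sort(table(m[a_rows, s]), decreasing = TRUE))[1L]
    alt <- sample(setdiff(NTS, maj), 1L)
    cod <- (s - 1L) %/% 3L
    for (b in b_rows) {
      old <- m[b, s]
      m[b, s] <- alt
      if (paste(m[b, cod * 3L + 1:3], collapse = "") %in% STOP_CODONS)
        m[b, s] <- old
    }
  }
  m
}

#' Simulate background genes on the strain tree
#'
#' Evolves `n_genes` unlinked codon alignments at the uniform background
#' rate on the strain tree (one long concatenated simulation, sliced per
#' gene).
#'
#' @param tree Strain tree.
#' @param n_genes Number of genes (default 500).
#' @param n_codons Codons per gene (default 100).
#' @param base_rate Substitution rate per site per unit branch length.
#' @param seed Optional integer seed.
#' @param prefix Gene-id prefix.
#' @return List of [gene_alignment()] objects with codon rows.
#' @export
simulate_background_genes <- function(tree, n_genes = 500L, n_codons = 100L,
                                      base_rate = 0.003, seed = NULL,
                                      prefix = "gene") {
  if (!is.null(seed)) set.seed(seed)
  L <- 3L * n_codons
  m <- evolve_on_tree(tree, random_sense_codons(n_codons * n_genes),
                      rep(base_rate, L * n_genes))
  lapply(seq_len(n_genes), function(g) {
    idx <- ((g - 1L) * L + 1L):(g * L)
    codon_rows <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
    gene_alignment(sprintf("%s%04d", prefix, g), tree$tip.label,
                   translate_rows(codon_rows),
                   codon_rows = unname(codon_rows))
  })
}

#' Map locus distances to target segregation values
#'
#' A saturating monotone coupling: `nsv = nsv_max * d / (d + d_half)` plus
#' Gaussian noise, clipped to \[0, 100\]. At `d = 0` only the noise
#' baseline remains; as `d` grows the target approaches `nsv_max`.
#'
#' @param locus_dist A [distance_matrix()] of locus distances.
#' @param nsv_max Asymptotic nsv (default 95).
#' @param d_half Half-saturation distance (default a quarter of the mean
#'   pairwise distance).
#' @param noise_sd Gaussian noise s.d. in nsv units (default 7).
#' @param seed Optional integer seed.
#' @return data.frame `strain_a`, `strain_b`, `locus_dist`, `target_nsv`.
#' @export
nsv_from_locus <- function(locus_dist, nsv_max = 95, d_half = NULL,
                           noise_sd = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pt <- pair_table(locus_dist = unclass(locus_dist))
  if (is.null(d_half)) d_half <- 0.25 * mean(pt$locus_dist)
  if (!is.finite(d_half) || d_half <= 0) d_half <- 1e-6
  mu <- nsv_max * pt$locus_dist / (pt$locus_dist + d_half)
  pt$target_nsv <- pmin(100, pmax(0, mu + rnorm(nrow(pt), 0, noise_sd)))
  names(pt)[1:2] <- c("strain_a", "strain_b")
  pt
}

#' Coupling-free target segregation values
#'
#' Null-control targets: independent of any distance, drawn around a common
#' mean. Used to verify that the genome scan stays quiet when nothing is
#' planted.
#'
#' @param n Number of pairs.
#' @param mean_nsv,sd_nsv Target distribution (defaults 40 and 15).
#' @param seed Optional integer seed.
#' @return Numeric vector of targets clipped to \[1, 99\].
#' @export
nsv_targets_null <- function(n, mean_nsv = 40, sd_nsv = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmin(99, pmax(1, rnorm(n, mean_nsv, sd_nsv)))
}

#' Sample a fruiting-body composition for a target nsv
#'
#' Per-fruiting-body focal-strain proportions are drawn from a symmetric
#' Beta(a, a) with `a = ((100 / target)^2 - 1) / 2`, times 100. Because
#' `Var(p) = 1 / (4 (2a + 1))` for Beta(a, a), the expected population
#' standard deviation of the percentages is `target / 2` while the mean is
#' 50 (so the nsv ceiling is 50), giving `E[nsv]` approximately equal to the
#' target. Limits: target <= 0 gives a point mass at 50; target >= 100
#' gives two-point 0/100 draws (guarded so both points occur).
#'
#' @param target_nsv Target nsv in \[0, 100\].
#' @param n_fb Number of fruiting bodies (>= 2).
#' @param mix_id Mix identifier.
#' @param strains Strain pair (or triple) of the mix.
#' @param focal_strain Labeled strain (default the first).
#' @return A [mix_composition()].
#' @export
sample_fb_composition <- function(target_nsv, n_fb, mix_id = "mix",
                                  strains = c("A", "B"),
                                  focal_strain = strains[1L]) {
  if (n_fb < 2L) stop("need at least 2 fruiting bodies")
  if (target_nsv <= 0) {
    p <- rep(50, n_fb)
  } else if (target_nsv >= 100) {
    p <- 100 * rbinom(n_fb, 1L, 0.5)
    if (length(unique(p)) == 1L) p[1L] <- 100 - p[1L]
  } else {
    a <- ((100 / target_nsv)^2 - 1) / 2
    p <- 100 * rbeta(n_fb, a, a)
  }
  mix_composition(mix_id, strains, focal_strain, p)
}

#' Simulate self-mix compositions
#'
#' One self-mix per strain: per-fruiting-body percentages from a tight
#' Beta(`noise_alpha`, `noise_alpha`) around 50, modelling labeling and
#' counting noise. The resulting nsv values are small, right-skewed and
#' gamma-like, which is what [fit_gamma_null()] consumes.
#'
#' @param strains Strain identifiers.
#' @param noise_alpha Beta concentration (default 400: percent s.d. about
#'   1.8, nsv about 3.5).
#' @param n_fb_range Inclusive range of fruiting bodies per mix (default
#'   6-12).
#' @param seed Optional integer seed.
#' @return List of self [mix_composition()] objects.
#' @export
simulate_self_mixes <- function(strains, noise_alpha = 400,
                                n_fb_range = c(6L, 12L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(strains, function(s) {
    n_fb <- sample(n_fb_range[1L]:n_fb_range[2L], 1L)
    p <- 100 * rbeta(n_fb, noise_alpha, noise_alpha)
    mix_composition(paste0("self_", s), c(s, s), s, p)
  })
}

#' Simulate binding and migration phenotypes
#'
#' Percent binding decreases linearly with scaled locus distance
#' (`100 - binding_slope * d / max(d)` plus noise, clipped); self pairs bind
#' near 100%. Slug-migration chimeras fall short of the clonal expectation
#' in proportion to the pair's target nsv
#' (`deviation = -migration_slope * nsv` plus noise), across
#' `n_experiments` experiments with shared experiment and strain effects.
#'
#' @param pairs data.frame with `strain_a`, `strain_b`, `locus_dist`,
#'   `target_nsv` (e.g. rows of [nsv_from_locus()]).
#' @param n_binding_reps Replicates per binding pair (default 3).
#' @param binding_slope Percent binding lost at the maximal distance
#'   (default 85).
#' @param binding_noise_sd Binding noise s.d. in percent (default 5).
#' @param migration_base Mean clonal trail length, arbitrary units
#'   (default 30).
#' @param migration_slope Trail-length deficit per nsv unit (default 0.1).
#' @param migration_noise_sd Residual noise s.d. (default 1).
#' @param n_experiments Migration experiments (default 4).
#' @param seed Optional integer seed.
#' @return List of data.frames `binding` (schema of
#'   [read_binding_table()]) and `migration` (schema of
#'   [read_migration_table()]).
#' @export
simulate_phenotypes <- function(pairs, n_binding_reps = 3L,
                                binding_slope = 85, binding_noise_sd = 5,
                                migration_base = 30, migration_slope = 0.1,
                                migration_noise_sd = 1, n_experiments = 4L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dmax <- max(pairs$locus_dist)
  dscale <- if (dmax > 0) pairs$locus_dist / dmax else rep(0, nrow(pairs))
  strains <- sort(unique(c(pairs$strain_a, pairs$strain_b)))
  # binding: hetero pairs plus self controls
  brow <- function(a, b, pct, rep_id) {
    pct <- min(100, max(0, pct))
    total <- runif(1L, 5000, 20000)
    data.frame(strain_a = a, strain_b = b, replicate = rep_id,
               intensity_bound = total * pct / 100,
               intensity_not_bound = total * (1 - pct / 100),
               protein_amount_ug = sample(c(25, 5, 0.5, 0.2), 1L),
               stringsAsFactors = FALSE)
  }
  binding <- list()
  for (i in seq_len(nrow(pairs)))
    for (r in seq_len(n_binding_reps))
      binding[[length(binding) + 1L]] <-
        brow(pairs$strain_a[i], pairs$strain_b[i],
             100 - binding_slope * dscale[i] + rnorm(1L, 0, binding_noise_sd),
             r)
  for (s in strains)
    for (r in seq_len(n_binding_reps))
      binding[[length(binding) + 1L]] <-
        brow(s, s, 100 - abs(rnorm(1L, 0, binding_noise_sd)), r)
  binding <- do.call(rbind, binding)
  # migration: clonal rows + chimera rows per experiment
  strain_eff <- setNames(rnorm(length(strains), 0, 3), strains)
  migration <- list()
  for (e in seq_len(n_experiments)) {
    expt_eff <- rnorm(1L, 0, 2)
    clonal <- setNames(migration_base + strain_eff[strains] + expt_eff +
                         rnorm(length(strains), 0, migration_noise_sd),
                       strains)
    for (s in strains)
      migration[[length(migration) + 1L]] <- data.frame(
        experiment = paste0("exp", e), strain_a = s,
        strain_b = NA_character_, trail_length = unname(clonal[s]),
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pairs))) {
      expect <- mean(clonal[c(pairs$strain_a[i], pairs$strain_b[i])])
      migration[[length(migration) + 1L]] <- data.frame(
        experiment = paste0("exp", e), strain_a = pairs$strain_a[i],
        strain_b = pairs$strain_b[i],
        trail_length = expect - migration_slope * pairs$target_nsv[i] +
          rnorm(1L, 0, migration_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(binding = binding, migration = do.call(rbind, migration))
}

#' Simulate a complete synthetic dataset bundle
#'
#' Chains the whole generator: strain tree and SNPs, planted two-gene locus,
#' background genes, pairwise and self mixes, and phenotypes for four
#' strains spanning the segregation range. With `couple_nsv = FALSE` the
#' target nsv values are drawn independently of the locus (the null
#' control). Fully determined by `seed`.
#'
#' @param seed Integer seed.
#' @param n_strains,n_clusters,n_sites Passed to [simulate_strains()].
#' @param n_background_genes,n_codons_background Background gene set.
#' @param n_codons_locus,rate_multiplier,n_term_fraction,split_divergence
#'   Passed to [simulate_locus()].
#' @param base_rate Background substitution rate.
#' @param couple_nsv Couple targets to locus distance (default `TRUE`).
#' @param nsv_max,d_half,noise_sd Passed to [nsv_from_locus()].
#' @param n_fb_range Fruiting bodies per pairwise mix (default 6-12).
#' @param self_noise_alpha Self-mix Beta concentration (default 400).
#' @param dir Optional directory: when given, the bundle is also written to
#'   disk via [write_bundle()].
#' @return List: `tree`, `snps`, `clusters`, `locus` (planted genes +
#'   groups), `genes` (background + planted), `pair_targets`, `mixes`,
#'   `self_mixes`, `phenotypes`, `truth`.
#' @export
simulate_bundle <- function(seed, n_strains = 20L, n_clusters = 4L,
                            n_sites = 3000L, n_background_genes = 500L,
                            n_codons_background = 100L,
                            n_codons_locus = 300L, rate_multiplier = 20,
                            n_term_fraction = 0.25, split_divergence = 0.6,
                            base_rate = 0.003, couple_nsv = TRUE,
                            nsv_max = 95, d_half = NULL, noise_sd = 7,
                            n_fb_range = c(6L, 12L), self_noise_alpha = 400,
                            dir = NULL) {
  set.seed(seed)
  sim <- simulate_strains(n_strains, n_clusters, n_sites)
  locus <- simulate_locus(sim$tree, rate_multiplier = rate_multiplier,
                          n_term_fraction = n_term_fraction,
                          n_codons = n_codons_locus, base_rate = base_rate,
                          split_divergence = split_divergence)
  background <- simulate_background_genes(sim$tree, n_background_genes,
                                          n_codons_background, base_rate)
  # genomic positions: planted genes tightly linked on chr3, background
  # genes scattered
  loc_len <- 3L * n_codons_locus
  locus$genes[[1L]]$position <- list(chromosome = "chr3", start = 2600000L,
                                     end = 2600000L + loc_len - 1L)
  locus$genes[[2L]]$position <- list(chromosome = "chr3",
                                     start = 2600000L + loc_len + 523L,
                                     end = 2600000L + 2L * loc_len + 522L)
  for (i in seq_along(background)) {
    glen <- 3L * n_codons_background
    start <- sample.int(8000000L, 1L)
    background[[i]]$position <- list(
      chromosome = paste0("chr", sample.int(6L, 1L)),
      start = start, end = start + glen - 1L)
  }
  locus_concat <- concat_alignments(locus$genes, gene_id = "tgr_locus")
  locus_dist <- protein_distance(locus_concat)
  if (couple_nsv) {
    pair_targets <- nsv_from_locus(locus_dist, nsv_max = nsv_max,
                                   d_half = d_half, noise_sd = noise_sd)
  } else {
    pair_targets <- pair_table(locus_dist = unclass(locus_dist))
    names(pair_targets)[1:2] <- c("strain_a", "strain_b")
    pair_targets$target_nsv <- nsv_targets_null(nrow(pair_targets))
  }
  mixes <- lapply(seq_len(nrow(pair_targets)), function(i) {
    n_fb <- sample(n_fb_range[1L]:n_fb_range[2L], 1L)
    sample_fb_composition(pair_targets$target_nsv[i], n_fb,
                          mix_id = sprintf("mix%03d", i),
                          strains = c(pair_targets$strain_a[i],
                                      pair_targets$strain_b[i]))
  })
  self_mixes <- simulate_self_mixes(sim$tree$tip.label,
                                    noise_alpha = self_noise_alpha,
                                    n_fb_range = n_fb_range)
  # phenotypes for four strains spanning the segregation range
  mean_target <- tapply(
    c(pair_targets$target_nsv, pair_targets$target_nsv),
    c(pair_targets$strain_a, pair_targets$strain_b), mean)
  ord <- names(sort(mean_target))
  pick <- unique(ord[round(seq(1L, length(ord), length.out = 4L))])
  ppairs <- pair_targets[pair_targets$strain_a %in% pick &
                           pair_targets$strain_b %in% pick, , drop = FALSE]
  phenotypes <- simulate_phenotypes(ppairs)
  truth <- list(seed = seed, tree_newick = write_newick(sim$tree),
                clusters = as.list(sim$clusters),
                planted_genes = names(locus$genes),
                haplotype_groups = as.list(locus$groups),
                couple_nsv = couple_nsv,
                coupling = list(nsv_max = nsv_max, d_half = d_half,
                                noise_sd = noise_sd,
                                rate_multiplier = rate_multiplier,
                                split_divergence = split_divergence),
                phenotype_strains = pick)
  bundle <- list(tree = sim$tree, snps = sim$snps, clusters = sim$clusters,
                 locus = locus, genes = c(background, unname(locus$genes)),
                 locus_dist = locus_dist, pair_targets = pair_targets,
                 mixes = mixes, self_mixes = self_mixes,
                 phenotypes = phenotypes, truth = truth)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a simulated bundle to a directory
#'
#' Writes `strains.nwk`, `snps.tsv`, `genes/<id>.prot.fasta` and
#' `genes/<id>.codon.fasta`, `gene_positions.tsv`, `mixes.tsv`,
#' `self_mixes.tsv`, `binding.tsv`, `migration.tsv` and `truth.json`.
#'
#' @param bundle Result of [simulate_bundle()].
#' @param dir Output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  write_newick(bundle$tree, file.path(dir, "strains.nwk"))
  write_snp_table(bundle$snps, file.path(dir, "snps.tsv"))
  for (g in bundle$genes)
    write_alignment_fasta(
      g, file.path(dir, "genes", paste0(g$gene_id, ".prot.fasta")),
      codon_path = file.path(dir, "genes", paste0(g$gene_id, ".codon.fasta")))
  pos <- do.call(rbind, lapply(bundle$genes, function(g) {
    p <- g$position
    data.frame(gene_id = g$gene_id,
               chromosome = if (is.null(p)) NA_character_ else p$chromosome,
               start = if (is.null(p)) NA_integer_ else p$start,
               end = if (is.null(p)) NA_integer_ else p$end,
               stringsAsFactors = FALSE)
  }))
  write_tsv(pos, file.path(dir, "gene_positions.tsv"))
  write_mix_table(bundle$mixes, file.path(dir, "mixes.tsv"))
  write_mix_table(bundle$self_mixes, file.path(dir, "self_mixes.tsv"))
  write_tsv(bundle$phenotypes$binding, file.path(dir, "binding.tsv"))
  write_tsv(bundle$phenotypes$migration, file.path(dir, "migration.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
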