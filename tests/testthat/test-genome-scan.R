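test_that("IBS distance equals site-by-site hand counts", {
  g <- rbind(s1 = c("A", "A", "T", "G"),
             s2 = c("A", "A", "T", "G"),
             s3 = c("T", "A", "G", "G"))
  d <- ibs_distance(snp_matrix(g))
  expect_equal(unclass(d)["s1", "s2"], 0)
  expect_equal(unclass(d)["s1", "s3"], 0.5)

  g2 <- rbind(a = c("A", "C"), b = c("T", "G"))
  expect_equal(unclass(ibs_distance(snp_matrix(g2)))["a", "b"], 1)

  # random matrix with missing data against a brute-force per-site count
  set.seed(17)
  g3 <- matrix(sample(c("A", "T", "C", NA), 30, replace = TRUE),
               nrow = 3, dimnames = list(paste0("s", 1:3), NULL))
  d3 <- unclass(ibs_distance(snp_matrix(g3)))
  for (i in 1:2) for (j in (i + 1):3) {
    same <- 0L; tot <- 0L
    for (s in 1:10) {
      if (is.na(g3[i, s]) || is.na(g3[j, s])) next
      tot <- tot + 1L
      if (g3[i, s] == g3[j, s]) same <- same + 1L
    }
    expect_equal(d3[i, j], 1 - same / tot)
  }
})

test_that("LD pruning drops duplicate columns and respects the window", {
  g <- rbind(s1 = c("A", "A", "C"),
             s2 = c("T", "T", "C"),
             s3 = c("A", "A", "A"),
             s4 = c("T", "T", "A"))
  snp <- snp_matrix(g, chromosome = rep("chr1", 3), position = c(10, 20, 30))
  pruned <- ld_prune(snp, r2_threshold = 1.0)
  expect_equal(ncol(pruned$genotypes), 2L)  # col2 duplicates col1
  expect_equal(pruned$position, c(10, 30))

  # unattainable threshold removes nothing
  expect_equal(ncol(ld_prune(snp, r2_threshold = 1.5)$genotypes), 3L)

  # random matrix: retained set equals exhaustive duplicate detection
  set.seed(19)
  g <- matrix(sample(c("A", "G"), 8 * 50, replace = TRUE), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  snp <- snp_matrix(g, chromosome = rep("chr1", 50), position = 1:50)
  pruned <- ld_prune(snp, r2_threshold = 1.0)
  # oracle: greedy scan dropping perfectly correlated duplicates
  num <- apply(g, 2, function(col) as.numeric(col == col[1]))
  kept <- integer(0)
  for (j in 1:50) {
    dup <- FALSE
    for (k in kept) {
      r2 <- suppressWarnings(cor(num[, j], num[, k]))^2
      if (!is.na(r2) && r2 >= 1 - 1e-12) dup <- TRUE
    }
    if (!dup) kept <- c(kept, j)
  }
  expect_equal(pruned$site_ids, snp$site_ids[kept])
})

test_that("complete linkage and cophenetic distances match a naive oracle", {
  d2 <- distance_matrix(matrix(c(0, .4, .4, 0), 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  hc <- complete_linkage(d2)
  expect_equal(hc$height, 0.4)

  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- complete_linkage(distance_matrix(m))
  expect_equal(sort(hc3$height), c(1, 3))  # (A,B)@1 then +C@3
  cd <- unclass(cophenetic_distances(hc3))
  expect_equal(cd["A", "B"], 1)
  expect_equal(cd["A", "C"], 3)
  expect_equal(cd["B", "C"], 3)

  set.seed(23)
  for (i in 1:5) {
    v <- matrix(runif(100, 0.1, 2), 10)
    v <- (v + t(v)) / 2; diag(v) <- 0
    dimnames(v) <- list(paste0("t", 1:10), paste0("t", 1:10))
    d <- distance_matrix(v)
    hc <- complete_linkage(d)
    oracle <- naive_complete_linkage(v)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-12)
    cd <- unclass(cophenetic_distances(hc))
    expect_equal(cd[rownames(v), colnames(v)], oracle$cophenetic,
                 tolerance = 1e-12)
    # ultrametric triple inequality
    for (a in 1:8) for (b in (a + 1):9) for (cc in (b + 1):10)
      expect_lte(cd[a, cc], max(cd[a, b], cd[b, cc]) + 1e-12)
  }

  # clustering an already-ultrametric matrix returns it exactly
  base <- naive_complete_linkage(matrix(runif(25, .1, 1), 5) |>
                                   (\(x) {d <- (x + t(x)) / 2; diag(d) <- 0
                                   dimnames(d) <- list(letters[1:5],
                                                       letters[1:5]); d})())
  um <- base$cophenetic
  back <- unclass(cophenetic_distances(complete_linkage(
    distance_matrix(um))))
  expect_equal(back[rownames(um), colnames(um)], um, tolerance = 1e-12)

  expect_error(complete_linkage(
    distance_matrix(matrix(c(0, NA, NA, 0), 2,
                           dimnames = list(1:2, 1:2)))), "NA")
})

test_that("protein p-distance honours both gap modes", {
  aln <- gene_alignment("g", c("x", "y"), c("ACDE", "ACDF"))
  expect_equal(unclass(protein_distance(aln))["x", "y"], 0.25)
  aln2 <- gene_alignment("g", c("x", "y", "z"),
                         c("AC-EF", "ACDEF", "GC-EF"))
  # complete deletion drops column 3: x vs z differ at 1 of 4
  dc <- unclass(protein_distance(aln2, "complete-deletion"))
  expect_equal(dc["x", "z"], 0.25)
  expect_equal(dc["x", "y"], 0)
  # pairwise deletion compares x,y over their 4 shared ungapped columns
  dp <- unclass(protein_distance(aln2, "pairwise-deletion"))
  expect_equal(dp["x", "y"], 0)
  expect_equal(dp["y", "z"], 0.25)  # 1 of 4 shared ungapped columns
  ident <- gene_alignment("g", c("x", "y"), c("MMMM", "MMMM"))
  expect_equal(unclass(protein_distance(ident))["x", "y"], 0)
})

test_that("allele counting is an exact string-set size", {
  rows <- rep("MKLV", 20)
  expect_equal(count_protein_alleles(gene_alignment("g", paste0("s", 1:20),
                                                    rows)), 1L)
  rows <- vapply(1:20, function(i) paste0("MKL", LETTERS[i]), "")
  expect_equal(count_protein_alleles(gene_alignment("g", paste0("s", 1:20),
                                                    rows)), 20L)
  set.seed(29)
  rows <- sample(c("MKLV", "MRLV", "MKLI"), 20, replace = TRUE)
  expect_equal(count_protein_alleles(gene_alignment("g", paste0("s", 1:20),
                                                    rows)),
               length(unique(rows)))
})

test_that("synonymous/non-synonymous tallies follow the genetic code", {
  # TTA vs TTG: both Leu, one silent third-position site
  aln <- gene_alignment("g", c("a", "b"), c("L", "L"),
                        codon_rows = c("TTA", "TTG"))
  expect_equal(count_syn_nonsyn(aln)[c("n_syn", "n_nonsyn", "n_total")],
               list(n_syn = 1L, n_nonsyn = 0L, n_total = 1L))
  # TTA vs TCA: Leu -> Ser, replacement
  aln <- gene_alignment("g", c("a", "b"), c("L", "S"),
                        codon_rows = c("TTA", "TCA"))
  expect_equal(count_syn_nonsyn(aln)[c("n_syn", "n_nonsyn", "n_total")],
               list(n_syn = 0L, n_nonsyn = 1L, n_total = 1L))
  # toy 4-codon alignment verified by hand translation:
  # codon2 AAA->AGA (K->R, nonsyn), codon3 TTA->TTG (syn),
  # codon4 GTT->ATT (V->I, nonsyn)
  sn <- count_syn_nonsyn(toy_alignment())
  expect_equal(sn[c("n_syn", "n_nonsyn", "n_total")],
               list(n_syn = 1L, n_nonsyn = 2L, n_total = 3L))
  # gapped codons are skipped and counted
  aln <- gene_alignment("g", c("a", "b", "c"), c("LX", "LX", "LX"),
                        codon_rows = c("TTA---", "TTG---", "TTANNN"))
  sn <- count_syn_nonsyn(aln)
  expect_equal(sn$n_syn, 1L)
  expect_gte(sn$n_skipped_codons, 3L)
  bad <- gene_alignment("g", c("a", "b"), c("L", "L"),
                        codon_rows = NULL)
  expect_error(count_syn_nonsyn(bad), "codon rows")
})

test_that("Sidak alpha reproduces the published thresholds and bounds", {
  expect_equal(signif(sidak_alpha(0.05, 6532), 3), 7.85e-6)
  expect_equal(signif(sidak_alpha(0.05, 15), 2), 0.0034)
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  expect_error(sidak_alpha(0.05, 0), "n_tests")
  expect_error(sidak_alpha(1.2, 5), "fwer")
  # Bonferroni bound and monotonicity
  prev <- Inf
  for (m in c(1, 2, 5, 10, 100, 10000)) {
    a <- sidak_alpha(0.05, m)
    expect_gte(a, 0.05 / m)
    expect_lte(a, 0.05 + 1e-12)
    expect_lt(a, prev + 1e-15)
    prev <- a
  }
})

test_that("scan correlations match brute-force Pearson over pairs", {
  set.seed(37)
  ids <- paste0("s", 1:6)
  nsv <- matrix(runif(36, 0, 100), 6, dimnames = list(ids, ids))
  nsv[lower.tri(nsv)] <- t(nsv)[lower.tri(nsv)]
  diag(nsv) <- NA
  seg <- segregation_matrix(nsv)
  # random genes: compare every scan r to the explicit-pair oracle
  genes <- lapply(1:5, function(k) {
    rows <- vapply(1:6, function(i)
      paste(sample(c("A", "R", "N", "D"), 40, replace = TRUE), collapse = ""),
      "")
    gene_alignment(paste0("g", k), ids, rows)
  })
  sc <- suppressWarnings(greenbeard_scan(genes, seg))
  for (k in seq_len(nrow(sc))) {
    g <- genes[[match(sc$gene_id[k], vapply(genes, `[[`, "", "gene_id"))]]
    oracle_r <- brute_pair_pearson(unclass(protein_distance(g)), nsv, ids)
    expect_equal(sc$r[k], oracle_r, tolerance = 1e-12)
  }
  expect_equal(attr(sc, "sidak_alpha"), sidak_alpha(0.05, nrow(sc)))
  # constant-distance gene: NA with warning, excluded from multiplicity
  const <- gene_alignment("const", ids, rep("MMMM", 6))
  expect_warning(sc2 <- greenbeard_scan(c(genes, list(const)), seg),
                 "zero variance")
  expect_true(is.na(sc2$r[sc2$gene_id == "const"]))
  expect_equal(attr(sc2, "n_tested"), 5L)
})

test_that("an exact affine relation between distance and nsv gives r = 1", {
  ids <- paste0("s", 1:5)
  # nsv proportional to hamming distances of constructed sequences
  rows <- c("AAAA", "AAAR", "AARR", "ARRR", "RRRR")
  g <- gene_alignment("gene", ids, rows)
  D <- unclass(protein_distance(g))
  nsv <- 20 + 60 * D
  diag(nsv) <- NA
  seg <- segregation_matrix(nsv)
  sc <- greenbeard_scan(list(g), seg)
  expect_equal(sc$r[1], 1, tolerance = 1e-12)
})

test_that("candidate co-location equals brute-force interval merging", {
  mk_rec <- function(id, chr, start, end, pass = TRUE)
    data.frame(gene_id = id, chromosome = chr, start = start, end = end,
               passes_threshold = pass, stringsAsFactors = FALSE)
  recs <- rbind(mk_rec("g1", "chr1", 1000, 2000),
                mk_rec("g2", "chr1", 7000, 8000),
                mk_rec("g3", "chr2", 1000, 2000))
  cl <- colocate_candidates(recs, window_bp = 50000)
  expect_equal(cl$cluster[cl$gene_id == "g1"], cl$cluster[cl$gene_id == "g2"])
  expect_false(cl$cluster[cl$gene_id == "g3"] ==
                 cl$cluster[cl$gene_id == "g1"])
  cl2 <- colocate_candidates(recs, window_bp = 1000)
  expect_false(cl2$cluster[cl2$gene_id == "g1"] ==
                 cl2$cluster[cl2$gene_id == "g2"])

  set.seed(41)
  for (i in 1:10) {
    n <- 12L
    starts <- sort(sample.int(1e6, n))
    recs <- do.call(rbind, lapply(seq_len(n), function(k)
      mk_rec(paste0("g", k), "chr1", starts[k], starts[k] + 500)))
    w <- 20000
    cl <- colocate_candidates(recs, window_bp = w)
    cl <- cl[order(cl$start), ]
    # oracle: new cluster whenever the gap to the previous interval end
    # exceeds the window
    expected <- cumsum(c(TRUE, diff(starts) - 500 > w))
    expect_equal(as.integer(factor(cl$cluster)), as.integer(expected))
  }
  # records without positions stay unclustered
  recs <- rbind(mk_rec("g1", "chr1", 1000, 2000),
                mk_rec("g2", NA, NA, NA))
  cl <- colocate_candidates(recs)
  expect_true(is.na(cl$cluster[cl$gene_id == "g2"]))
})
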