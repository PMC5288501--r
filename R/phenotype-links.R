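# Phenotype-linkage statistics: percent binding from pull-down intensities,
# slug-migration deviation from the clonal expectation, and their
# correlations with segregation.

#' Percent protein binding
#'
#' `100 * bound / (bound + not_bound)` per measurement. The input lane, when
#' recorded, is kept for auditing but does not enter the normalization.
#'
#' @param bound_intensity,not_bound_intensity Non-negative band intensities
#'   (vectorized).
#' @return Percent bound in \[0, 100\]; `NA` with a warning where both
#'   intensities are zero.
#' @export
percent_binding <- function(bound_intensity, not_bound_intensity) {
  if (any(bound_intensity < 0, na.rm = TRUE) ||
      any(not_bound_intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- bound_intensity + not_bound_intensity
  zero <- !is.na(tot) & tot == 0
  if (any(zero))
    warning(sum(zero), " measurement(s) with both intensities zero (NA)")
  out <- 100 * bound_intensity / tot
  out[zero] <- NA_real_
  out
}

#' Mean percent binding per strain pair
#'
#' Averages per-replicate percent binding (from [percent_binding()]) per
#' unordered strain pair.
#'
#' @param binding data.frame as returned by [read_binding_table()].
#' @return data.frame `strain_a`, `strain_b`, `percent_bound`,
#'   `n_replicates`.
#' @export
binding_means <- function(binding) {
  pct <- percent_binding(binding$intensity_bound, binding$intensity_not_bound)
  key <- ifelse(binding$strain_a <= binding$strain_b,
                paste(binding$strain_a, binding$strain_b, sep = "\r"),
                paste(binding$strain_b, binding$strain_a, sep = "\r"))
  agg <- tapply(pct, key, mean, na.rm = TRUE)
  n <- tapply(!is.na(pct), key, sum)
  ab <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  data.frame(strain_a = ab[, 1L], strain_b = ab[, 2L],
             percent_bound = as.numeric(agg), n_replicates = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Correlation of percent binding with segregation
#'
#' Pearson correlation (with two-sided t-based p) between mean percent
#' binding and nsv over hetero strain pairs only; self-pairs never enter.
#'
#' @param binding Either a per-pair mean table from [binding_means()] or a
#'   raw replicate table (columns of [read_binding_table()]).
#' @param segmat A [segregation_matrix()].
#' @return List: `r`, `p_value`, `n_pairs`.
#' @export
binding_segregation_correlation <- function(binding, segmat) {
  if (!"percent_bound" %in% names(binding)) binding <- binding_means(binding)
  hetero <- binding$strain_a != binding$strain_b
  binding <- binding[hetero, , drop = FALSE]
  nsv <- unclass(segmat)
  ok <- binding$strain_a %in% rownames(nsv) &
    binding$strain_b %in% rownames(nsv)
  binding <- binding[ok, , drop = FALSE]
  binding$nsv <- nsv[cbind(binding$strain_a, binding$strain_b)]
  binding <- binding[!is.na(binding$nsv) & !is.na(binding$percent_bound), ,
                     drop = FALSE]
  if (nrow(binding) < 3L)
    stop("need at least 3 hetero pairs with both binding and nsv")
  if (var(binding$percent_bound) == 0 || var(binding$nsv) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_pairs = nrow(binding)))
  ct <- cor.test(binding$percent_bound, binding$nsv, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = nrow(binding))
}

#' Slug-migration deviation from the clonal expectation
#'
#' Within each experiment, the expected trail length of a pairwise mix is
#' the mean of the two clones' trail lengths from the same experiment; the
#' deviation is the chimera's trail length minus that expectation.
#' Deviations are then averaged (mean and standard error) over experiments
#' per pair. Pair-experiments missing a clonal row are skipped with a
#' warning.
#'
#' @param migration data.frame as returned by [read_migration_table()]
#'   (clonal rows have `strain_b` `NA`).
#' @return data.frame `strain_a`, `strain_b`, `mean_deviation`,
#'   `se_deviation`, `n_experiments`.
#' @export
migration_deviation <- function(migration) {
  clonal <- migration[is.na(migration$strain_b), , drop = FALSE]
  chim <- migration[!is.na(migration$strain_b), , drop = FALSE]
  clonal_lookup <- function(expt, strain) {
    v <- clonal$trail_length[clonal$experiment == expt &
                               clonal$strain_a == strain]
    if (length(v)) mean(v) else NA_real_
  }
  chim$deviation <- NA_real_
  n_skipped <- 0L
  for (i in seq_len(nrow(chim))) {
    ca <- clonal_lookup(chim$experiment[i], chim$strain_a[i])
    cb <- clonal_lookup(chim$experiment[i], chim$strain_b[i])
    if (is.na(ca) || is.na(cb)) { n_skipped <- n_skipped + 1L; next }
    chim$deviation[i] <- chim$trail_length[i] - mean(c(ca, cb))
  }
  if (n_skipped > 0L)
    warning(n_skipped, " chimera row(s) missing a clonal control in the ",
            "same experiment; skipped")
  chim <- chim[!is.na(chim$deviation), , drop = FALSE]
  key <- ifelse(chim$strain_a <= chim$strain_b,
                paste(chim$strain_a, chim$strain_b, sep = "\r"),
                paste(chim$strain_b, chim$strain_a, sep = "\r"))
  mu <- tapply(chim$deviation, key, mean)
  n <- tapply(chim$deviation, key, length)
  se <- tapply(chim$deviation, key, sd) / sqrt(n)
  ab <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  data.frame(strain_a = ab[, 1L], strain_b = ab[, 2L],
             mean_deviation = as.numeric(mu), se_deviation = as.numeric(se),
             n_experiments = as.integer(n), stringsAsFactors = FALSE)
}

#' Correlation of migration deviation with segregation
#'
#' Pearson correlation (two-sided t-based p) between per-pair mean migration
#' deviation and nsv; self-pairs excluded.
#'
#' @param deviation data.frame from [migration_deviation()].
#' @param segmat A [segregation_matrix()].
#' @return List: `r`, `p_value`, `n_pairs` (`r = NA` under zero variance).
#' @export
migration_segregation_correlation <- function(deviation, segmat) {
  nsv <- unclass(segmat)
  dev <- deviation[deviation$strain_a != deviation$strain_b, , drop = FALSE]
  ok <- dev$strain_a %in% rownames(nsv) & dev$strain_b %in% rownames(nsv)
  dev <- dev[ok, , drop = FALSE]
  dev$nsv <- nsv[cbind(dev$strain_a, dev$strain_b)]
  dev <- dev[!is.na(dev$nsv) & !is.na(dev$mean_deviation), , drop = FALSE]
  if (nrow(dev) < 3L) stop("need at least 3 pairs with both values")
  if (var(dev$mean_deviation) == 0 || var(dev$nsv) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_pairs = nrow(dev)))
  ct <- cor.test(dev$mean_deviation, dev$nsv, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(dev))
}
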