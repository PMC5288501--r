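# Segregation statistics: the normalized segregation value (nsv), the
# self-mix gamma null and classification threshold, matrix assembly,
# bootstrap mix comparisons, and non-transitive hierarchy detection.

#' Normalized segregation value (nsv)
#'
#' Segregation of a strain across the fruiting bodies of one mix is the
#' standard deviation of its per-fruiting-body percentages. Because the
#' overall representation m of the strain bounds that standard deviation by
#' sqrt(m (100 - m)), the raw value is divided by this maximum, giving a
#' statistic interpretable as percent segregation:
#' `nsv = 100 * s / sqrt(m (100 - m))` with `s` the population (divide-by-n)
#' standard deviation and `m` the mean of `fb_percent`. The population form
#' makes nsv = 100 exactly attainable by two-point 0/100 compositions.
#'
#' @param fb_percent Numeric vector (length >= 2) of per-fruiting-body
#'   percentages in \[0, 100\].
#' @return nsv in \[0, 100\]. When the mean is exactly 0 or 100 the standard
#'   deviation is necessarily 0 and 0 is returned.
#' @examples
#' compute_nsv(c(0, 0, 100, 100))  # 100
#' compute_nsv(c(20, 40, 60, 80))  # 44.72
#' @export
compute_nsv <- function(fb_percent) {
  if (length(fb_percent) < 2L)
    stop("nsv needs at least 2 fruiting bodies")
  if (any(!is.finite(fb_percent) | fb_percent < 0 | fb_percent > 100))
    stop("fb_percent values must lie in [0,100]")
  m <- mean(fb_percent)
  if (m == 0 || m == 100) return(0)
  s <- sqrt(mean((fb_percent - m)^2))
  # s <= sqrt(m (100 - m)) analytically; clamp floating-point overshoot
  min(100, 100 * s / sqrt(m * (100 - m)))
}

#' Fit the self-mix gamma null
#'
#' Self-mixes (clones mixed with themselves) measure the technical noise of
#' the segregation assay. Their nsv values are fitted with a gamma
#' distribution and the classification threshold is set at a high quantile of
#' the fit (default the 99th percentile).
#'
#' @param self_nsv Numeric vector (length >= 5) of self-mix nsv values;
#'   zeros are replaced by `zero_floor` before fitting (gamma support is
#'   positive) and the replacement count is messaged.
#' @param quantile_level Quantile defining the threshold (default 0.99).
#' @param method `"mle"` (maximum likelihood, via \pkg{MASS}) or
#'   `"lmoments"` (L-moment matching, Hosking's approximation).
#' @param zero_floor Replacement value for exact zeros (default 0.01).
#' @return A `gamma_null` object: `shape`, `rate`, `quantile_level`,
#'   `threshold`, `n_fitted`, `method`, `converged`.
#' @export
fit_gamma_null <- function(self_nsv, quantile_level = 0.99,
                           method = c("mle", "lmoments"), zero_floor = 0.01) {
  method <- match.arg(method)
  x <- as.numeric(self_nsv)
  if (length(x) < 5L) stop("gamma null needs at least 5 self-mix values")
  if (any(!is.finite(x) | x < 0)) stop("self-mix nsv must be finite and >= 0")
  nz <- sum(x == 0)
  if (nz > 0) {
    message(nz, " zero nsv value(s) floored at ", zero_floor)
    x[x == 0] <- zero_floor
  }
  if (length(unique(x)) == 1L)
    stop("degenerate likelihood: all self-mix nsv values identical (",
         x[1L], ")")
  if (method == "mle") {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(x, "gamma")),
      error = function(e) stop("gamma MLE did not converge: ",
                               conditionMessage(e)))
    shape <- unname(fit$estimate["shape"])
    rate <- unname(fit$estimate["rate"])
  } else {
    lm12 <- sample_lmoments(x)
    shape <- gamma_shape_from_lmoments(lm12[1L], lm12[2L])
    rate <- shape / lm12[1L]
  }
  structure(
    list(shape = shape, rate = rate, quantile_level = quantile_level,
         threshold = qgamma(quantile_level, shape = shape, rate = rate),
         n_fitted = length(x), method = method, converged = TRUE),
    class = "gamma_null")
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf(paste0("<gamma_null> shape=%.3f rate=%.3f; %g%% quantile ",
                     "threshold=%.2f (n=%d, %s)\n"),
              x$shape, x$rate, 100 * x$quantile_level, x$threshold,
              x$n_fitted, x$method))
  invisible(x)
}

# unbiased sample L-moments l1, l2 (Hosking 1990)
sample_lmoments <- function(x) {
  x <- sort(x)
  n <- length(x)
  b0 <- mean(x)
  b1 <- sum((seq_len(n) - 1) / (n - 1) * x) / n
  c(l1 = b0, l2 = 2 * b1 - b0)
}

# Hosking's rational approximation for the gamma shape from t = l2/l1
gamma_shape_from_lmoments <- function(l1, l2) {
  t <- l2 / l1
  if (t <= 0 || t >= 1) stop("L-moment ratio outside (0,1)")
  if (t < 0.5) {
    z <- pi * t^2
    (1 - 0.3080 * z) / (z - 0.05812 * z^2 + 0.01765 * z^3)
  } else {
    z <- 1 - t
    (0.7213 * z - 0.5947 * z^2) / (1 - 2.1817 * z + 1.2113 * z^2)
  }
}

#' Classify a mix as segregating or not
#'
#' A mix segregates when its nsv reaches the null threshold; the boundary
#' value itself counts as segregating (threshold 18 with nsv < 18 is
#' non-segregation, nsv >= 18 segregation).
#'
#' @param nsv Numeric vector of nsv values.
#' @param null A `gamma_null` from [fit_gamma_null()], or a bare numeric
#'   threshold.
#' @return Character vector, `"segregating"` or `"non-segregating"`.
#' @export
classify_mix <- function(nsv, null) {
  threshold <- if (inherits(null, "gamma_null")) null$threshold else
    as.numeric(null)
  ifelse(nsv >= threshold, "segregating", "non-segregating")
}

#' Assemble the strain-by-strain segregation matrix
#'
#' Computes nsv per mix and fills a symmetric matrix over all strains seen.
#' Self-mix nsv is kept in the `self_values` attribute, never on the
#' diagonal. Duplicate measurements of the same unordered pair (or strain,
#' for self-mixes) are averaged with a warning; unmeasured pairs are `NA`.
#' Three-strain mixes do not define a pairwise entry and are skipped with a
#' message (use [compute_nsv()] on their focal percentages directly).
#'
#' @param mixes List of [mix_composition()] objects.
#' @return A [segregation_matrix()].
#' @export
build_segregation_matrix <- function(mixes) {
  strains <- sort(unique(unlist(lapply(mixes, `[[`, "strains"))))
  vals <- matrix(NA_real_, length(strains), length(strains),
                 dimnames = list(strains, strains))
  self <- setNames(rep(NA_real_, length(strains)), strains)
  pair_acc <- list()
  self_acc <- list()
  n_threeway <- 0L
  for (m in mixes) {
    if (length(unique(m$strains)) > 2L) { n_threeway <- n_threeway + 1L; next }
    v <- compute_nsv(m$fb_percent)
    if (m$is_self_mix) {
      s <- m$strains[1L]
      self_acc[[s]] <- c(self_acc[[s]], v)
    } else {
      key <- paste(sort(unique(m$strains)), collapse = "\r")
      pair_acc[[key]] <- c(pair_acc[[key]], v)
    }
  }
  if (n_threeway > 0L)
    message(n_threeway,
            " three-strain mix(es) skipped in the pairwise matrix")
  dup <- names(pair_acc)[lengths(pair_acc) > 1L]
  if (length(dup))
    warning(length(dup), " strain pair(s) measured more than once; ",
            "values averaged (e.g. ", gsub("\r", "+", dup[1L]), ")")
  for (key in names(pair_acc)) {
    ab <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    vals[ab[1L], ab[2L]] <- vals[ab[2L], ab[1L]] <- mean(pair_acc[[key]])
  }
  if (any(lengths(self_acc) > 1L))
    warning(sum(lengths(self_acc) > 1L),
            " strain(s) with multiple self-mixes; values averaged")
  for (s in names(self_acc)) self[s] <- mean(self_acc[[s]])
  segregation_matrix(vals, self_values = self)
}

#' Self-mix nsv values from a list of mixes
#'
#' Convenience extractor feeding [fit_gamma_null()]: one nsv per self-mix
#' (not averaged per strain).
#'
#' @param mixes List of [mix_composition()] objects.
#' @return Named numeric vector of self-mix nsv.
#' @export
self_mix_nsv <- function(mixes) {
  sel <- Filter(function(m) m$is_self_mix, mixes)
  setNames(vapply(sel, function(m) compute_nsv(m$fb_percent), numeric(1L)),
           vapply(sel, function(m) m$strains[1L], character(1L)))
}

#' Bootstrap comparison of segregation between mixes
#'
#' For each mix, draws `n_boot` subsamples of `subsample_size` fruiting
#' bodies without replacement and computes nsv per subsample; the resampled
#' nsv vectors are then compared between all mix pairs with two-sample
#' t-tests at the Sidak-corrected per-test alpha
#' `1 - (1 - fwer)^(1/m)` for `m` pairwise tests.
#'
#' @param mixes List of at least 2 [mix_composition()] objects, each with at
#'   least `subsample_size` fruiting bodies.
#' @param n_boot Bootstrap replicates per mix (default 1000).
#' @param subsample_size Fruiting bodies per subsample (default 10).
#' @param fwer Familywise error rate (default 0.05).
#' @return data.frame with one row per mix pair: `mix_a`, `mix_b`,
#'   `t_statistic`, `p_value`, `sidak_alpha`, `significant`; the per-mix
#'   bootstrap nsv vectors are attached as attribute `boot_nsv`.
#' @export
bootstrap_compare <- function(mixes, n_boot = 1000L, subsample_size = 10L,
                              fwer = 0.05) {
  if (length(mixes) < 2L) stop("need at least 2 mixes to compare")
  ids <- vapply(mixes, `[[`, character(1L), "mix_id")
  short <- vapply(mixes, function(m) length(m$fb_percent) < subsample_size,
                  logical(1L))
  if (any(short))
    stop("mix '", ids[short][1L], "' has fewer than ", subsample_size,
         " fruiting bodies")
  boot <- lapply(mixes, function(m)
    replicate(n_boot, compute_nsv(sample(m$fb_percent, subsample_size))))
  names(boot) <- ids
  pairs <- utils::combn(seq_along(mixes), 2L)
  m_tests <- ncol(pairs)
  alpha <- sidak_alpha(fwer, m_tests)
  out <- data.frame(
    mix_a = ids[pairs[1L, ]], mix_b = ids[pairs[2L, ]],
    t_statistic = NA_real_, p_value = NA_real_,
    sidak_alpha = alpha, significant = NA, stringsAsFactors = FALSE)
  for (k in seq_len(m_tests)) {
    tt <- t.test(boot[[pairs[1L, k]]], boot[[pairs[2L, k]]])
    out$t_statistic[k] <- unname(tt$statistic)
    out$p_value[k] <- tt$p.value
  }
  out$significant <- out$p_value < alpha
  attr(out, "boot_nsv") <- boot
  attr(out, "n_boot") <- n_boot
  attr(out, "subsample_size") <- subsample_size
  out
}

#' Partner hierarchies and non-transitive swaps
#'
#' Ranks all shared partners by their nsv against each of two reference
#' strains and reports every partner pair whose relative order differs
#' between the references - the signature of non-transitive segregation
#' behaviour. Ties are broken by lexicographic strain id and flagged.
#'
#' @param segmat A [segregation_matrix()].
#' @param reference_a,reference_b The two reference strains.
#' @param partners Optional partner subset (default: all strains other than
#'   the references with non-`NA` values against both).
#' @return List: `reference_a`, `reference_b`, `order_a`, `order_b`
#'   (partners by increasing nsv), `swaps` (data.frame of discordant pairs),
#'   `ties` (logical).
#' @export
hierarchy_and_swaps <- function(segmat, reference_a, reference_b,
                                partners = NULL) {
  strains <- rownames(segmat)
  if (!all(c(reference_a, reference_b) %in% strains))
    stop("reference strain not present in the segregation matrix")
  if (is.null(partners))
    partners <- setdiff(strains, c(reference_a, reference_b))
  va <- unclass(segmat)[reference_a, partners]
  vb <- unclass(segmat)[reference_b, partners]
  keep <- !is.na(va) & !is.na(vb)
  if (!all(keep)) {
    partners <- partners[keep]; va <- va[keep]; vb <- vb[keep]
  }
  ties <- anyDuplicated(va) > 0L || anyDuplicated(vb) > 0L
  order_a <- partners[order(va, partners)]
  order_b <- partners[order(vb, partners)]
  swaps <- list()
  if (length(partners) >= 2L) {
    cmb <- utils::combn(partners, 2L)
    for (k in seq_len(ncol(cmb))) {
      x <- cmb[1L, k]; y <- cmb[2L, k]
      da <- rank_cmp(va[x], va[y], x, y)
      db <- rank_cmp(vb[x], vb[y], x, y)
      if (da != db)
        swaps[[length(swaps) + 1L]] <- data.frame(
          partner_x = x, partner_y = y,
          nsv_a_x = unname(va[x]), nsv_a_y = unname(va[y]),
          nsv_b_x = unname(vb[x]), nsv_b_y = unname(vb[y]),
          stringsAsFactors = FALSE)
    }
  }
  swaps <- if (length(swaps)) do.call(rbind, swaps) else
    data.frame(partner_x = character(), partner_y = character(),
               nsv_a_x = numeric(), nsv_a_y = numeric(),
               nsv_b_x = numeric(), nsv_b_y = numeric())
  list(reference_a = reference_a, reference_b = reference_b,
       order_a = order_a, order_b = order_b, swaps = swaps, ties = ties)
}

# -1/+1 comparison with lexicographic tie-break on ids
rank_cmp <- function(vx, vy, x, y) {
  if (vx < vy) -1L else if (vx > vy) 1L else if (x < y) -1L else 1L
}
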