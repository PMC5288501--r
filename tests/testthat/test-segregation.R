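test_that("nsv matches direct arithmetic on worked compositions", {
  expect_equal(compute_nsv(c(50, 50, 50, 50)), 0)
  expect_equal(compute_nsv(c(0, 0, 100, 100)), 100)   # m=50, s=50, smax=50
  # m=50, s=sqrt(500), smax=50
  expect_equal(compute_nsv(c(20, 40, 60, 80)), 100 * sqrt(500) / 50)
  # m=25, s=smax=sqrt(1875)
  expect_equal(compute_nsv(c(0, 0, 0, 100)), 100)
  expect_equal(compute_nsv(c(0, 0)), 0)     # mean exactly 0
  expect_equal(compute_nsv(c(100, 100)), 0) # mean exactly 100
  expect_error(compute_nsv(50), "at least 2")
  expect_error(compute_nsv(c(10, 101)), "\\[0,100\\]")
})

test_that("nsv is bounded, symmetric under relabeling, and monotone", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1L), 0, 100)
    v <- compute_nsv(p)
    expect_gte(v, 0)
    expect_lte(v, 100)
    # relabeling the strains flips every percentage p -> 100 - p
    expect_equal(compute_nsv(100 - p), v)
  }
  # nsv = 100 only for two-point {0,100} support
  expect_lt(compute_nsv(c(0, 1, 100)), 100)
  # pushing deviations toward the extremes never decreases nsv
  for (i in 1:20) {
    p <- runif(8, 10, 90)
    m <- mean(p)
    stretched <- pmin(100, pmax(0, m + 1.5 * (p - m)))
    expect_gte(compute_nsv(stretched) + 1e-12, compute_nsv(p))
  }
})

test_that("gamma null recovers known parameters and flags degeneracy", {
  set.seed(5)
  x <- rgamma(10000, shape = 4.26, rate = 0.51)
  fit <- fit_gamma_null(x)
  expect_lt(abs(fit$shape - 4.26) / 4.26, 0.05)
  expect_lt(abs(fit$rate - 0.51) / 0.51, 0.05)
  # the 99% quantile of the published fit is about 20.5, not 18
  expect_equal(qgamma(0.99, 4.26, 0.51), 20.5, tolerance = 0.005)
  expect_equal(fit$threshold, qgamma(0.99, fit$shape, fit$rate))

  expect_error(fit_gamma_null(rep(5, 5)), "degenerate")
  expect_error(fit_gamma_null(c(1, 2, 3)), "at least 5")

  # threshold strictly increasing in the quantile level
  f90 <- fit_gamma_null(x, quantile_level = 0.90)
  f99 <- fit_gamma_null(x, quantile_level = 0.99)
  expect_lt(f90$threshold, f99$threshold)

  # L-moment fallback lands near the MLE on clean gamma data
  flm <- fit_gamma_null(x, method = "lmoments")
  expect_lt(abs(flm$shape - 4.26) / 4.26, 0.05)

  expect_message(fit_gamma_null(c(0, x[1:9])), "floored")
})

test_that("classification uses the >= threshold convention", {
  expect_equal(classify_mix(17.99, 18), "non-segregating")
  expect_equal(classify_mix(18, 18), "segregating")
  expect_equal(classify_mix(100, 18), "segregating")
  null <- list(threshold = 18)
  class(null) <- "gamma_null"
  expect_equal(classify_mix(c(10, 30), null),
               c("non-segregating", "segregating"))
})

test_that("segregation matrix assembly matches per-mix recomputation", {
  mk <- function(id, a, b, p) mix_composition(id, c(a, b), a, p)
  mixes <- list(mk("m1", "A", "B", c(0, 0, 100, 100)),
                mk("m2", "A", "C", c(40, 50, 60)),
                mk("m3", "B", "C", c(50, 50, 50)),
                mix_composition("s1", c("A", "A"), "A", c(49, 51)))
  seg <- build_segregation_matrix(mixes)
  expect_equal(unclass(seg)["A", "B"], 100)
  expect_equal(unclass(seg)["B", "A"], 100)
  expect_equal(unclass(seg)["A", "C"], compute_nsv(c(40, 50, 60)))
  expect_equal(unclass(seg)["B", "C"], 0)
  expect_true(is.na(unclass(seg)["A", "A"]))
  expect_equal(attr(seg, "self_values")[["A"]], compute_nsv(c(49, 51)))

  # duplicate pair entries are averaged with a warning
  dup <- list(mk("m1", "A", "B", c(0, 0, 100, 100)),
              mk("m2", "B", "A", c(50, 50, 50, 50)))
  expect_warning(seg2 <- build_segregation_matrix(dup), "averaged")
  expect_equal(unclass(seg2)["A", "B"], 50)

  # larger set: every entry equals compute_nsv applied to its mix
  set.seed(9)
  strains <- paste0("s", 1:8)
  pairs <- combn(strains, 2)
  mixes <- lapply(seq_len(ncol(pairs)), function(k)
    mk(paste0("m", k), pairs[1, k], pairs[2, k], runif(6, 0, 100)))
  seg <- build_segregation_matrix(mixes)
  for (k in seq_len(ncol(pairs)))
    expect_equal(unclass(seg)[pairs[1, k], pairs[2, k]],
                 compute_nsv(mixes[[k]]$fb_percent))
})

test_that("bootstrap comparison separates unlike mixes and not identical ones", {
  set.seed(31)
  # the alpha for 15 tests reproduces the published 0.0034
  expect_equal(signif(sidak_alpha(0.05, 15), 2), 0.0034)

  strong <- sample_fb_composition(80, 40, "hi", c("A", "B"))
  weak <- sample_fb_composition(20, 40, "lo", c("A", "C"))
  res <- bootstrap_compare(list(strong, weak), n_boot = 300)
  expect_true(res$significant[1])
  expect_equal(res$sidak_alpha, sidak_alpha(0.05, 1))

  # a mix against itself: two identical fb vectors give exchangeable
  # bootstrap distributions; significance should be rare
  p <- sample_fb_composition(50, 40, "x", c("A", "B"))$fb_percent
  hits <- 0L
  for (i in 1:30) {
    m1 <- mix_composition("a", c("A", "B"), "A", p)
    m2 <- mix_composition("b", c("A", "C"), "A", p)
    r <- bootstrap_compare(list(m1, m2), n_boot = 200)
    hits <- hits + r$significant[1]
  }
  expect_lte(hits, 5L)

  expect_error(bootstrap_compare(list(strong, weak), subsample_size = 100),
               "fewer than")
})

test_that("non-transitive swaps equal brute-force rank comparison", {
  # orderings mirroring the published example: partners ranked differently
  # against the two reference strains
  strains <- c("ref1", "ref2", "p1", "p2", "p3")
  m <- matrix(NA_real_, 5, 5, dimnames = list(strains, strains))
  m["ref1", c("p1", "p2", "p3")] <- c(20, 40, 60)
  m["ref2", c("p1", "p2", "p3")] <- c(30, 70, 50)  # p2/p3 swap
  m[c("p1", "p2", "p3"), "ref1"] <- m["ref1", c("p1", "p2", "p3")]
  m[c("p1", "p2", "p3"), "ref2"] <- m["ref2", c("p1", "p2", "p3")]
  m[lower.tri(m)][is.na(m[lower.tri(m)])] <- 0
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  seg <- segregation_matrix(m)
  rep <- hierarchy_and_swaps(seg, "ref1", "ref2")
  expect_equal(rep$order_a, c("p1", "p2", "p3"))
  expect_equal(rep$order_b, c("p1", "p3", "p2"))
  expect_equal(nrow(rep$swaps), 1L)
  expect_setequal(unlist(rep$swaps[1, c("partner_x", "partner_y")]),
                  c("p2", "p3"))

  # identical rankings give an empty swap list
  m["ref2", c("p1", "p2", "p3")] <- c(25, 45, 65)
  m[c("p1", "p2", "p3"), "ref2"] <- m["ref2", c("p1", "p2", "p3")]
  expect_equal(nrow(hierarchy_and_swaps(segregation_matrix(m),
                                        "ref1", "ref2")$swaps), 0L)

  # random matrices against exhaustive pair enumeration
  set.seed(13)
  for (rep_i in 1:10) {
    n <- 6L
    ids <- paste0("x", 1:n)
    v <- matrix(runif(n * n, 0, 100), n, dimnames = list(ids, ids))
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    diag(v) <- NA
    seg <- segregation_matrix(v)
    out <- hierarchy_and_swaps(seg, ids[1], ids[2])
    partners <- setdiff(ids, ids[1:2])
    expected <- 0L
    for (a in seq_along(partners)) for (b in seq_along(partners)) {
      if (a >= b) next
      da <- sign(v[ids[1], partners[a]] - v[ids[1], partners[b]])
      db <- sign(v[ids[2], partners[a]] - v[ids[2], partners[b]])
      if (da != db) expected <- expected + 1L
    }
    expect_equal(nrow(out$swaps), expected)
  }
})
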