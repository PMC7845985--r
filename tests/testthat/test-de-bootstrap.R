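# Core bootstrap DE machinery: exact test, resampling, median-p, FDR, fold
# change, status calls and TPM.

test_that("exact test matches hand-derived and degenerate cases", {
  # full enumeration of Binomial(10, 1/2): only k = 0 and k = 10 qualify
  expect_equal(exact_test_two_libraries(0, 10, 1e6, 1e6), 2 / 1024)
  # observed at the mode with symmetric sizes: every outcome is included
  expect_equal(exact_test_two_libraries(5, 5, 1e6, 1e6), 1)
  # no information
  expect_equal(exact_test_two_libraries(0, 0, 1e6, 1e6), 1)
  expect_error(exact_test_two_libraries(-1, 3, 1e6, 1e6), "non-negative")
  expect_error(exact_test_two_libraries(1, 3, 0, 1e6), "positive")
})

test_that("exact test agrees with full-support enumeration", {
  set.seed(7)
  worst <- 0
  for (i in 1:500) {
    t <- sample(0:200, 1)
    x <- sample.int(t + 1, 1) - 1
    pr <- runif(1, 0.05, 0.95)
    worst <- max(worst, abs(papayaDE:::binom_two_sided(x, t, pr) -
                              brute_binom_p(x, t, pr)))
  }
  expect_lt(worst, 1e-12)
})

test_that("exact test agrees with edgeR's exact binomial test at equal sizes", {
  skip_if_not_installed("edgeR")
  set.seed(11)
  x1 <- rpois(300, 40)
  x2 <- rpois(300, 40)
  p_mine <- exact_test_two_libraries(x1, x2, 2e6, 2e6)
  p_edger <- edgeR::binomTest(x1, x2, 2e6, 2e6)
  expect_lt(max(abs(p_mine - p_edger)), 1e-10)
})

test_that("NB exact test converges to the binomial test as dispersion vanishes", {
  set.seed(13)
  xa <- rpois(40, 30)
  xb <- rpois(40, 30)
  p_binom <- exact_test_two_libraries(xa, xb, 1e5, 1.4e5)
  p_nb <- nb_exact_test(xa, xb, 1e5, 1.4e5, dispersion = 1e-8)
  expect_equal(p_nb, p_binom, tolerance = 1e-5)
  # overdispersion makes the same discrepancy less surprising
  expect_gt(nb_exact_test(10, 40, 1e5, 1e5, dispersion = 0.5),
            exact_test_two_libraries(10, 40, 1e5, 1e5))
  expect_equal(nb_exact_test(0, 0, 1e5, 1e5, dispersion = 0.1), 1)
  expect_error(nb_exact_test(1, 2, 1e5, 1e5, dispersion = 0), "dispersion")
  # pluggable strategy reaches the bootstrap
  counts <- matrix(c(5, 50, 40, 6, 7, 45, 35, 8), 2, 4, byrow = TRUE,
                   dimnames = list(c("g1", "g2"),
                                   c("SW", "SD", "TW", "TD")))
  p_strat <- bootstrap_pvalues(counts, c("SW", "SD"), B = 10, seed = 3,
                               test = "nb", dispersion = 0.2)
  expect_true(all(p_strat > 0 & p_strat <= 1))
})

test_that("Poisson resampling is seed-deterministic and fixes zeros", {
  cfg <- small_config()
  counts <- generate_counts(cfg)$counts
  a <- poisson_resample(counts, 5)
  b <- poisson_resample(counts, 5)
  expect_identical(a, b)
  expect_false(identical(a, poisson_resample(counts, 6)))
  zero <- counts == 0
  expect_true(all(a[zero] == 0))
})

test_that("Poisson resampling is mean-unbiased", {
  m <- matrix(100, 1, 2, dimnames = list("g1", c("SW", "SD")))
  draws <- vapply(1:5000, function(s) poisson_resample(m, s)[1, 1],
                  numeric(1))
  # se = sqrt(100/5000); accept 3 standard errors
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / 5000))
})

test_that("bootstrap median p behaves on degenerate configurations", {
  counts <- matrix(c(0, 30, 0, 25, 5, 5, 6, 6), 2, 4, byrow = TRUE,
                   dimnames = list(c("zero", "busy"),
                                   c("SW", "SD", "TW", "TD")))
  # count 0 in both contrast libraries -> p exactly 1 for any B
  p <- bootstrap_pvalues(counts[, c("SW", "TW"), drop = FALSE],
                         c("SW", "TW"), B = 7, seed = 2)
  expect_equal(unname(p["zero"]), 1)
  # B = 1 equals the single replicate's p
  seeds <- papayaDE:::replicate_seeds(9, 1)
  pseudo <- poisson_resample(counts, seeds[1])
  p1 <- bootstrap_pvalues(counts, c("SW", "SD"), B = 1, seed = 9)
  direct <- exact_test_two_libraries(pseudo[, "SW"], pseudo[, "SD"],
                                     sum(pseudo[, "SW"]),
                                     sum(pseudo[, "SD"]))
  expect_equal(unname(p1), direct)
  # determinism and prefix-stable replicate seeds
  expect_identical(bootstrap_pvalues(counts, c("SW", "SD"), B = 5, seed = 4),
                   bootstrap_pvalues(counts, c("SW", "SD"), B = 5, seed = 4))
  expect_identical(papayaDE:::replicate_seeds(4, 5),
                   papayaDE:::replicate_seeds(4, 10)[1:5])
})

test_that("median aggregation uses the central order statistics", {
  # odd B: plain median of replicate p-values
  expect_equal(median(c(0.2, 0.5, 0.9)), 0.5)
  # genes with both-zero counts keep p = 1 through any even/odd B
  counts <- matrix(0, 3, 4,
                   dimnames = list(paste0("g", 1:3),
                                   c("SW", "SD", "TW", "TD")))
  counts["g2", ] <- c(50, 10, 40, 45)
  for (B in c(2, 3)) {
    p <- bootstrap_pvalues(counts, c("SW", "SD"), B = B, seed = 1)
    expect_equal(unname(p[c("g1", "g3")]), c(1, 1))
  }
})

test_that("BH q-values match the hand-worked step-up and preserve p order", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # independent step-up computation
  m <- length(p)
  o <- order(p)
  q_hand <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_hand <- pmin(q_hand, 1)[order(o)]
  expect_equal(q, q_hand)
})

test_that("fold change follows the CPM convention and zero rules", {
  expect_equal(fold_change(10, 30, 1e6, 1e6), 3)
  expect_equal(fold_change(5, 5, 2e6, 2e6), 1)
  expect_equal(fold_change(7, 0, 1e6, 1e6), 0)     # numerator zero
  expect_identical(fold_change(0, 7, 1e6, 1e6), Inf)
  expect_true(is.na(fold_change(0, 0, 1e6, 1e6)))
  # scaling invariance: multiply counts and sizes by the same factor
  expect_equal(fold_change(12, 30, 1e6, 2e6),
               fold_change(12 * 7, 30 * 7, 7e6, 14e6))
})

test_that("status classification applies the FC/FDR rules with bounds", {
  expect_equal(classify_deg(3, 1e-5), "up")
  expect_equal(classify_deg(0.5, 1e-5), "down")     # inclusive boundary
  expect_equal(classify_deg(1.5, 1e-5), "not_significant")  # strict up bound
  expect_equal(classify_deg(3, 0.01), "not_significant")
  expect_equal(classify_deg(NA_real_, 0.5), "undetermined")
  expect_equal(classify_deg(Inf, 1e-9), "up")
  expect_equal(classify_deg(0, 1e-9), "down")
})

test_that("TPM normalises by length and sums to one million", {
  expect_equal(tpm(10, 500), 1e6)
  expect_equal(tpm(c(10, 10), c(100, 200)), c(2 / 3, 1 / 3) * 1e6)
  expect_equal(tpm(c(0, 0), c(100, 200)), c(0, 0))
  set.seed(5)
  x <- rpois(30, 40)
  expect_equal(sum(tpm(x, sample(300:900, 30))), 1e6)
})

test_that("both-zero genes never end up or down", {
  cfg <- small_config(n_genes = 120L, de_fraction = 0.2, seed = 17L)
  counts <- generate_counts(cfg)$counts
  counts[1:10, ] <- 0
  de <- run_de(counts, c("SW", "SD"), B = 20, seed = 31)
  expect_true(all(de$status[1:10] == "undetermined"))
  expect_false(any(de$status[1:10] %in% c("up", "down")))
})
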