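# Independent brute-force oracle: enumerate every table with the observed
# margins and sum the probabilities not exceeding the observed one.
fisher_oracle <- function(a, b, c, d) {
  k <- a + c; r1 <- a + b; tot <- a + b + c + d
  support <- max(0, k - (tot - r1)):min(k, r1)
  probs <- vapply(support, function(x)
    exp(lchoose(k, x) + lchoose(tot - k, r1 - x) - lchoose(tot, r1)),
    numeric(1))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("fisher_exact matches printed examples and flags degenerate tables", {
  # symmetric table: p = 1
  expect_equal(fisher_exact(5, 95, 5, 95)$p_value, 1)
  # 4 copies in cases, 0 in controls, 2000 + 2000 chromosomes: only the two
  # extreme tables are as unlikely as the observed one
  r <- fisher_exact(4, 1996, 0, 2000)
  expect_equal(r$p_value, dhyper(4, 4, 3996, 2000) + dhyper(0, 4, 3996, 2000))
  expect_equal(r$p_value, 0.1248, tolerance = 1e-3)
  # zero margin: untestable, p = 1
  z <- fisher_exact(0, 100, 0, 100)
  expect_equal(z$p_value, 1)
  expect_false(z$testable)
  expect_true(is.na(z$odds_ratio))
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  # odds ratio is ad/bc with infinity preserved
  expect_equal(fisher_exact(10, 90, 5, 95)$odds_ratio, (10 * 95) / (90 * 5))
  expect_equal(fisher_exact(4, 96, 0, 100)$odds_ratio, Inf)
})

test_that("fisher_exact agrees with stats::fisher.test and the oracle", {
  set.seed(71)
  for (i in 1:200) {
    tot <- sample(4:400, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    ours <- fisher_exact(a, b, c, d)$p_value
    expect_equal(ours, fisher_oracle(a, b, c, d), tolerance = 1e-9)
    ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    expect_equal(ours, min(ref, 1), tolerance = 1e-7)
  }
})

test_that("significance counting is nested across thresholds", {
  res <- tibble::tibble(
    p_value = c(1e-9, 1e-6, 1e-3, 0.5, 1),
    testable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(count_significant(res, 5e-8), 1)
  expect_equal(count_significant(res, 1e-5), 2)
  expect_equal(count_significant(res, 1e-2), 3)
  expect_lte(count_significant(res, 5e-8), count_significant(res, 1e-5))
  expect_lte(count_significant(res, 1e-5), count_significant(res, 1e-2))
  expect_equal(count_significant(res[0, ], 1e-2), 0)
})

test_that("V_A-by-P-value fractions are monotone and anchored", {
  res <- tibble::tibble(
    site = 1:4, s = -0.01, p = c(0.5, 0.1, 0.01, 0.001),
    alpha = c(1, 2, 3, 4),
    p_value = c(1e-6, 0.02, 0.2, 1),
    testable = c(TRUE, TRUE, TRUE, FALSE),
    in_sample = c(TRUE, TRUE, TRUE, FALSE))
  v <- 2 * res$p * (1 - res$p) * res$alpha^2
  out <- va_explained_by_pvalue(res, thresholds = c(0, 1e-5, 0.05, 1, 1.0001))
  expect_equal(out$fraction[1], 0)
  expect_equal(out$fraction[2], v[1] / sum(v))
  expect_equal(out$fraction[3], sum(v[1:2]) / sum(v))
  expect_equal(out$fraction[4], sum(v[1:3]) / sum(v))
  # "threshold > 1" = everything polymorphic in the sample
  expect_equal(out$fraction[5], sum(v[1:3]) / sum(v))
  expect_true(all(diff(out$fraction) >= 0))
})

test_that("exact-test rejections under the null are below the nominal rate", {
  # all alpha = 0 at common frequencies: the exact test is valid (and
  # conservative), so the rejection rate at 0.01 cannot exceed the nominal
  # rate by more than Monte Carlo error
  arch0 <- make_fixture("null_trait")
  set.seed(72)
  n_rep <- 60
  hits <- replicate(n_rep, {
    cohort <- make_cohort(arch0, n_source = 1200, n_cases = 300,
                          n_controls = 300)
    count_significant(assoc_test(cohort), 0.01)
  })
  rate <- sum(hits) / (n_rep * nrow(arch0$sites))
  expect_lt(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / (n_rep * 5)))
})

test_that("power-by-bin conditions on occupied bins", {
  res1 <- tibble::tibble(site = 1:3, s = -0.01, p = c(0.3, 0.01, 0.001),
                         alpha = 1, p_value = c(1e-7, 0.5, 0.5),
                         odds_ratio = c(2, 1, 1),
                         testable = TRUE, in_sample = TRUE)
  res2 <- res1
  res2$p_value <- c(0.5, 1e-7, 0.5)
  out <- power_by_bin(list(res1, res2), bin_by = "frequency",
                      breaks = c(0, 0.005, 0.1, 1), threshold = 1e-5)
  expect_equal(nrow(out), 3)
  # common bin (0.1, 1]: hit in replicate 1 only -> power 0.5
  expect_equal(out$power[out$bin == "(0.1,1]"], 0.5)
  # middle bin (0.005, 0.1]: hit in replicate 2 only -> power 0.5
  expect_equal(out$power[out$bin == "(0.005,0.1]"], 0.5)
  # rare bin: never significant -> power 0
  expect_equal(out$power[1], 0)
  expect_error(power_by_bin(list(res1)), "2 replicates")
})
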