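test_that("per-feature success probability matches direct evaluation", {
  expect_identical(per_feature_success_prob(0, 1000), 0)
  expect_equal(per_feature_success_prob(0.37, 1), 0.37)
  ## direct double evaluation of (1-p)^L is itself only ~1e-10 accurate
  expect_equal(per_feature_success_prob(1e-6, 1000), 1 - (1 - 1e-6)^1000,
               tolerance = 1e-9)
  expect_equal(per_feature_success_prob(1e-6, 1000), 9.995005e-4,
               tolerance = 1e-6)
  expect_equal(per_feature_success_prob(1, 50), 1)
  ## monotone in both arguments
  rates <- c(1e-8, 1e-6, 1e-4, 1e-2, 0.5)
  expect_true(all(diff(per_feature_success_prob(rates, 1e3)) > 0))
  lens <- c(1, 10, 1e3, 1e6)
  expect_true(all(diff(per_feature_success_prob(1e-6, lens)) > 0))
  expect_error(per_feature_success_prob(-0.1, 10), "\\[0, 1\\]")
  expect_error(per_feature_success_prob(0.1, 0), ">= 1")
})

test_that("binomial burden p-value matches the exhaustive-summation oracle", {
  expect_identical(binomial_burden_pvalue(0, 10, 0.1), 1)
  expect_equal(binomial_burden_pvalue(5, 5, 0.5), 0.03125)
  expect_equal(binomial_burden_pvalue(3, 10, 0.1), 0.0701908,
               tolerance = 1e-6)
  for (N in c(1, 3, 7, 20)) {
    for (p in c(0.01, 0.3, 0.9)) {
      for (n in 0:N) {
        expect_equal(binomial_burden_pvalue(n, N, p),
                     naive_binom_tail(n, N, p), tolerance = 1e-10)
      }
    }
  }
  ## monotone non-increasing in n
  ps <- vapply(0:10, binomial_burden_pvalue, numeric(1),
               cohort_size = 10, p_n = 0.2)
  expect_true(all(diff(ps) <= 0))
  expect_error(binomial_burden_pvalue(11, 10, 0.1), "<=")
})

test_that("negative-binomial p-value matches its oracle and the binomial duality", {
  expect_identical(negbin_pvalue(0, 100, 10, 0.01), 1)
  expect_equal(negbin_pvalue(2, 4, 1, 0.5), 0.6875)
  ## k = x leaves only the r = 0 term, p^k
  expect_equal(negbin_pvalue(6, 3, 2, 0.3), 0.3^6)
  for (k in c(1, 2, 5, 10)) {
    for (x in c(12, 30, 50)) {
      for (p in c(0.01, 0.1, 0.5)) {
        expect_equal(negbin_pvalue(k, x, 1, p), naive_negbin(k, x, p),
                     tolerance = 1e-10)
        ## duality: NB tail equals P(Bin(x, p) >= k)
        expect_equal(negbin_pvalue(k, x, 1, p),
                     pbinom(k - 1, x, p, lower.tail = FALSE),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(negbin_pvalue(11, 5, 2, 0.1), "exceeds")
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  ## single p-value is an identity
  for (p in c(1e-12, 0.001, 0.05, 0.5, 1)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  }
  ## two components: survival of chi-square df 4 is e^(-X/2) (1 + X/2)
  for (pp in list(c(0.05, 0.05), c(0.01, 0.8), c(0.3, 0.7))) {
    x <- -2 * sum(log(pp))
    expect_equal(fisher_combine(pp), exp(-x / 2) * (1 + x / 2),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0174787, tolerance = 1e-5)
  ## zero components are clamped, not fatal; negatives are fatal
  expect_lt(fisher_combine(c(0, 0.5)), 1e-250)
  expect_error(fisher_combine(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "non-empty")
  ## never exceeds 1 and is monotone in each component
  set.seed(42)
  for (i in 1:20) {
    p <- runif(3)
    expect_lte(fisher_combine(p), 1)
    bumped <- p
    bumped[2] <- min(1, p[2] * 1.5)
    expect_gte(fisher_combine(bumped), fisher_combine(p))
  }
})

test_that("BH q-values reproduce the step-up oracle and its invariances", {
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bh_fdr(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    ## permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null sample-count draws give a conservative p-value distribution", {
  N <- 100
  p_n <- 0.01
  set.seed(1234)
  n <- rbinom(10000, N, p_n)
  pv <- vapply(n, binomial_burden_pvalue, numeric(1),
               cohort_size = N, p_n = p_n)
  expect_lte(mean(pv < 0.05), 0.07)
  ## also at a larger success probability
  p_n <- 0.2
  n <- rbinom(10000, N, p_n)
  pv <- vapply(n, binomial_burden_pvalue, numeric(1),
               cohort_size = N, p_n = p_n)
  expect_lte(mean(pv < 0.05), 0.07)
})
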