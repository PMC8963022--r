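# Two-pass brute-force one-way ANOVA, independent of the lm route.
oracle_anova <- function(groups) {
  values <- unlist(groups)
  grand <- mean(values)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df_b <- length(groups) - 1
  df_w <- length(values) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(ss_between = ss_between, ss_within = ss_within, f = f,
       p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Explicit-formula Friedman oracle.
oracle_friedman <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

test_that("the Anderson-Darling statistic matches an independent reference", {
  skip_if_not_installed("nortest")
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(sample(20:200, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.1, 4))
    ours <- anderson_darling_normal(x)
    ref <- nortest::ad.test(x)
    expect_equal(ours$statistic_uncorrected, unname(ref$statistic),
                 tolerance = 1e-6)
  }
})

test_that("Anderson-Darling discriminates normal from uniform samples", {
  accept <- vapply(1:100, function(s) {
    anderson_darling_normal(with_rng(rng_handle(s), rnorm(500)))$p_value > 0.05
  }, logical(1))
  reject <- vapply(1:100, function(s) {
    anderson_darling_normal(rng_uniform(rng_handle(1000 + s), 500))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(accept), 0.95)
  expect_gte(mean(reject), 0.95)
  expect_error(anderson_darling_normal(rep(1, 50)), "constant")
  expect_error(anderson_darling_normal(rnorm(5)), "n >= 8")
})

test_that("one-way ANOVA matches the brute-force decomposition", {
  nine_same <- rep(list(c(1, 2, 3, 4, 5)), 9)
  res <- oneway_anova(nine_same)
  expect_equal(res$table$sum_sq[1], 0, tolerance = 1e-12)
  expect_identical(res$table$df[1], 8L)  # 9 methods -> df 8

  set.seed(71)
  for (i in 1:20) {
    groups <- lapply(seq_len(sample(2:9, 1)),
                     function(g) rnorm(sample(3:10, 1), mean = g / 3))
    res <- oneway_anova(groups)
    ora <- oracle_anova(groups)
    expect_equal(res$table$sum_sq[1], ora$ss_between, tolerance = 1e-10)
    expect_equal(res$table$sum_sq[2], ora$ss_within, tolerance = 1e-10)
    expect_equal(res$statistic, ora$f, tolerance = 1e-10)
    expect_equal(res$p_value, ora$p, tolerance = 1e-10)
  }
  # zero variance everywhere: F undefined, reported as NA
  degenerate <- oneway_anova(rep(list(c(2, 2, 2)), 3))
  expect_true(is.na(degenerate$statistic))
})

test_that("Friedman ranks, statistic and p-value are correct", {
  m <- rbind(c(0.1, 0.5, 0.9), c(0.2, 0.6, 0.7), c(0.15, 0.4, 0.8))
  res <- friedman_test(m)
  expect_equal(unname(res$rank_table$ranks[1, ]), c(1, 2, 3))
  # the best treatment in every block attains rank k in every row
  expect_true(all(res$rank_table$ranks[, 3] == 3))
  # row sums are k(k+1)/2
  expect_true(all(rowSums(res$rank_table$ranks) == 6))
  expect_equal(res$statistic, oracle_friedman(m), tolerance = 1e-12)
  ref <- stats::friedman.test(m)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)

  # complete ties: no discrimination, chi-square 0
  flat <- matrix(1, 4, 5)
  expect_equal(friedman_test(flat)$statistic, 0, tolerance = 1e-12)
  expect_error(friedman_test(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("Friedman agrees with independent references on random matrices", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(2:8, 1); k <- sample(2:9, 1)
    m <- matrix(rnorm(n * k), n, k)
    res <- friedman_test(m)
    expect_equal(res$statistic, oracle_friedman(m), tolerance = 1e-10)
    expect_equal(res$statistic,
                 unname(stats::friedman.test(m)$statistic),
                 tolerance = 1e-10)
    expect_identical(res$df, k - 1L)
  }
})

test_that("rank sums satisfy their conservation identities", {
  set.seed(91)
  for (i in 1:10) {
    m <- matrix(runif(45), 5, 9)
    rt <- rank_table(m)
    expect_true(all(rowSums(rt$ranks) == 9 * 10 / 2))
    expect_equal(sum(rt$rank_sums), 5 * 9 * 10 / 2)
  }
})

test_that("comparison routes by normality at the 0.05 threshold", {
  set.seed(102)
  gauss <- matrix(rnorm(45, mean = 0.8, sd = 0.02), 5, 9)
  rep_g <- compare_samplers(gauss)
  expect_identical(rep_g$route, "anova")
  expect_null(rep_g$rank_table)

  heavy <- matrix(c(rep(0.1, 30), rexp(15, 0.5)), 5, 9)
  rep_h <- compare_samplers(heavy)
  expect_identical(rep_h$route, "friedman")
  expect_false(is.null(rep_h$rank_table))
  expect_match(rep_h$summary, "friedman")
})
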