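t_mort <- list(a = 132, b = 477, c = 156, d = 412)  # HA mortality, intervention

test_that("2x2 tables tally post/pre events exactly", {
  rows <- data.frame(
    site = "intervention",
    period = rep(c("pre", "post"), c(5, 4)),
    died = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    ha = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
  t <- build_two_by_two(rows, "died", site = "intervention")
  expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = 1, b = 3, c = 2, d = 3))
  t2 <- build_two_by_two(rows, "died", stratum = rows$ha)
  expect_equal(unlist(t2[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 2, d = 1))
  # constant-false outcome
  rows$never <- FALSE
  t3 <- build_two_by_two(rows, "never")
  expect_equal(t3$a + t3$c, 0)
  # empty stratum flagged
  t4 <- build_two_by_two(rows, "died", stratum = rep(FALSE, nrow(rows)))
  expect_true(t4$empty)
})

test_that("odds ratio is symmetric, row-scale invariant and zero-cell corrected", {
  expect_equal(as.numeric(odds_ratio(list(a = 1, b = 1, c = 1, d = 1))), 1)
  base <- odds_ratio(t_mort)
  scaled <- odds_ratio(list(a = t_mort$a * 3, b = t_mort$b * 3,
                            c = t_mort$c, d = t_mort$d))
  expect_equal(as.numeric(scaled), as.numeric(base))
  corrected <- odds_ratio(list(a = 0, b = 10, c = 5, d = 5))
  expect_true(attr(corrected, "corrected"))
  expect_equal(as.numeric(corrected), (0.5 / 10.5) / (5.5 / 5.5))
  expect_error(odds_ratio(list(a = 0, b = 0, c = 0, d = 0)), "all-zero")
})

test_that("Woolf interval brackets the point estimate and tightens with n", {
  ci <- woolf_ci(t_mort)
  expect_lt(ci[1], as.numeric(odds_ratio(t_mort)))
  expect_gt(ci[2], as.numeric(odds_ratio(t_mort)))
  big <- lapply(t_mort[c("a", "b", "c", "d")], `*`, 10)
  ci_big <- woolf_ci(big)
  expect_lt(diff(log(ci_big)), diff(log(ci)))
  # symmetric table: interval symmetric about 1 on the log scale
  ci1 <- woolf_ci(list(a = 1, b = 1, c = 1, d = 1))
  expect_equal(log(ci1[1]), -log(ci1[2]))
})

test_that("chi-square p-value matches the closed-form Pearson statistic", {
  set.seed(51)
  for (i in 1:25) {
    t <- list(a = as.numeric(sample(5:200, 1)), b = as.numeric(sample(5:200, 1)),
              c = as.numeric(sample(5:200, 1)), d = as.numeric(sample(5:200, 1)))
    n <- t$a + t$b + t$c + t$d
    stat <- n * (t$a * t$d - t$b * t$c)^2 /
      ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
    expect_equal(chi2_p(t), stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  expect_equal(chi2_p(list(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_equal(chi2_p(list(a = 10, b = 20, c = 20, d = 40)), 1)  # equal props
  expect_true(is.na(chi2_p(list(a = 0, b = 0, c = 3, d = 4))))   # degenerate
})

test_that("CMH agrees with mantelhaen.test and reduces correctly for one stratum", {
  t <- t_mort
  t2 <- list(a = 64, b = 545, c = 92, d = 476)
  # two strata: base R mantelhaen.test is the independent reference
  arr <- array(c(t$a, t$b, t$c, t$d, t2$a, t2$b, t2$c, t2$d), c(2, 2, 2))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  both <- cmh_test(list(t, t2))
  expect_equal(both$statistic, unname(ref$statistic))
  expect_equal(both$p_value, ref$p.value)
  expect_equal(both$common_or, unname(ref$estimate))
  # single stratum: MH chi-square of that table; common OR = table OR
  one <- cmh_test(list(t))
  expect_equal(one$common_or, as.numeric(odds_ratio(t)))
  n <- t$a + t$b + t$c + t$d
  ex <- (t$a + t$b) * (t$a + t$c) / n
  v <- (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d) / (n^2 * (n - 1))
  expect_equal(one$statistic, (t$a - ex)^2 / v)
  # duplicated stratum: same common OR, doubled statistic
  two <- cmh_test(list(t, t))
  expect_equal(two$common_or, one$common_or)
  expect_equal(two$statistic, 2 * one$statistic, tolerance = 1e-8)
  # strata with OR 1 give p near 1
  null <- cmh_test(list(list(a = 20, b = 20, c = 20, d = 20)))
  expect_gt(null$p_value, 0.99)
  expect_error(cmh_test(list(list(a = 0, b = 0, c = 1, d = 1))), "margins")
})

test_that("continuous comparisons behave at the null and under separation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_continuous(x, x, "mann_whitney"), 1)
  expect_lt(compare_continuous(rnorm(100), rnorm(100) + 10, "t"), 1e-10)
  expect_error(compare_continuous(1, c(1, 2), "t"), "at least two")
  expect_error(compare_continuous(numeric(), 1:3), "non-empty")
})

test_that("t-test type-I error is near nominal under the null", {
  set.seed(52)
  rej <- mean(replicate(1000, {
    compare_continuous(rnorm(30), rnorm(30), "t") < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
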