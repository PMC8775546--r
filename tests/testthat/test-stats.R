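test_that("assumption report reproduces its component tests and fences", {
  set.seed(31)
  left <- rnorm(12); right <- rnorm(12, sd = 2)
  rep <- check_assumptions(left, right)
  expect_equal(rep$shapiro$p[1], shapiro.test(left)$p.value, tolerance = 1e-12)
  expect_equal(rep$shapiro$p[2], shapiro.test(right)$p.value, tolerance = 1e-12)
  lev <- levene_bf_oracle(left, right)
  expect_equal(rep$levene_statistic, lev$F, tolerance = 1e-10)
  expect_equal(rep$levene_p, lev$p, tolerance = 1e-10)

  # Tukey fences under type-7 quantiles: Q1 = 2, Q3 = 3, so 100 is extreme
  rep2 <- check_assumptions(c(1, 2, 2, 3, 100), c(1, 2, 2, 3, 4))
  expect_identical(rep2$outliers$value, 100)
  expect_identical(rep2$outliers$severity, "extreme")

  expect_error(check_assumptions(c(1, 2), rnorm(5)),
               class = "kin_error_insufficient_sample")
})

test_that("normality failure switches the decision to nonparametric", {
  set.seed(41)
  skewed <- exp(rnorm(20, sd = 1.5))
  normal <- rnorm(20)
  # oracle run: the skewed side fails Shapiro-Wilk at 0.05
  expect_lt(shapiro.test(skewed)$p.value, 0.05)
  rep <- check_assumptions(normal, skewed)
  expect_identical(rep$decision, "nonparametric")
  rep2 <- check_assumptions(normal, rnorm(20))
  expect_identical(rep2$decision, "parametric")
})

test_that("Welch contrast matches the closed-form oracle", {
  cases <- list(
    list(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10)),
    list(a = rnorm(8, sd = 1), b = rnorm(15, 2, 4)),
    list(a = runif(6), b = runif(30) * 10)
  )
  set.seed(51)
  for (cs in cases) {
    res <- compare_sides(cs$a, cs$b,
                         assumptions = check_assumptions(cs$a, cs$b, 1e-12))
    orc <- welch_oracle(cs$a, cs$b)
    expect_identical(res$test, "welch_t")
    expect_equal(res$statistic, orc$t, tolerance = 1e-10)
    expect_equal(res$df, orc$df, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_equal(res$effect, mean(cs$b) - mean(cs$a), tolerance = 1e-12)
  }
})

test_that("equal-n equal-variance Welch df is 2n - 2", {
  a <- c(1, 2, 3, 4, 6)
  b <- a + 10  # identical variance
  res <- compare_groups(a, b)
  expect_equal(res$df, 2 * length(a) - 2, tolerance = 1e-10)
})

test_that("identical samples give t = 0, p = 1; constant ones are flagged", {
  set.seed(61)
  x <- rnorm(10)
  res <- compare_sides(x, x, assumptions = check_assumptions(x, x, 1e-12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  deg <- compare_sides(rep(2, 5), rep(2, 5))
  expect_identical(deg$statistic, 0)
  expect_identical(deg$p_value, 1)
  expect_true("degenerate" %in% deg$flags)
})

test_that("swapping side labels flips t and preserves p", {
  set.seed(71)
  for (i in 1:10) {
    l <- rnorm(9); r <- rnorm(11, mean = 0.5)
    asm <- check_assumptions(l, r, 1e-12)
    ab <- compare_sides(l, r, assumptions = asm)
    ba <- compare_sides(r, l, assumptions = check_assumptions(r, l, 1e-12))
    expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    expect_equal(ab$effect, -ba$effect, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney path matches exact enumeration and tie-corrected approximation", {
  # exact, tie-free, small n
  a <- c(1.1, 3.4, 2.2, 5.6, 0.3)
  b <- c(2.9, 7.1, 6.5, 8.8, 4.4)
  asm <- structure(list(shapiro = data.frame(side = c("left", "right"),
                                             W = NA_real_, p = 0.001),
                        levene_statistic = NA_real_, levene_p = NA_real_,
                        outliers = data.frame(), alpha_normality = 0.05,
                        decision = "nonparametric"),
                   class = "assumption_report")
  res <- compare_sides(a, b, assumptions = asm)
  orc <- mw_exact_oracle(a, b)
  expect_identical(res$test, "mann_whitney")
  expect_equal(res$statistic, orc$W, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)

  # ties force the corrected normal approximation
  a2 <- c(1, 2, 2, 3, 5, 7, 7)
  b2 <- c(2, 4, 4, 6, 7, 9, 10)
  res2 <- compare_sides(a2, b2, assumptions = asm)
  orc2 <- mw_normal_oracle(a2, b2)
  expect_equal(res2$statistic, orc2$W, tolerance = 1e-12)
  expect_equal(res2$p_value, orc2$p, tolerance = 1e-10)
})

test_that("shifted distributions are detected with high power", {
  hits <- 0L
  for (i in 1:50) {
    set.seed(800 + i)
    l <- rnorm(15)
    r <- rnorm(15, mean = 3)  # 3 SD shift
    if (compare_sides(l, r)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})

test_that("one-way ANOVA matches the sums-of-squares oracle and F = t^2", {
  set.seed(91)
  groups <- list(tango = rnorm(6), waltz = rnorm(5, 1), foxtrot = rnorm(7, 0.5),
                 line = rnorm(4, -1))
  res <- compare_across_dances(groups)
  orc <- anova_oracle(groups)
  expect_equal(res$statistic, orc$F, tolerance = 1e-10)
  expect_equal(res$df, c(orc$df1, orc$df2), tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)

  two <- list(a = rnorm(8), b = rnorm(9, 0.4))
  res2 <- compare_across_dances(two)
  expect_equal(res2$statistic, pooled_t_oracle(two$a, two$b)^2,
               tolerance = 1e-10)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res3 <- compare_across_dances(same)
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_equal(res3$p_value, 1, tolerance = 1e-12)

  expect_error(compare_across_dances(list(a = rnorm(3), b = 1)),
               class = "kin_error_insufficient_sample")
  expect_error(compare_across_dances(list(a = rnorm(3))),
               class = "kin_error_argument")
})

test_that("outlier flagging never alters the downstream statistic", {
  set.seed(101)
  l <- c(rnorm(9), 8)  # one gross outlier, kept in
  r <- rnorm(10)
  asm <- check_assumptions(l, r, 1e-12)
  expect_gt(nrow(asm$outliers), 0)
  asm_clean <- asm
  asm_clean$outliers <- asm$outliers[0, ]
  with_flag <- compare_sides(l, r, assumptions = asm)
  without_flag <- compare_sides(l, r, assumptions = asm_clean)
  expect_identical(with_flag$statistic, without_flag$statistic)
  expect_identical(with_flag$p_value, without_flag$p_value)
})
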