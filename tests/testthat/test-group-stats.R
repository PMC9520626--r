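test_that("ANOVA F matches direct sums-of-squares arithmetic", {
  groups <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8),
                 c(13, 9, 11, 8, 7, 12))
  fit <- oneway_anova(groups_to_df(groups))
  expect_equal(fit$F, brute_anova_F(groups), tolerance = 1e-9)
  expect_equal(fit$df_between, 2L)
  expect_equal(fit$df_within, 15L)
  expect_equal(glance(fit)$p,
               pf(brute_anova_F(groups), 2, 15, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical groups give F = 0 and p = 1", {
  fit <- oneway_anova(groups_to_df(list(1:3, 1:3)))
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
})

test_that("degenerate zero-variance groups are flagged with p = 0", {
  fit <- oneway_anova(groups_to_df(list(c(1, 1, 1), c(2, 2, 2))))
  expect_true(fit$degenerate)
  expect_equal(fit$p, 0)
})

test_that("at k = 2 the ANOVA reproduces the pooled t-test (F = t^2)", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(8, mean = 0.5)
    fit <- oneway_anova(groups_to_df(list(a, b)))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(fit$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("F is invariant under shift and scale", {
  set.seed(33)
  g <- list(rnorm(5), rnorm(5, 1), rnorm(5, 2))
  f0 <- oneway_anova(groups_to_df(g))$F
  shifted <- lapply(g, function(v) 100 + v)
  scaled <- lapply(g, function(v) 0.001 * v)
  expect_equal(oneway_anova(groups_to_df(shifted))$F, f0, tolerance = 1e-9)
  expect_equal(oneway_anova(groups_to_df(scaled))$F, f0, tolerance = 1e-9)
})

test_that("null rejection rate sits near the nominal 5% level", {
  set.seed(808)
  rejections <- vapply(1:400, function(i) {
    d <- groups_to_df(list(rnorm(5), rnorm(5), rnorm(5)))
    oneway_anova(d)$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})

test_that("homogeneity test behaves at its boundaries and under power", {
  d <- groups_to_df(list(1:3, 1:3))
  h <- variance_homogeneity(d)
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)
  expect_true(h$equal_variances)

  set.seed(55)
  hits <- vapply(1:100, function(i) {
    d <- groups_to_df(list(rnorm(20, sd = 1), rnorm(20, sd = 10)))
    !variance_homogeneity(d)$equal_variances
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("homogeneity null rejection is near alpha", {
  set.seed(56)
  hits <- vapply(1:400, function(i) {
    d <- groups_to_df(list(rnorm(10), rnorm(10), rnorm(10)))
    variance_homogeneity(d)$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.015)
  expect_lt(mean(hits), 0.10)
})

test_that("post-hoc tables cover all pairs with sane p values", {
  set.seed(61)
  d <- groups_to_df(list(rnorm(5), rnorm(5, 1), rnorm(5, 2), rnorm(5, 3)))
  fit <- oneway_anova(d)
  for (m in c("lsd", "tamhane")) {
    tab <- posthoc(fit, m)
    expect_equal(nrow(tab), choose(4, 2))
    expect_true(all(tab$p >= 0 & tab$p <= 1))
  }
  expect_error(posthoc(fit, "bonferroni"))
})

test_that("identical groups give zero differences and p = 1 in both methods", {
  fit <- oneway_anova(groups_to_df(list(c(1, 2, 3), c(1, 2, 3))))
  for (m in c("lsd", "tamhane")) {
    tab <- posthoc(fit, m)
    expect_equal(tab$mean_difference, 0)
    expect_equal(tab$p, 1)
  }
})

test_that("LSD at k = 2 equals the pooled t-test", {
  set.seed(71)
  a <- rnorm(6); b <- rnorm(7, 1)
  tab <- posthoc(oneway_anova(groups_to_df(list(a, b))), "lsd")
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(abs(tab$statistic), abs(unname(tt$statistic)),
               tolerance = 1e-9)
  expect_equal(tab$p, tt$p.value, tolerance = 1e-9)
})

test_that("Tamhane T2 is conservative relative to raw Welch tests", {
  set.seed(81)
  d <- groups_to_df(list(rnorm(5), rnorm(6, 1, 3), rnorm(7, 2, 0.5)))
  tab <- posthoc(oneway_anova(d), "tamhane")
  expect_true(all(tab$p >= tab$p_unadjusted))
  # and each unadjusted p equals the Welch two-sample t-test p
  groups <- split(d$value, d$group)
  for (i in seq_len(nrow(tab))) {
    w <- t.test(groups[[tab$group1[i]]], groups[[tab$group2[i]]])
    expect_equal(tab$p_unadjusted[i], w$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches closed forms and guards input", {
  x <- 1:10
  expect_equal(pearson_correlation(data.frame(x = x, y = 2 * x + 1))$r, 1)

  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 3, 4, 5))
  fit <- pearson_correlation(d)
  mx <- mean(d$x); my <- mean(d$y)
  r_hand <- sum((d$x - mx) * (d$y - my)) /
    sqrt(sum((d$x - mx)^2) * sum((d$y - my)^2))
  expect_equal(fit$r, r_hand, tolerance = 1e-12)
  expect_equal(fit$slope, unname(coef(lm(y ~ x, d))[2]), tolerance = 1e-12)

  expect_error(pearson_correlation(data.frame(x = 1:2, y = 2:3)),
               class = "tg_parameter_error")
  expect_error(pearson_correlation(data.frame(x = rep(1, 5), y = 1:5)),
               class = "tg_data_error")
})

test_that("independent variables show near-zero correlation", {
  set.seed(99)
  rs <- vapply(1:20, function(i)
    abs(pearson_correlation(data.frame(x = rnorm(1000), y = rnorm(1000)))$r),
    0)
  expect_lt(sort(rs)[19], 0.08)  # 95th percentile over seeds
})

test_that("compare_groups routes the post-hoc by the homogeneity gate", {
  set.seed(111)
  equal_var <- groups_to_df(list(rnorm(8), rnorm(8, 1), rnorm(8, 2)))
  cg <- compare_groups(equal_var)
  expect_equal(unique(cg$posthoc$method),
               if (cg$homogeneity$equal_variances) "LSD" else "TamhaneT2")
  expect_equal(nrow(cg$measure_summary), 3)
  expect_named(cg$measure_summary, c("group", "n", "mean", "sd", "sem"))
})
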