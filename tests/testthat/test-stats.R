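test_that("one-way ANOVA matches hand-computed sums of squares", {
  r <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 13.5)
  expect_equal(r$df, c(1, 4))

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ident <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  expect_error(anova_oneway(list(c(1, 2))), "two groups")
  expect_error(anova_oneway(list(c(1, 2), 3)), "two observations")
})

test_that("one-way ANOVA agrees with the base R oracle on random data", {
  set.seed(8)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(4:9, 1), mean = j / 2))
    mine <- anova_oneway(groups)
    y <- unlist(groups)
    g <- factor(rep(seq_len(k), lengths(groups)))
    oracle <- stats::oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, unname(oracle$p.value), tolerance = 1e-9)
  }
})

test_that("summary-based ANOVA is exact on summaries of raw groups", {
  set.seed(17)
  for (i in 1:5) {
    groups <- lapply(1:4, function(j) rnorm(sample(3:10, 1), mean = j))
    summaries <- dplyr::bind_rows(lapply(seq_along(groups), function(j)
      group_summary(paste0("g", j), length(groups[[j]]),
                    mean(groups[[j]]), sd(groups[[j]]))))
    from_sum <- anova_from_summaries(summaries)
    from_raw <- anova_oneway(groups)
    expect_equal(from_sum$statistic, from_raw$statistic, tolerance = 1e-9)
    expect_equal(from_sum$p_value, from_raw$p_value, tolerance = 1e-9)
  }
  eq <- anova_from_summaries(dplyr::bind_rows(
    group_summary("a", 5, 1, 0.5), group_summary("b", 7, 1, 0.5)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("egg-type ANOVA reconstructed from published summaries", {
  vit <- anova_from_summaries(egg_group_summaries("vitd3"))
  expect_equal(vit$df, c(3, 30))
  expect_equal(vit$p_value, 0.538, tolerance = 0.02)
  oh <- anova_from_summaries(egg_group_summaries("ohd3"))
  expect_equal(oh$p_value, 0.121, tolerance = 0.02)
})

test_that("p decreases in F at fixed degrees of freedom", {
  fs <- seq(0.1, 10, length.out = 20)
  ps <- stats::pf(fs, 3, 30, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("two-factor additive ANOVA matches sequential least squares", {
  # 2x2 balanced layout with known cell structure
  a <- factor(rep(c("a1", "a2"), each = 4))
  b <- factor(rep(c("b1", "b2"), times = 4))
  y <- c(1, 2, 1.5, 2.5, 3, 4, 3.5, 4.5)
  mine <- anova_twoway_tukey(y, a, b)
  oracle <- stats::anova(stats::lm(y ~ a + b))
  expect_equal(mine$factor_a$statistic, oracle$`F value`[1], tolerance = 1e-9)
  expect_equal(mine$factor_b$statistic, oracle$`F value`[2], tolerance = 1e-9)
  expect_equal(mine$factor_a$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(mine$factor_b$p_value, oracle$`Pr(>F)`[2], tolerance = 1e-9)

  # unbalanced random layouts against the sequential (Type-I) oracle
  set.seed(12)
  for (i in 1:5) {
    n <- sample(16:30, 1)
    fa <- factor(sample(letters[1:3], n, replace = TRUE))
    fb <- factor(sample(c("u", "v"), n, replace = TRUE))
    while (nlevels(droplevels(fa)) < 3 || nlevels(droplevels(fb)) < 2) {
      fa <- factor(sample(letters[1:3], n, replace = TRUE))
      fb <- factor(sample(c("u", "v"), n, replace = TRUE))
    }
    yy <- rnorm(n) + as.integer(fa) * 0.5
    mine <- anova_twoway_tukey(yy, fa, fb)
    oracle <- stats::anova(stats::lm(yy ~ fa + fb))
    expect_equal(mine$factor_a$statistic, oracle$`F value`[1], tolerance = 1e-9)
    expect_equal(mine$factor_b$statistic, oracle$`F value`[2], tolerance = 1e-9)
  }
  expect_error(anova_twoway_tukey(1:4, factor(rep("x", 4)),
                                  factor(c("u", "v", "u", "v"))),
               "two levels")
})

test_that("Tukey HSD p-values match the base R oracle and dominate t-tests", {
  set.seed(23)
  n <- 24
  fa <- factor(rep(letters[1:3], each = 8))
  fb <- factor(rep(c("u", "v"), times = 12))
  y <- rnorm(n) + as.integer(fa)
  mine <- anova_twoway_tukey(y, fa, fb)
  tk <- mine$tukey[mine$tukey$factor == "factor_a", ]

  oracle <- stats::TukeyHSD(stats::aov(y ~ fa + fb))$fa
  for (i in seq_len(nrow(tk))) {
    key <- paste0(tk$level_2[i], "-", tk$level_1[i])
    expect_equal(tk$p_adj[i], oracle[key, "p adj"], tolerance = 1e-6)
  }

  # adjusted p never below the unadjusted pairwise p on the same MSE
  df_e <- mine$factor_a$df[2]
  fit <- stats::lm(y ~ fa + fb)
  mse <- sum(stats::residuals(fit)^2) / df_e
  means <- tapply(y, fa, mean)
  ns <- table(fa)
  combs <- utils::combn(levels(fa), 2)
  for (j in seq_len(ncol(combs))) {
    l1 <- combs[1, j]; l2 <- combs[2, j]
    t_stat <- abs(means[[l2]] - means[[l1]]) /
      sqrt(mse * (1 / ns[[l1]] + 1 / ns[[l2]]))
    p_t <- 2 * stats::pt(t_stat, df_e, lower.tail = FALSE)
    p_tukey <- tk$p_adj[tk$level_1 == l1 & tk$level_2 == l2]
    expect_gte(p_tukey, p_t - 1e-12)
  }
})

test_that("regression recovers exact and noisy linear relationships", {
  ex <- linregress(1:6, 2 * (1:6))
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 0)
  expect_equal(ex$pearson_r, 1)

  x <- 1:6
  y <- x + c(1, -1, 1, -1, 1, -1)
  mine <- linregress(x, y)
  fit <- stats::lm(y ~ x)
  expect_equal(mine$slope, unname(stats::coef(fit))[2], tolerance = 1e-12)
  expect_equal(mine$intercept, unname(stats::coef(fit))[1], tolerance = 1e-12)
  expect_equal(mine$pearson_r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(mine$p_value,
               summary(fit)$coefficients["x", "Pr(>|t|)"], tolerance = 1e-9)

  zi <- linregress(x, y, zero_intercept = TRUE)
  fit0 <- stats::lm(y ~ x + 0)
  expect_equal(zi$slope, unname(stats::coef(fit0)), tolerance = 1e-12)
  expect_equal(zi$p_value,
               summary(fit0)$coefficients["x", "Pr(>|t|)"], tolerance = 1e-9)

  expect_error(linregress(c(1, 1, 1), 1:3), "constant")
  expect_error(linregress(1:2, 1:2), "three points")
})

test_that("Pearson r is invariant to sign-preserving affine transforms", {
  set.seed(44)
  x <- rnorm(10); y <- x + rnorm(10, sd = 0.3)
  r0 <- linregress(x, y)$pearson_r
  r1 <- linregress(3 * x + 7, 0.5 * y - 2)$pearson_r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("dairy fat explains the D3 vitamers across the product range", {
  pts <- dairy_fat_points()
  fit <- linregress(pts$fat_pct, pts$vitd3)
  expect_gte(fit$pearson_r, 0.97)
  expect_lt(fit$p_value, 0.001)
})
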