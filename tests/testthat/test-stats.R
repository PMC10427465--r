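test_that("scale conversion maps endpoints and midpoints and is invertible", {
  expect_equal(convert_scale(c(-5, 0, 5), c(-5, 5), c(-3, 3)), c(-3, 0, 3))
  expect_equal(convert_scale(2.5, c(-5, 5), c(-3, 3)), 1.5)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(convert_scale(convert_scale(x, c(-5, 5), c(-3, 3)),
                             c(-3, 3), c(-5, 5)), x, tolerance = 1e-12)
  expect_error(convert_scale(1, c(2, 2), c(0, 1)), "degenerate")
  expect_error(convert_scale(7, c(-5, 5), c(-3, 3)), "bounds")
})

test_that("attractiveness aggregation averages items and honours exclusions", {
  tab <- tibble::tibble(
    target_id = rep("t1", 2), rater_id = "r1",
    item = c("short", "long"), score = c(1, 3), familiarity = 1L)
  expect_equal(aggregate_attractiveness(tab)$attractiveness, 2)

  tab2 <- tibble::tibble(
    target_id = "t1", rater_id = rep(c("r1", "r2"), each = 2),
    item = rep(c("short", "long"), 2), score = c(1, 3, 2, 4),
    familiarity = 1L)
  expect_equal(aggregate_attractiveness(tab2)$attractiveness, mean(c(1.5, 3.5)))

  tab3 <- tab
  tab3$familiarity <- 3L
  agg3 <- aggregate_attractiveness(tab3)
  expect_true(agg3$missing)
  expect_true(is.na(agg3$attractiveness))
})

test_that("ICC(3,k) is 1 for duplicated raters and matches aov mean squares", {
  set.seed(2)
  base <- rnorm(12)
  tab <- tibble::tibble(
    target_id = rep(paste0("t", 1:12), 2),
    rater_id = rep(c("r1", "r2"), each = 12),
    item = "short", score = rep(base, 2))
  expect_equal(interrater_icc(tab)$icc, 1, tolerance = 1e-12)

  # independent oracle: two-way ANOVA mean squares via aov
  set.seed(3)
  long <- tidyr::expand_grid(target_id = paste0("t", 1:15),
                             rater_id = paste0("r", 1:6))
  long$item <- "short"
  long$score <- rnorm(15)[as.integer(factor(long$target_id))] +
    rnorm(6, 0, 0.5)[as.integer(factor(long$rater_id))] + rnorm(nrow(long))
  fit <- summary(stats::aov(score ~ factor(target_id) + factor(rater_id),
                            data = long))[[1]]
  msr <- fit["factor(target_id)", "Mean Sq"]
  mse <- fit["Residuals", "Mean Sq"]
  expect_equal(interrater_icc(long)$icc, (msr - mse) / msr, tolerance = 1e-10)

  expect_error(interrater_icc(tab[tab$rater_id == "r1", ]), "two")
})

test_that("ICC recovers the variance-component ratio on simulated ratings", {
  tau2 <- 1; sig2 <- 2; k <- 8; n <- 300
  expected <- tau2 / (tau2 + sig2 / k)  # ICC(3,k)
  set.seed(11)
  reps <- replicate(15, {
    long <- tidyr::expand_grid(target_id = sprintf("t%03d", 1:n),
                               rater_id = paste0("r", 1:k))
    long$item <- "short"
    long$score <- sqrt(tau2) * rnorm(n)[as.integer(factor(long$target_id))] +
      rnorm(nrow(long), 0, sqrt(sig2))
    interrater_icc(long)$icc
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 0.002)
})

test_that("pearson_cor matches hand values and a brute-force formula", {
  expect_equal(pearson_cor(x = 1:10, y = 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))$r, 0.8,
               tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    res <- pearson_cor(x = x, y = y)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_brute, tolerance = 1e-12)
  }

  # orthogonalized data: r = 0, p = 1
  x <- rnorm(30)
  y <- rnorm(30)
  y <- residuals(lm(y ~ x))
  expect_equal(pearson_cor(x = x, y = y)$p, 1, tolerance = 1e-6)

  expect_error(pearson_cor(x = 1:10, y = rep(1, 10)), "variance")
  expect_error(pearson_cor(x = 1:3, y = c(2, 1, 3)), "more than 3")
})

test_that("summary-statistic t-test matches the t distribution and handles ties", {
  same <- two_sample_t(1, 1, 20, 1, 1, 25)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)

  # p agrees with the t distribution at the pooled df
  gc <- two_sample_t(0.4, 1.1, 18, -0.2, 0.9, 22)
  expect_equal(gc$p, 2 * pt(-abs(gc$t), 18 + 22 - 2), tolerance = 1e-12)

  w <- two_sample_t(0.4, 1.1, 18, -0.2, 0.9, 22, variant = "welch")
  expect_lt(w$df, 38)
  expect_error(two_sample_t(0, 0, 10, 1, 1, 10), "positive")
})

test_that("standardized OLS recovers identities and nulls", {
  set.seed(6)
  d <- tibble::tibble(x = rnorm(40))
  d$y <- d$x
  fit <- ols_standardized(d, "y", "x")
  expect_equal(unname(fit$coefficients$beta), 1, tolerance = 1e-12)

  # beta of an orthogonal predictor equals its simple correlation
  x1 <- rnorm(200); x2 <- residuals(lm(rnorm(200) ~ x1))
  y <- 0.5 * x1 + 0.3 * x2 + rnorm(200)
  d2 <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  fit2 <- ols_standardized(d2, "y", c("x1", "x2"))
  expect_equal(unname(fit2$coefficients$beta[fit2$coefficients$term == "x1"]),
               pearson_cor(x = y, y = x1)$r, tolerance = 1e-10)

  # independent noise predictor: beta within 3 SE of zero
  set.seed(7)
  d3 <- tibble::tibble(y = rnorm(500), x = rnorm(500))
  fit3 <- ols_standardized(d3, "y", "x")
  expect_lt(abs(fit3$coefficients$beta), 3 * fit3$coefficients$se)

  expect_error(ols_standardized(tibble::tibble(y = rnorm(10), x = rnorm(10),
                                               x2 = NA_real_),
                                "y", c("x", "x2")), "complete")
})

test_that("equivalence test matches its closed form, the worked example, and antisymmetry", {
  # r equal to the bound: z = 0, p = 0.5
  at_bound <- equivalence_test_r(-0.2, 100, -0.2)
  expect_equal(at_bound$p, 0.5, tolerance = 1e-12)

  # independent normal-CDF oracle via the complementary error function
  ex <- equivalence_test_r(0.13, 130, -0.06, bound_kind = "conservative")
  z <- (atanh(0.13) - atanh(-0.06)) * sqrt(130 - 3)
  expect_equal(ex$z, z, tolerance = 1e-12)
  expect_equal(ex$p, 0.5 * pracma::erfc(z / sqrt(2)), tolerance = 1e-9)
  expect_equal(round(ex$p, 2), 0.02)

  # antisymmetry: swapping r and bound maps p to 1 - p
  set.seed(8)
  for (i in 1:10) {
    r <- runif(1, -0.5, 0.5); b <- runif(1, -0.5, 0.5); n <- sample(10:200, 1)
    expect_equal(equivalence_test_r(r, n, b)$p,
                 1 - equivalence_test_r(b, n, r)$p, tolerance = 1e-12)
  }

  expect_error(equivalence_test_r(1, 100, -0.2), "< 1")
  expect_error(equivalence_test_r(0.1, 3, -0.2), "n > 3")
})

test_that("TOST reports the larger one-sided p", {
  res <- equivalence_tost_r(0.05, 150, -0.2, 0.2)
  expect_equal(res$p_tost, max(res$p_lower, res$p_upper))
  expect_lt(res$p_tost, 0.05)
  one <- equivalence_test_r(0.05, 150, -0.2)
  expect_equal(res$p_lower, one$p, tolerance = 1e-12)
})

test_that("correlation_table covers all pairs pairwise-complete", {
  set.seed(9)
  d <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  d$b[1:3] <- NA
  ct <- correlation_table(d)
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$n[ct$var1 == "a" & ct$var2 == "b"], 27L)
  expect_equal(ct$n[ct$var1 == "a" & ct$var2 == "c"], 30L)
})
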