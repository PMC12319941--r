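test_that("paired t matches the hand formula and tail conventions", {
  x <- c(2, 4, 6, 9)
  y <- c(1, 2, 3, 5)
  d <- x - y  # 1, 2, 3, 4
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  two <- paired_t(x, y, tails = 2)
  expect_equal(two$t, t_hand, tolerance = 1e-12)
  expect_equal(two$df, 3)
  expect_equal(two$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  one <- paired_t(x, y, tails = 1, direction = "greater")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)  # predicted side
  # x = y: trivial zero statistic
  same <- paired_t(y, y, tails = 2)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate constant nonzero difference
  expect_error(paired_t(y + 1, y), "zero variance")
  expect_error(paired_t(1:4, 1:3), "equal length")
  expect_error(paired_t(1:2, 2:3), "at least 3")
  td <- tidy(two)
  expect_equal(td$statistic, t_hand)
  expect_equal(glance(two)$n, 4)
})

test_that("paired t rejects at the nominal rate under the null", {
  set.seed(314)
  p <- vapply(1:2000, function(i) {
    paired_t(rnorm(16), rnorm(16), tails = 2)$p
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("Greenhouse-Geisser epsilon matches the classical formula", {
  # two-level factors are spherical by construction
  set.seed(8)
  expect_equal(gg_epsilon(matrix(rnorm(20), 10, 2)), 1)
  # compound symmetry: epsilon = 1
  cs <- matrix(0.3, 4, 4); diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1, tolerance = 1e-12)
  # arbitrary covariance vs the elementwise textbook formula
  for (i in 1:10) {
    X <- matrix(rnorm(45), 15, 3)
    S <- cov(X)
    k <- 3
    sbar_d <- mean(diag(S))
    sbar <- mean(S)
    row_m <- rowMeans(S)
    eps_oracle <- (k * (sbar_d - sbar))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(row_m^2) + k^2 * sbar^2))
    expect_equal(gg_epsilon(S), eps_oracle, tolerance = 1e-10)
    expect_equal(gg_epsilon(X), eps_oracle, tolerance = 1e-10)
    expect_gt(gg_epsilon(S), 1 / (k - 1))
    expect_lte(gg_epsilon(S), 1)
  }
  expect_error(gg_epsilon(matrix(1, 1, 1)), "2 levels")
})

test_that("the repeated-measures ANOVA matches base aov as oracle", {
  set.seed(33)
  for (i in 1:5) {
    d <- expand.grid(subject = factor(1:8), a = factor(1:3), b = factor(1:2))
    d$value <- rnorm(nrow(d)) + as.numeric(d$a) * 0.3
    res <- rm_anova_2way(d, dv = "value", subject = "subject",
                         a = "a", b = "b")
    fit <- summary(aov(value ~ a * b + Error(subject / (a * b)), data = d))
    f_a <- fit[["Error: subject:a"]][[1]]["a", "F value"]
    f_b <- fit[["Error: subject:b"]][[1]]["b", "F value"]
    f_ab <- fit[["Error: subject:a:b"]][[1]]["a:b", "F value"]
    expect_equal(res$F, c(f_a, f_b, f_ab), tolerance = 1e-8)
    expect_equal(res$df1, c(2, 1, 2))
    expect_equal(res$df2, c(14, 7, 14))
    # corrected dfs are the epsilon-deflated ones
    expect_equal(res$df1_gg, res$epsilon_gg * res$df1)
  }
})

test_that("degenerate ANOVA inputs behave as defined", {
  # constant across factor a: its effect is exactly zero
  d <- expand.grid(subject = factor(1:5), a = factor(1:3), b = factor(1:2))
  d$value <- as.numeric(d$b) + as.numeric(d$subject) / 10 +
    rnorm(nrow(d), 0, 0.1)
  d$value <- ave(d$value, d$subject, d$b)  # remove all a-variation
  res <- rm_anova_2way(d, dv = "value", subject = "subject", a = "a", b = "b")
  expect_equal(res$F[res$effect == "a"], 0)
  # additive noiseless data: interaction F = 0
  d2 <- expand.grid(subject = factor(1:5), a = factor(1:3), b = factor(1:2))
  d2$value <- as.numeric(d2$a) + 2 * as.numeric(d2$b)
  res2 <- rm_anova_2way(d2, dv = "value", subject = "subject",
                        a = "a", b = "b")
  expect_equal(res2$F[res2$effect == "a:b"], 0)
  # incomplete table errors with advice
  expect_error(rm_anova_2way(d2[-1, ], dv = "value", subject = "subject",
                             a = "a", b = "b"), "incomplete")
})

test_that("two-level ANOVA effects reproduce paired t exactly", {
  set.seed(44)
  d <- expand.grid(subject = factor(1:9), a = factor(1:2), b = factor(1:2))
  d$value <- rnorm(nrow(d))
  res <- rm_anova_2way(d, dv = "value", subject = "subject", a = "a", b = "b")
  # factor a main effect vs paired t on b-averaged values
  wide <- tapply(d$value, list(d$subject, d$a), mean)
  tt <- paired_t(wide[, 1], wide[, 2])
  a_row <- res[res$effect == "a", ]
  expect_equal(a_row$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a_row$p, tt$p, tolerance = 1e-10)
  expect_equal(a_row$epsilon_gg, 1)
})

test_that("the 2x2 interaction contrast equals t^2 on double differences", {
  set.seed(45)
  d <- expand.grid(subject = factor(1:7), a = factor(1:2), b = factor(1:2))
  d$value <- rnorm(nrow(d))
  res <- interaction_contrast_2x2(d, dv = "value", subject = "subject",
                                  a = "a", b = "b")
  cell <- tapply(d$value, list(d$subject, d$a, d$b), mean)
  dd <- (cell[, 1, 1] - cell[, 2, 1]) - (cell[, 1, 2] - cell[, 2, 2])
  tt <- paired_t(dd, rep(0, length(dd)))
  expect_equal(res$F, tt$t^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p, tolerance = 1e-10)
  # zero double differences: F = 0
  d0 <- d
  d0$value <- as.numeric(d0$a) + as.numeric(d0$b)
  expect_equal(interaction_contrast_2x2(d0, dv = "value",
                                        subject = "subject",
                                        a = "a", b = "b")$F, 0)
  # swapping factor-level labels leaves F unchanged
  d_swap <- d
  d_swap$a <- factor(ifelse(d$a == "1", "2", "1"))
  res_swap <- interaction_contrast_2x2(d_swap, dv = "value",
                                       subject = "subject", a = "a", b = "b")
  expect_equal(res_swap$F, res$F, tolerance = 1e-10)
  # subsetting from a larger design
  d3 <- expand.grid(subject = factor(1:7), a = factor(1:3), b = factor(1:2))
  d3$value <- rnorm(nrow(d3))
  sub <- interaction_contrast_2x2(d3, dv = "value", subject = "subject",
                                  a = "a", b = "b", levels_a = c("1", "3"))
  expect_equal(sub$df1, 1)
  expect_error(interaction_contrast_2x2(d3, dv = "value",
                                        subject = "subject", a = "a",
                                        b = "b"), "2 levels")
})

test_that("noncentral-t power is exact, monotone, and bounded", {
  # independent oracle: base power.t.test
  expect_equal(power_paired_t(16, 0.8),
               power.t.test(n = 16, delta = 0.8, sd = 1,
                            type = "paired")$power, tolerance = 1e-6)
  expect_equal(power_paired_t(10, 0.5, tails = 1),
               power.t.test(n = 10, delta = 0.5, sd = 1, type = "paired",
                            alternative = "one.sided")$power,
               tolerance = 1e-6)
  # d = 0: power equals alpha
  expect_equal(power_paired_t(12, 0, alpha = 0.05), 0.05, tolerance = 1e-9)
  # strictly increasing in n and d
  pn <- vapply(c(4, 8, 16, 32), power_paired_t, numeric(1), d = 0.5)
  expect_true(all(diff(pn) > 0))
  pd <- vapply(c(0.1, 0.4, 0.8, 1.5), function(d) power_paired_t(16, d),
               numeric(1))
  expect_true(all(diff(pd) > 0))
  expect_gt(power_paired_t(16, 10), 0.9999)
  expect_error(power_paired_t(16, 0.8, alpha = 1.2), "alpha")
})
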