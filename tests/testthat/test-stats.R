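test_that("one-way ANOVA matches a hand-computed decomposition", {
  g1 <- c(4, 6, 5); g2 <- c(7, 9, 8); g3 <- c(5, 5, 8)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 3)
  # manual sums of squares
  grand <- mean(vals)
  ssb <- 3 * ((mean(g1) - grand)^2 + (mean(g2) - grand)^2 +
                (mean(g3) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_manual <- (ssb / 2) / (ssw / 6)
  res <- one_way_anova(vals, grp)
  expect_equal(res$F, f_manual, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # cross-check against the standard linear-model ANOVA table
  lm_tab <- anova(lm(vals ~ grp))
  expect_equal(res$F, lm_tab$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, lm_tab$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("ANOVA handles symmetric and degenerate inputs", {
  expect_error(one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
  res <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(one_way_anova(1:4, rep("a", 4)), ">= 2 groups")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA F is shift-invariant and scale-invariant", {
  set.seed(4)
  vals <- rnorm(30); grp <- rep(letters[1:3], each = 10)
  f0 <- one_way_anova(vals, grp)$F
  expect_equal(one_way_anova(vals + 100, grp)$F, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(vals * 3.7, grp)$F, f0, tolerance = 1e-9)
})

test_that("Dunnett with one treatment group reduces to the pooled t-test", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(12) + 0.6
  dn <- dunnett_test(c(x, y), rep(c("ctrl", "trt"), c(8, 12)), "ctrl")
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(dn$adjusted_p, tt$p.value, tolerance = 1e-9)
  expect_equal(dn$t_statistic, unname(tt$statistic), tolerance = 1e-9)
})

test_that("treatment identical to control gives t = 0 and p = 1", {
  x <- c(1, 2, 3, 4)
  vals <- c(x, x, x + 2)
  grp <- rep(c("ctrl", "same", "shift"), each = 4)
  dn <- dunnett_test(vals, grp, "ctrl")
  same <- dn[dn$group == "same", ]
  expect_equal(same$t_statistic, 0)
  expect_equal(same$adjusted_p, 1, tolerance = 1e-9)
})

test_that("adjusted p dominates the unadjusted t p-value and grows with k", {
  set.seed(6)
  n <- 8
  ctrl <- rnorm(n)
  trts <- replicate(5, rnorm(n) + runif(1, 0, 1), simplify = FALSE)
  p_first <- vapply(1:5, function(k) {
    vals <- c(ctrl, unlist(trts[1:k]))
    grp <- rep(c("ctrl", paste0("t", 1:k)), each = n)
    dn <- dunnett_test(vals, grp, "ctrl")
    dn$adjusted_p[dn$group == "t1"]
  }, numeric(1))
  # monotone non-decreasing in the family size
  expect_true(all(diff(p_first) >= -1e-9))
  # each adjusted p >= its own two-sided t p (computed from pooled df)
  vals <- c(ctrl, unlist(trts))
  grp <- rep(c("ctrl", paste0("t", 1:5)), each = n)
  dn <- dunnett_test(vals, grp, "ctrl")
  p_unadj <- 2 * pt(abs(dn$t_statistic), dn$df, lower.tail = FALSE)
  expect_true(all(dn$adjusted_p >= p_unadj - 1e-9))
})

test_that("quadrature agrees with Monte Carlo and with multcomp", {
  skip_if_not_installed("multcomp")
  set.seed(7)
  n <- 7; k <- 3
  vals <- c(rnorm(n), rnorm(n) + 0.9, rnorm(n) - 0.2, rnorm(n) + 0.5)
  grp <- rep(c("ctrl", "a", "b", "c"), each = n)
  dn <- dunnett_test(vals, grp, "ctrl")
  # Monte-Carlo evaluation of the same joint null
  for (i in seq_len(nrow(dn))) {
    p_mc <- 1 - dunnett_prob_mc(abs(dn$t_statistic[i]), rep(n, k), n,
                                df = 4 * n - 4, nsim = 2e5, seed = 99)
    expect_lt(abs(dn$adjusted_p[i] - p_mc), 0.01)
  }
  # multcomp (mvtnorm-based) as an independent implementation
  d <- data.frame(y = vals, g = relevel(factor(grp), "ctrl"))
  mc <- summary(multcomp::glht(aov(y ~ g, d),
                               linfct = multcomp::mcp(g = "Dunnett")))
  p_mc2 <- as.numeric(mc$test$pvalues)
  ord <- match(dn$group, sub(" - ctrl", "", names(mc$test$coefficients)))
  expect_equal(dn$adjusted_p, p_mc2[ord], tolerance = 5e-3)
})

test_that("unbalanced designs use the exact correlation structure", {
  skip_if_not_installed("multcomp")
  set.seed(8)
  sizes <- c(ctrl = 12, a = 5, b = 9)
  vals <- c(rnorm(12), rnorm(5) + 0.8, rnorm(9) + 0.3)
  grp <- rep(names(sizes), sizes)
  dn <- dunnett_test(vals, grp, "ctrl")
  d <- data.frame(y = vals, g = relevel(factor(grp), "ctrl"))
  mc <- summary(multcomp::glht(aov(y ~ g, d),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(dn$adjusted_p,
               as.numeric(mc$test$pvalues)[match(dn$group, c("a", "b"))],
               tolerance = 5e-3)
})

test_that("error paths: control flags and degenerate variance", {
  expect_error(dunnett_test(1:6, rep(c("a", "b"), 3), "zz"), "not present")
  expect_error(dunnett_test(rep(1, 6), rep(c("a", "b"), 3), "a"),
               "zero pooled")
})

test_that("star binning uses the configured alpha ladder", {
  p <- c(0.2, 0.04, 0.009, 0.0009, 0.00009)
  expect_equal(significance_stars(p), c("", "*", "**", "***", "****"))
  expect_equal(significance_stars(0.04, alpha_levels = c(0.1, 0.01)), "*")
})
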