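test_that("one-way ANOVA handles identical, separated and random groups", {
  res <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  res2 <- one_way_anova(list(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(res2$statistic, Inf)
  expect_equal(res2$p.value, 0)
  withr::with_seed(3, {
    for (i in 1:10) {
      g <- list(rnorm(10), rnorm(10, 0.5), rnorm(10, 1))
      expect_equal(one_way_anova(g)$statistic, naive_anova_F(g), tolerance = 1e-10)
    }
  })
  expect_error(one_way_anova(list(1:3)), ">= 2")
  expect_error(one_way_anova(list(1, 2:3)), ">= 2 values")
})

test_that("ANOVA F is shift-invariant and scale-invariant", {
  withr::with_seed(5, {
    g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
    f0 <- one_way_anova(g)$statistic
    expect_equal(one_way_anova(lapply(g, `+`, 100))$statistic, f0)
    expect_equal(one_way_anova(lapply(g, `*`, 3.7))$statistic, f0)
  })
})

test_that("two-group Dunnett collapses to the pooled t test", {
  withr::with_seed(7, {
    x <- rnorm(12); y <- rnorm(10, 0.7)
    d <- dunnett_vs_control(list(x, y), control = 1, n_mc = 1e5, seed = 2)
    tt <- stats::t.test(y, x, var.equal = TRUE)
    expect_lt(abs(d$p_adj - tt$p.value), 0.005)
    expect_equal(d$p_raw, tt$p.value, tolerance = 1e-12)
  })
})

test_that("Dunnett adjusted p dominates the raw p and handles identical groups", {
  withr::with_seed(9, {
    g <- list(rnorm(8), rnorm(8, 0.3), rnorm(8, 0.8), rnorm(8))
    d <- dunnett_vs_control(g, n_mc = 2e4, seed = 3)
    expect_true(all(d$p_adj >= d$p_raw))
    same <- rep(list(c(1, 2, 3, 4)), 3)
    expect_gte(min(dunnett_vs_control(same, n_mc = 2000, seed = 1)$p_adj), 0.99)
  })
  expect_error(dunnett_vs_control(list(1:3, 4:6), n_mc = 500), "n_mc")
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
  skip_if_not_installed("multcomp")
  withr::with_seed(11, {
    v <- c(rnorm(10), rnorm(10, 0.6), rnorm(10, 1.1))
    g <- factor(rep(c("c", "a", "b"), each = 10), levels = c("c", "a", "b"))
    ref <- summary(multcomp::glht(stats::aov(v ~ g),
                                  linfct = multcomp::mcp(g = "Dunnett")))
    mine <- dunnett_vs_control(split(v, g), control = 1, n_mc = 2e5, seed = 4)
    expect_equal(mine$p_adj, as.numeric(ref$test$pvalues), tolerance = 0.01)
  })
})

test_that("Bonferroni adjustment multiplies and caps", {
  g <- list(c(1.1, 1.9, 3.2), c(1.0, 2.1, 2.9), c(5.1, 6.0, 7.2))
  one <- bonferroni_pairs(g, list(c(1, 2)))
  expect_equal(one$p_adj, one$p_raw)
  three <- bonferroni_pairs(g, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(three$p_adj, pmin(1, 3 * three$p_raw))
  expect_error(bonferroni_pairs(g, list(c(1, 1))), "distinct")
})

test_that("ROC curves hit the closed-form extremes and tie handling", {
  perfect <- roc_curve(c(4, 5, 6), c(1, 2, 3))
  expect_equal(perfect$auc, 1)
  expect_equal(roc_curve(c(2, 4), c(1, 3))$auc, 0.75)
  expect_equal(roc_curve(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  op <- perfect$operating_points
  expect_equal(op[1, ], data.frame(sensitivity = 0, one_minus_specificity = 0))
  expect_equal(unlist(op[nrow(op), ], use.names = FALSE), c(1, 1))
  expect_error(roc_curve(numeric(0), 1:3), "at least one")
})

test_that("AUC equals the all-pairs oracle and flips with direction", {
  withr::with_seed(13, {
    for (i in 1:20) {
      pos <- round(rnorm(sample(3:15, 1)), 1)   # rounding forces ties
      neg <- round(rnorm(sample(3:15, 1)), 1)
      a <- roc_curve(pos, neg)$auc
      expect_equal(a, naive_auc(pos, neg), tolerance = 1e-12)
      b <- roc_curve(neg, pos)$auc
      expect_equal(a + b, 1, tolerance = 1e-12)
      expect_equal(roc_curve(pos, neg, "lesser_is_positive")$auc, 1 - a,
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    for (i in 1:5) {
      pos <- rnorm(10, 1); neg <- rnorm(12)
      ref <- pROC::auc(pROC::roc(
        response = c(rep(1, 10), rep(0, 12)), predictor = c(pos, neg),
        direction = "<", quiet = TRUE))
      expect_equal(roc_curve(pos, neg)$auc, as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("accuracy bands use left-closed right-open intervals", {
  expect_equal(as.character(classify_auc(c(0.55, 0.6, 0.65, 0.7, 0.75,
                                           0.8, 0.85, 0.9, 0.97))),
               c("no_value", "poor", "poor", "fair", "fair",
                 "good", "good", "excellent", "excellent"))
  b <- classify_auc(c(0.62, 0.95))
  expect_true(b[2] > b[1])                 # ordered factor
  expect_error(classify_auc(1.2), "\\[0, 1\\]")
})
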