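# Statistical battery: frozen oracle values and distributional checks.

test_that("assumption gate returns Shapiro/Bartlett p-values and flags", {
  withr::with_seed(1, {
    g <- replicate(3, stats::rnorm(30), simplify = FALSE)
  })
  gate <- gate_assumptions(g)
  expect_length(gate$shapiro_p, 3L)
  expect_equal(gate$shapiro_p[[1]], stats::shapiro.test(g[[1]])$p.value)
  expect_equal(gate$bartlett_p, stats::bartlett.test(g)$p.value)
  expect_error(gate_assumptions(list(rep(1, 10), stats::rnorm(10))),
               "constant group")
  expect_error(gate_assumptions(list(1:2, stats::rnorm(10))), ">= 3")
})

test_that("assumption gate behaves under H0 and H1 (simulation)", {
  res <- withr::with_seed(99, vapply(1:100, function(i) {
    g0 <- replicate(3, stats::rnorm(50), simplify = FALSE)
    g1 <- list(stats::rnorm(50), stats::rnorm(50), stats::rnorm(50, 0, sqrt(10)))
    c(gate_assumptions(g0)$bartlett_p, gate_assumptions(g1)$bartlett_p)
  }, numeric(2)))
  expect_gte(mean(res[1, ] > 0.05), 0.90)   # equal variances: mostly pass
  expect_gte(mean(res[2, ] < 0.05), 0.90)   # 10x variance: mostly flagged
})

test_that("Kruskal-Wallis matches the hand-rank formula and base R", {
  # {1,2,3},{4,5,6},{7,8,9}: mean ranks 2,5,8 ->
  # H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(unname(kw$statistic), 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kruskal_wallis(list(rep(1, 3), rep(1, 3), rep(1, 3)))$statistic,
               c(H = 0))
  withr::with_seed(3, {
    for (i in 1:10) {
      g <- replicate(sample(3:5, 1),
                     sample(0:5, sample(4:9, 1), replace = TRUE),
                     simplify = FALSE)                      # heavy ties
      ref <- stats::kruskal.test(g)
      kw2 <- kruskal_wallis(g)
      expect_equal(unname(kw2$statistic), unname(ref$statistic))
      expect_equal(kw2$p_value, ref$p.value)
    }
  })
})

test_that("H is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    g <- replicate(4, stats::rnorm(8), simplify = FALSE)
  })
  h0 <- kruskal_wallis(g)$statistic
  expect_identical(kruskal_wallis(lapply(g, exp))$statistic, h0)
  expect_identical(kruskal_wallis(lapply(g, function(v) v^3))$statistic, h0)
})

test_that("rank-sum: exact tail enumeration, ties, and approximation", {
  # exhaustive oracle: all 20 assignments of {1..6} into two triples
  combos <- utils::combn(6, 3)
  obs <- sum(1:3)
  tail_lo <- mean(apply(combos, 2, sum) <= obs)
  expect_equal(2 * tail_lo, 0.1)
  expect_equal(ranksum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(ranksum(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)
  expect_equal(ranksum(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  withr::with_seed(7, {
    x <- stats::rnorm(10); y <- stats::rnorm(10, 0.8)
  })
  expect_equal(ranksum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # exact vs normal approximation at combined n = 20
  approx_p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(ranksum(x, y)$p_value - approx_p), 0.01)
})

test_that("post hoc tables have the right shape and corrections", {
  withr::with_seed(8, {
    g <- list(a = stats::rnorm(10), b = stats::rnorm(10),
              c = stats::rnorm(10), d = stats::rnorm(10, 3))
  })
  ph <- posthoc_pairwise(g)
  expect_equal(nrow(ph), 6L)                     # 4 choose 2
  expect_equal(ph$adjusted_p, pmin(1, ph$p * 6))
  expect_equal(posthoc_pairwise(list(a = rep(2, 4), b = rep(2, 4)))$adjusted_p,
               1)
  # no rank overlap at n = 10: exact two-sided p = 2/choose(20,10)
  sep <- posthoc_pairwise(list(a = 1:10, b = 21:30))
  expect_equal(sep$p, 2 / choose(20, 10))
  tk <- posthoc_pairwise(g, "tukey_on_ranks")
  expect_equal(nrow(tk), 6L)
  expect_true(all(tk$p >= 0 & tk$p <= 1))
  # the clearly separated pair should be significant under both methods
  expect_lt(tk$p[tk$pair == "a-d"], 0.05)
})

test_that("ART alignment matches a hand cell-means oracle and lm on ranks", {
  withr::with_seed(10, {
    a <- gl(2, 6); b <- gl(3, 2, 12); y <- stats::rnorm(12)
  })
  art <- art_anova(y, a, b)
  mu <- mean(y)
  cm <- stats::ave(y, a, b); ma <- stats::ave(y, a); mb <- stats::ave(y, b)
  res <- y - cm
  aligned <- list("A" = res + ma - mu, "B" = res + mb - mu,
                  "A:B" = res + cm - ma - mb + mu)
  for (nm in names(aligned)) {
    expect_lt(abs(sum(aligned[[nm]])), 1e-9)     # alignment identity
    r <- rank(aligned[[nm]])
    an <- stats::anova(stats::lm(r ~ a * b))
    row <- switch(nm, "A" = "a", "B" = "b", "A:B" = "a:b")
    expect_equal(unname(art[[nm]]$statistic),
                 an[row, "F value"], tolerance = 1e-9)
    expect_equal(art[[nm]]$p_value, an[row, "Pr(>F)"], tolerance = 1e-9)
  }
  expect_equal(unname(art[["A"]]$df), c(1L, 6L))
  expect_equal(unname(art[["A:B"]]$df), c(2L, 6L))
})

test_that("ART rejects malformed designs", {
  a <- gl(2, 4)
  expect_error(art_anova(stats::rnorm(8), a,
                         factor(c(1, 2, 1, 2, 1, 2, 1, 1))), "balanced")
  expect_error(art_anova(stats::rnorm(4), gl(2, 2), gl(2, 2)), "empty cell")
  expect_error(art_anova(stats::rnorm(4), gl(2, 2), gl(2, 1, 4)),
               ">= 2 observations")
})

test_that("Bland-Altman bias, limits, and proportional-bias probe", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$slope, 0)
  ba1 <- bland_altman(x, x - 0.3)
  expect_equal(ba1$bias, 0.3)
  expect_equal(ba1$slope, 0)
  # m2 = 0.9 m1: differences 0.1 m1 on means 0.95 m1 -> slope 0.1/0.95
  ba2 <- bland_altman(x, 0.9 * x)
  expect_equal(ba2$slope, 0.1 / 0.95, tolerance = 1e-12)
  expect_true(ba2$loa_low <= ba2$bias && ba2$bias <= ba2$loa_high)
})

test_that("ICC(A,1) matches the two-way mean-squares oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  got <- icc_agreement(a, b)
  # oracle: mean squares from an explicit two-way ANOVA decomposition
  y <- c(a, b)
  subj <- factor(rep(1:6, 2)); rater <- factor(rep(1:2, each = 6))
  an <- stats::anova(stats::lm(y ~ subj + rater))
  msr <- an["subj", "Mean Sq"]; msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  icc_ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(got$icc, icc_ref, tolerance = 1e-12)
  expect_equal(icc_agreement(a, a)$icc, 1)
  # absolute agreement penalizes a constant offset relative to consistency
  off <- icc_agreement(a, a + 5)
  expect_lt(off$icc, 1)
  expect_true(icc_agreement(rep(3, 5), rep(3, 5))$undefined)
})

test_that("Bonferroni caps at one and preserves order", {
  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.5, 4), 1.0)
  expect_equal(bonferroni(c(0.04, 0.001, 0.2), 3), c(0.12, 0.003, 0.6))
  expect_error(bonferroni(c(0.1, 0.2), 1), "m must be")
})

test_that("summary table reports mean, SD, CV and flags tiny groups", {
  tab <- data.frame(species = "m", tissue = c("x", "x", "x", "y"),
                    value = c(0.2, 0.3, 0.4, 1))
  s <- build_summary(tab)
  expect_equal(s$mean[s$tissue == "x"], 0.3)
  expect_equal(s$sd[s$tissue == "x"], 0.1)
  expect_true(is.na(s$sd[s$tissue == "y"]))
  # mouse PCL preset: mean 0.041, SD 0.015 -> CV 36.59% -> 37%
  withr::with_seed(2, {
    v <- stats::rnorm(10)
  })
  v <- (v - mean(v)) / stats::sd(v) * 0.015 + 0.041
  s2 <- build_summary(data.frame(species = "mouse", tissue = "PCL", value = v))
  expect_equal(round(s2$cv_pct), 37)
  tab$value[4] <- NA
  expect_warning(s3 <- build_summary(tab), "empty group")
  expect_equal(nrow(s3), 1L)
})
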