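test_that("ComBat removes constructed site effects, preserves group effects", {
  set.seed(91)
  n <- 60; p <- 4
  site <- rep(c("A", "B"), each = n / 2)
  group <- rep(c(1, 0), n / 2)           # balanced across sites
  x <- matrix(rnorm(n * p), n, p)
  x[site == "B", ] <- x[site == "B", ] + 5          # additive site shift
  x <- x + outer(group, rep(1, p))                  # +1 group effect

  fit <- combat_fit_apply(x, site, covariates = cbind(group = group))
  h <- fit$harmonized

  site_diff_raw <- colMeans(x[site == "B", ]) - colMeans(x[site == "A", ])
  site_diff_adj <- colMeans(h[site == "B", ]) - colMeans(h[site == "A", ])
  expect_true(all(abs(site_diff_adj) < 0.1 * abs(site_diff_raw)))  # >90% removed

  # the retained +1 group effect is preserved: harmonization moves the
  # estimated group difference by < 10% of the constructed effect size
  # (the estimate itself carries sampling noise of ~0.26 at this n)
  grp_raw <- colMeans(x[group == 1, ]) - colMeans(x[group == 0, ])
  grp_adj <- colMeans(h[group == 1, ]) - colMeans(h[group == 0, ])
  expect_true(all(abs(grp_adj - grp_raw) < 0.1)) # 10% of the +1 effect

  # between-site F statistic decreases on the model's own training data
  fstat <- function(v, s) summary(stats::aov(v ~ factor(s)))[[1]][["F value"]][1]
  expect_true(all(vapply(seq_len(p), function(j)
    fstat(h[, j], site) < fstat(x[, j], site), logical(1))))
  expect_true(all(fit$model$delta_star > 0))
})

test_that("ComBat is a no-op for one site and near-no-op without site effects", {
  set.seed(92)
  x <- matrix(rnorm(80), 20, 4)
  one <- combat_fit_apply(x, rep("s1", 20))
  expect_identical(one$harmonized, x)

  # null safety: no true site effect => changes small relative to feature SD
  site <- rep(c("A", "B"), 10)
  h <- combat_fit_apply(x, site)$harmonized
  rel <- mean(abs(h - x)) / mean(apply(x, 2, sd))
  expect_lt(rel, 0.5)

  expect_error(combat_fit_apply(x, c(rep("A", 19), "lonely")), "lonely")
  expect_error(
    combat_fit_apply(x, site, covariates = cbind(g = as.numeric(site == "A"))),
    "rank deficient")
})

test_that("pooled t test: hand cases, df arithmetic, uniform null p", {
  set.seed(93)
  x <- rnorm(10)
  cmp <- two_sample_t(x, x)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)

  cmp2 <- two_sample_t(rnorm(211), rnorm(210))
  expect_identical(cmp2$df, 419L)

  # matches stats::t.test with var.equal
  a <- rnorm(14); b <- rnorm(9, 0.3)
  ref <- t.test(a, b, var.equal = TRUE)
  cmp3 <- two_sample_t(a, b)
  expect_equal(cmp3$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp3$p_value, ref$p.value, tolerance = 1e-12)

  # null p values are uniform (KS over replicates)
  ps <- vapply(1:500, function(i)
    two_sample_t(rnorm(12), rnorm(12))$p_value, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-3)

  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("Cohen's d and CI reproduce published-style worked values", {
  d_ttd <- cohens_d_ci(5.96, 0.55, 211, 4.95, 0.42, 210)
  expect_equal(d_ttd$d, 2.066, tolerance = 0.005)
  d_bc <- cohens_d_ci(31.79, 25.63, 211, 44.44, 37.90, 210)
  expect_equal(d_bc$d, -0.391, tolerance = 0.005)
  expect_equal(d_bc$ci95, c(-0.584, -0.198), tolerance = 0.01)

  d0 <- cohens_d_ci(3, 1, 20, 3, 1, 20)
  expect_equal(d0$d, 0)
  expect_equal(d0$ci95[1], -d0$ci95[2])
  expect_error(cohens_d_ci(1, 0, 10, 2, 0, 10), "standard deviations")
})

test_that("chi-square equals the O/E definition and handles degenerate input", {
  expect_equal(chi_square_test(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_test(matrix(10, 2, 2))$p_value, 1)
  expect_identical(chi_square_test(matrix(1:6, 2, 3))$df, 2L)

  set.seed(94)
  for (rep in 1:20) {
    o <- matrix(rpois(6, 20) + 1, 2, 3)
    got <- chi_square_test(o)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(got$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(o, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("BH-FDR matches the hand step-up and brute-force rejection rule", {
  got <- fdr_bh(c(0.005, 0.03, 0.04))
  expect_equal(got$adjusted, c(0.015, 0.04, 0.04))

  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)

  set.seed(95)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))^2
    got <- fdr_bh(p, alpha = 0.05)
    m <- length(p)
    ps <- sort(p)
    kmax <- suppressWarnings(max(which(ps <= seq_len(m) * 0.05 / m)))
    ref_reject <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
    expect_identical(got$reject, ref_reject)
    expect_equal(got$adjusted, p.adjust(p, "BH"))
    # adjusted p monotone in raw-p rank
    expect_true(all(diff(got$adjusted[order(p)]) >= -1e-15))
  }
})

test_that("Spearman correlation handles ties via average ranks", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)

  set.seed(96)
  x <- sample(1:5, 40, replace = TRUE)   # heavy ties
  y <- x + sample(0:2, 40, replace = TRUE)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(got$rho,
               unname(suppressWarnings(
                 cor.test(x, y, method = "spearman")$estimate)),
               tolerance = 1e-12)
  n <- 40
  tref <- got$rho * sqrt((n - 2) / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tref), n - 2))
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
})

test_that("group_comparison_table harmonizes, tests and adjusts per metric", {
  set.seed(97)
  n <- 40
  grp <- rep(c("SCD", "HC"), n / 2)
  site <- rep(c(1, 1, 2, 2), n / 4)
  m <- data.frame(a = rnorm(n) + (grp == "SCD") * 2,
                  b = rnorm(n),
                  const = rep(1, n))
  tab <- group_comparison_table(m, factor(grp, c("SCD", "HC")), site = site)
  expect_identical(tab$metric, c("a", "b"))  # constant column dropped
  expect_lt(tab$p[tab$metric == "a"], 0.01)
  expect_identical(tab$df, rep(as.integer(n) - 2L, 2))
  expect_true(all(c("p_fdr", "significant") %in% names(tab)))
  expect_gt(tab$cohens_d[1], 0)  # group A = SCD is larger
})
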