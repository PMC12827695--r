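test_that("global metrics match hand values on canonical graphs", {
  k4 <- 1 - diag(4)
  gm <- global_metrics(k4)
  expect_equal(gm$Cp, 1); expect_equal(gm$Lp, 1)
  expect_equal(gm$Eglob, 1); expect_equal(gm$Eloc, 1)
  expect_equal(gm$Lp, 1 / gm$Eglob)  # harmonic calibration on K_n only

  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  gm <- global_metrics(p4)
  expect_equal(gm$Lp, 10 / 6)
  expect_equal(gm$Eglob, (1 + 0.5 + 1 / 3 + 1 + 0.5 + 1) / 6)

  star <- matrix(0, 3, 3); star[1, 2:3] <- 1; star <- star + t(star)
  expect_equal(global_metrics(star)$Cp, 0)

  expect_warning(gm0 <- global_metrics(matrix(0, 3, 3)), "empty")
  expect_equal(gm0$Eglob, 0)
})

test_that("nodal metrics match enumeration on canonical graphs", {
  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  nm <- nodal_metrics(p4)
  expect_equal(nm$Bc, c(0, 2, 2, 0))
  expect_equal(nm$Dc, c(1, 2, 2, 1))

  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1; star4 <- star4 + t(star4)
  nm <- nodal_metrics(star4)
  expect_equal(nm$Bc[1], 3)   # all three leaf pairs route via the hub
  expect_equal(nm$Dc[1], 3)

  iso <- matrix(0, 4, 4); iso[2, 3] <- iso[3, 2] <- 1
  nm <- nodal_metrics(iso)
  expect_equal(nm$Ne[1], 0); expect_equal(nm$Dc[1], 0); expect_equal(nm$Bc[1], 0)
})

test_that("all metrics equal brute-force oracles on random small graphs", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.8))
    if (sum(a) == 0) next
    ref <- bf_global(a)
    gm <- global_metrics(a)
    expect_equal(gm$Cp, ref$Cp, tolerance = 1e-12)
    expect_equal(gm$Lp, ref$Lp, tolerance = 1e-12)
    expect_equal(gm$Eglob, ref$Eglob, tolerance = 1e-12)
    expect_equal(gm$Eloc, ref$Eloc, tolerance = 1e-12)
    nm <- nodal_metrics(a)
    expect_equal(nm$Bc, bf_betweenness(a), tolerance = 1e-10)
    expect_equal(nm$Ne, ref$Ne, tolerance = 1e-12)
    expect_equal(nm$Dc, rowSums(a))
  }
})

test_that("global efficiency is monotone under edge addition (nested graphs)", {
  set.seed(72)
  fc <- matrix(rnorm(100), 10, 10); fc <- (fc + t(fc)) / 2; diag(fc) <- 0
  gs <- threshold_proportional(fc)
  eg <- vapply(gs$graphs, function(a)
    suppressWarnings(global_metrics(a)$Eglob), numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("rewired nulls preserve degree sequences; self-null normalizes to 1", {
  set.seed(73)
  for (rep in 1:10) {
    a <- random_adjacency(10, 0.4)
    if (sum(a) < 4) next
    b <- edgedyn:::rewire_degree_preserving(a, n_swaps = 10 * sum(a) / 2)
    expect_identical(rowSums(b), rowSums(a))
    expect_true(all(diag(b) == 0))
    expect_true(all(b %in% c(0L, 1L)))
  }

  # star: no legal swap exists, so nulls equal the original graph
  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1; star4 <- star4 + t(star4)
  sw <- suppressWarnings(null_normalize(star4, n_nulls = 3, seed = 1))
  expect_equal(sw$gamma, 1); expect_equal(sw$lambda, 1); expect_equal(sw$sigma, 1)

  # sigma is exactly gamma/lambda as stored
  a <- random_adjacency(12, 0.4)
  sw2 <- null_normalize(a, n_nulls = 5, rewires_per_edge = 5, seed = 4)
  expect_identical(sw2$sigma, sw2$gamma / sw2$lambda)

  # ring lattice clusters far above degree-matched randomizations
  rl <- ring_lattice(50, 4)
  swl <- null_normalize(rl, n_nulls = 20, rewires_per_edge = 10, seed = 5)
  expect_gt(swl$gamma, 1.5)

  # determinism under a fixed seed
  s1 <- null_normalize(a, n_nulls = 4, seed = 9)
  s2 <- null_normalize(a, n_nulls = 4, seed = 9)
  expect_identical(s1, s2)
})

test_that("AUC over the grid is the trapezoidal integral", {
  expect_equal(auc_over_grid(rep(2, 5), seq(0, 1, 0.25)), 2)
  expect_equal(auc_over_grid(c(0, 1), c(0, 1)), 0.5)
  set.seed(74)
  v <- rnorm(10); g <- sort(runif(10))
  ref <- sum(vapply(1:9, function(i)
    (g[i + 1] - g[i]) * (v[i] + v[i + 1]) / 2, numeric(1)))
  expect_equal(auc_over_grid(v, g), ref)
  expect_error(auc_over_grid(1:3, 1:4), "length")
})

test_that("metric_table assembles per-sparsity rows plus AUC summaries", {
  set.seed(75)
  fc <- matrix(rnorm(64), 8, 8); fc <- (fc + t(fc)) / 2; diag(fc) <- 0
  gs <- threshold_proportional(fc, c(0.2, 0.3, 0.4))
  mt <- suppressWarnings(metric_table(gs, n_nulls = 2, seed = 3))
  expect_identical(nrow(mt$global), 4L)            # 3 sparsities + AUC
  expect_identical(sum(mt$global$summary == "AUC"), 1L)
  auc_cp <- mt$global$Cp[mt$global$summary == "AUC"]
  expect_equal(auc_cp, auc_over_grid(mt$global$Cp[1:3], c(0.2, 0.3, 0.4)))
  expect_identical(nrow(mt$nodal), 8L * 3L + 8L)   # per-S rows + AUC per node
})
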