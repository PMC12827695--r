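test_that("zscore standardizes rows with sample SD and rejects degenerate input", {
  x <- matrix(c(1, 2, 3,
                5, 7, 9), 2, 3, byrow = TRUE)
  z <- zscore_series(roi_time_series(x, roi_labels = c("a", "b")))
  expect_equal(z$data[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z$data[2, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_identical(z$dof_convention, "sample (T-1)")

  set.seed(11)
  z2 <- zscore_series(matrix(rnorm(200), 4, 50))
  expect_lt(max(abs(rowMeans(z2$data))), 1e-10)
  expect_lt(max(abs(apply(z2$data, 1, sd) - 1)), 1e-8)

  bad <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE)
  expect_error(roi_time_series(bad, roi_labels = c("flat", "ok")), "flat")
})

test_that("edge time series are z-products in canonical lexicographic order", {
  # raw rows [1,2,3] and [3,2,1] z-score to [-1,0,1] and [1,0,-1]
  x <- matrix(c(1, 2, 3,
                3, 2, 1,
                1, 2, 3), 3, 3, byrow = TRUE)
  ets <- compute_ets(roi_time_series(x))
  expect_identical(ets$edge_index, cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  expect_equal(ets$data[1, ], c(-1, 0, -1), ignore_attr = TRUE)  # anti-phase
  expect_equal(ets$data[2, ], c(1, 0, 1), ignore_attr = TRUE)    # in-phase
  # time-mean times T/(T-1) recovers r = -1 and +1
  expect_equal(mean(ets$data[1, ]) * 3 / 2, -1)
  expect_equal(mean(ets$data[2, ]) * 3 / 2, 1)

  ets2 <- compute_ets(matrix(rnorm(20), 2, 10))
  expect_identical(nrow(ets2$data), 1L)
})

test_that("edge_index enumerates all unordered pairs exactly once", {
  for (n in c(2L, 3L, 5L, 9L)) {
    idx <- edge_index(n)
    expect_identical(nrow(idx), (n * (n - 1L)) %/% 2L)
    expect_true(all(idx[, 1] < idx[, 2]))
    expect_false(anyDuplicated(paste(idx[, 1], idx[, 2])) > 0)
    # lexicographic order
    expect_true(all(diff(idx[, 1] * (n + 1) + idx[, 2]) > 0))
  }
})

test_that("Pearson identity holds for every pair on random data", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:8, 1); t_n <- sample(10:60, 1)
    x <- matrix(rnorm(n * t_n), n, t_n)
    ets <- compute_ets(roi_time_series(x))
    r_ets <- rowMeans(ets$data) * t_n / (t_n - 1)
    r_ref <- cor(t(x))[ets$edge_index]
    expect_lt(max(abs(r_ets - r_ref)), 1e-10)
  }
})

test_that("eFC matrix matches brute force and normalizes to [-1, 1]", {
  set.seed(31)
  x <- matrix(rnorm(15), 3, 5)
  ets <- compute_ets(roi_time_series(x))
  efc_raw <- compute_efc(ets, normalize = FALSE)
  ref <- matrix(NA_real_, 3, 3)
  for (u in 1:3) for (v in 1:3) ref[u, v] <- sum(ets$data[u, ] * ets$data[v, ])
  expect_equal(efc_raw$data, ref, ignore_attr = TRUE)

  efc <- compute_efc(ets)
  expect_true(all(abs(efc$data) <= 1 + 1e-12))
  expect_equal(diag(efc$data), rep(1, 3), ignore_attr = TRUE)
  expect_equal(efc$data, t(efc$data))

  # duplicated ROI rows -> duplicated edge rows -> off-diagonal 1
  xd <- rbind(x, x[1, ])
  etsd <- compute_ets(roi_time_series(xd, roi_labels = letters[1:4]))
  # edges (1,2) and (2,4) share identical z rows for ROIs 1 and 4
  efcd <- compute_efc(etsd)
  e12 <- which(etsd$edge_index[, 1] == 1 & etsd$edge_index[, 2] == 2)
  e24 <- which(etsd$edge_index[, 1] == 2 & etsd$edge_index[, 2] == 4)
  expect_equal(efcd$data[e12, e24], 1)

  # an identically zero edge row is zeroed out with a warning
  ets$data[2, ] <- 0
  expect_warning(efc0 <- compute_efc(ets), "zero")
  expect_equal(efc0$data[2, ], rep(0, 3), ignore_attr = TRUE)
  expect_equal(efc0$data[, 2], rep(0, 3), ignore_attr = TRUE)

  expect_error(compute_efc(compute_ets(matrix(rnorm(300), 30, 10)),
                           max_edges = 100), "max_edges")
})

test_that("RSS trace: hand value, permutation invariance, scale property", {
  set.seed(41)
  x <- matrix(rnorm(40), 4, 10)
  ets <- compute_ets(roi_time_series(x))
  rss <- compute_rss(ets)
  expect_identical(length(rss$values), 10L)
  expect_true(all(rss$values >= 0))
  expect_equal(rss$values, sqrt(colSums(ets$data^2)))

  # hand arithmetic on a tiny edge matrix
  ets_toy <- ets
  ets_toy$data <- matrix(c(1, 0.5, 2), 3, 1)
  expect_equal(compute_rss(ets_toy)$values, sqrt(5.25))

  # permuting ROI order leaves RSS unchanged
  perm <- sample(4)
  rss_p <- compute_rss(compute_ets(roi_time_series(x[perm, ])))
  expect_equal(rss_p$values, rss$values)

  # scaling all z rows by c scales RSS by c^2
  z <- zscore_series(roi_time_series(x))
  z$data <- z$data * 3
  rss_s <- compute_rss(compute_ets(z))
  expect_equal(rss_s$values, 9 * rss$values)
})
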