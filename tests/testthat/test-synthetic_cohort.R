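test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_frames = 10), "n_frames")
  expect_error(cohort_spec(event_rate_per_group = c(0, 0.2)),
               "event_rate_per_group")
  expect_error(cohort_spec(n_roi = 3, n_communities = 5), "n_communities")
  expect_error(cohort_spec(apoe_probs = c(0.5, 0.5, 0.5)), "apoe_probs")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(bandpass = c(0.1, 0.01)), "bandpass")
})

test_that("identical spec (and seed) reproduces the cohort byte-identically", {
  spec <- cohort_spec(n_per_group = 3, n_roi = 8, n_frames = 60,
                      n_communities = 2, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$metadata, c2$metadata)
  for (s in seq_along(c1$series))
    expect_identical(c1$series[[s]]$data, c2$series[[s]]$data)
  expect_identical(c1$truth, c2$truth)

  c3 <- generate_cohort(cohort_spec(n_per_group = 3, n_roi = 8, n_frames = 60,
                                    n_communities = 2, seed = 6))
  expect_false(identical(c1$series[[1]]$data, c3$series[[1]]$data))
})

test_that("round-robin site assignment and metadata invariants hold", {
  co <- generate_cohort(cohort_spec(n_per_group = 3, n_sites = 2,
                                    n_roi = 6, n_frames = 40,
                                    n_communities = 2, seed = 2))
  expect_identical(length(co$series), 6L)
  expect_identical(nrow(co$metadata), 6L)
  expect_identical(as.integer(table(co$metadata$group)), c(3L, 3L))
  # within-group round robin over 2 sites: sizes {4, 2}
  expect_identical(sort(as.integer(table(co$metadata$site))), c(2L, 4L))
  expect_true(all(co$metadata$mmse <= 30 & co$metadata$mmse >= 24))
  expect_true(all(co$metadata$apoe4_count %in% 0:2))
  expect_identical(co$metadata$subject_id, names(co$series))
})

test_that("zero-amplitude generator yields pure noise at the stated SD", {
  spec <- cohort_spec(n_per_group = 3, n_roi = 10, n_frames = 200,
                      event_amplitude_per_group = c(0, 0),
                      site_shift_sd = 0, site_scale_sd = 0,
                      n_sites = 1, seed = 8)
  co <- generate_cohort(spec)
  sds <- unlist(lapply(co$series, function(s) apply(s$data, 1, sd)))
  expect_equal(mean(sds), 1, tolerance = 0.05)
  expect_true(all(lengths(lapply(co$truth, `[[`, "event_frames")) > 0))
})

test_that("renewal process hits the prescribed mean inter-event intervals", {
  spec <- cohort_spec(n_per_group = 50, n_roi = 4, n_frames = 500,
                      n_communities = 2,
                      event_rate_per_group = c(0.20, 0.12),
                      n_sites = 1, seed = 9)
  co <- generate_cohort(spec)
  g <- co$metadata$group
  mean_iei <- function(ids) {
    iv <- unlist(lapply(co$truth[ids], function(tr) diff(tr$event_frames)))
    mean(iv)
  }
  iei_1 <- mean_iei(which(g == spec$group_labels[1]))  # rate 0.20 -> 5
  iei_2 <- mean_iei(which(g == spec$group_labels[2]))  # rate 0.12 -> 8.33
  expect_lt(abs(iei_1 - 5) / 5, 0.10)
  expect_lt(abs(iei_2 - 1 / 0.12) / (1 / 0.12), 0.10)

  # fixed-interval model is exactly periodic
  spec_f <- cohort_spec(n_per_group = 1, n_roi = 4, n_frames = 100,
                        n_communities = 2, interval_model = "fixed",
                        event_rate_per_group = c(0.1, 0.1), n_sites = 1,
                        seed = 1)
  co_f <- generate_cohort(spec_f)
  expect_identical(co_f$truth[[1]]$event_frames, seq.int(10L, 100L, 10L))
})

test_that("zero amplitude-MMSE slope leaves scores uncorrelated", {
  spec <- cohort_spec(n_per_group = 100, n_roi = 4, n_frames = 40,
                      n_communities = 2, n_sites = 1, seed = 10,
                      mmse_slope = 0)
  co <- generate_cohort(spec)
  amp <- spec$event_amplitude_per_group[match(co$metadata$group,
                                              spec$group_labels)]
  rho <- spearman_cor(amp, co$metadata$mmse)$rho
  expect_lt(abs(rho), 0.15)
})

test_that("TTD grows as the event rate falls (monotone in expectation)", {
  rates <- c(0.25, 0.15, 0.09)
  mean_ttd <- vapply(seq_along(rates), function(k) {
    ttds <- vapply(1:6, function(r) {
      spec <- cohort_spec(n_per_group = 3, n_roi = 12, n_frames = 200,
                          n_communities = 3,
                          event_rate_per_group = rep(rates[k], 2),
                          n_sites = 1, seed = 100 * k + r)
      co <- generate_cohort(spec)
      mean(dynamics_table(co$series)$mean_ttd_frames)
    }, numeric(1))
    mean(ttds)
  }, numeric(1))
  expect_true(all(diff(mean_ttd) > 0))
})

test_that("null cohorts reject dynamics t-tests at about the nominal rate", {
  # identical group parameters: two-sided t on mean TTD should reject ~5%
  rej <- vapply(1:60, function(r) {
    spec <- cohort_spec(n_per_group = 6, n_roi = 8, n_frames = 120,
                        n_communities = 2,
                        event_rate_per_group = c(0.15, 0.15),
                        event_amplitude_per_group = c(2.5, 2.5),
                        n_sites = 1, seed = 5000 + r)
    co <- generate_cohort(spec)
    dyn <- dynamics_table(co$series)
    g <- co$metadata$group
    two_sample_t(dyn$mean_ttd_frames[g == "SCD"],
                 dyn$mean_ttd_frames[g == "HC"])$p_value < 0.05
  }, logical(1))
  # binomial 95% band around 0.05 for 60 replicates: [0, 0.105]
  expect_lte(mean(rej), 0.105)
})
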