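test_that("coupling_spec validates edges, lags, strengths and groups", {
  cp <- coupling_spec(rbind(c(3, 8), c(11, 30)), lag_ms = 20, strength = 0.6,
                      group = "CPS")
  expect_s3_class(cp, "coupling_spec")
  expect_equal(nrow(cp), 2L)
  expect_equal(nrow(coupling_spec()), 0L)
  expect_error(coupling_spec(rbind(c(1, 2)), lag_ms = 0), "lag_ms")
  expect_error(coupling_spec(rbind(c(1, 1))), "self-coupling")
  expect_error(coupling_spec(rbind(c(1, 2)), strength = 1.5), "strength")
  expect_error(coupling_spec(rbind(c(1, 2)), group = "CTL"), "group")
})

test_that("a sub-sample lag is rejected as unusable coupling", {
  cp <- coupling_spec(rbind(c(1, 2)), lag_ms = 3, strength = 0.5)  # 0.3 smp @100Hz
  cfg <- cohort_config(n_subjects_per_group = 1, n_parcels = 4,
                       segments_per_subject_range = c(2, 3), seed = 1)
  expect_error(generate_cohort(cfg, cp), "shorter than one sample")
  # same lag is fine at 1200 Hz
  cfg2 <- cohort_config(n_subjects_per_group = 1, n_parcels = 4, mode = "raw",
                        n_blocks = 1, block_duration_s = 30,
                        segments_per_subject_range = c(1, 3), seed = 1)
  expect_silent(generate_recording("S", "CPS", cp, cfg2, seed = 2))
})

test_that("recordings and cohorts are bit-reproducible given the seed", {
  cfg <- cohort_config(n_subjects_per_group = 2, n_parcels = 6,
                       segments_per_subject_range = c(3, 5), seed = 11)
  cp <- coupling_spec(rbind(c(1, 4)), lag_ms = 20, strength = 0.5)
  a <- simulate_fc_cohort(cfg, cp)
  b <- simulate_fc_cohort(cfg, cp)
  expect_identical(a$features$x, b$features$x)
  rcfg <- cohort_config(n_subjects_per_group = 1, n_parcels = 4, mode = "raw",
                        n_blocks = 1, block_duration_s = 30,
                        segments_per_subject_range = c(1, 3), seed = 5)
  r1 <- generate_recording("S", "SPS", cp, rcfg, seed = 9)
  r2 <- generate_recording("S", "SPS", cp, rcfg, seed = 9)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$annotations, r2$annotations)
})

test_that("lagged coupling shows up at the configured sample delay", {
  cp <- coupling_spec(rbind(c(3, 7)), lag_ms = 20, strength = 0.6,
                      group = "both")
  cfg <- cohort_config(n_subjects_per_group = 1, n_parcels = 8, mode = "raw",
                       sample_rate_hz = 100, n_blocks = 1,
                       block_duration_s = 120, noise_sd = 0.05,
                       segments_per_subject_range = c(4, 12), seed = 3)
  rec <- generate_recording("S", "CPS", cp, cfg, seed = 11)
  cc <- ccf(rec$signals[3, ], rec$signals[7, ], lag.max = 6, plot = FALSE)
  peak <- cc$lag[which.max(abs(cc$acf))]
  expect_equal(abs(peak), 2)      # 20 ms at 100 Hz
  # uncoupled pair shows no comparable peak
  cc0 <- ccf(rec$signals[1, ], rec$signals[2, ], lag.max = 6, plot = FALSE)
  expect_lt(max(abs(cc0$acf)), max(abs(cc$acf)) / 2)
})

test_that("cohort sizes, segment-count ranges and ground truth are honoured", {
  cfg <- cohort_config(n_subjects_per_group = 3, n_parcels = 10,
                       segments_per_subject_range = c(4, 9), seed = 21)
  cp <- coupling_spec(rbind(c(2, 5), c(3, 9)), lag_ms = 20, strength = 0.6,
                      group = c("CPS", "CPS"))
  coh <- generate_cohort(cfg, cp)
  expect_length(coh$subjects, 6L)
  expect_equal(sum(vapply(coh$subjects, function(s)
    s$group_label == "CPS", logical(1))), 3L)
  counts <- vapply(coh$subjects, `[[`, integer(1), "n_segments")
  expect_true(all(counts >= 4 & counts <= 9))
  gt <- coh$ground_truth
  expect_equal(gt$parcel_i, c(5L, 9L))
  expect_equal(gt$parcel_j, c(2L, 3L))
  expect_equal(gt$feature, c(5L * 4L / 2L + 2L, 9L * 8L / 2L + 3L))
  # single subject per group -> two recordings
  cfg1 <- cohort_config(n_subjects_per_group = 1, n_parcels = 4,
                        segments_per_subject_range = c(2, 3), seed = 1)
  expect_length(generate_cohort(cfg1)$subjects, 2L)
})

test_that("raw-mode spike tuning lands the segment yield inside the range", {
  cfg <- cohort_config(n_subjects_per_group = 2, n_parcels = 3, mode = "raw",
                       n_blocks = 3, block_duration_s = 60,
                       segments_per_subject_range = c(6, 14),
                       spike_rate_per_min = 2, seed = 31)
  coh <- generate_cohort(cfg)
  for (s in coh$subjects) {
    segs <- preprocess_recording(s)
    expect_true(length(segs) >= 6 && length(segs) <= 14)
  }
  # infeasible range: spike-free blocks cannot reach the minimum
  bad <- cohort_config(n_subjects_per_group = 1, n_parcels = 3, mode = "raw",
                       n_blocks = 1, block_duration_s = 60,
                       segments_per_subject_range = c(50, 60), seed = 1)
  expect_error(generate_cohort(bad), "infeasible")
})

test_that("zero-lag coupling produces no imaginary coherence", {
  # internal hook: force lag 0 samples past the public validation
  set.seed(42)
  act0 <- data.frame(from = 1L, to = 2L, lag_smp = 0L, strength = 0.6)
  x0 <- seizfc:::simulate_segment_array(200, 4, 400, 100, act0, 0.5, c(1, 45))
  map <- fc_index_map(4)
  coupled <- which(map$parcel_i == 2 & map$parcel_j == 1)
  uncoupled <- which(map$parcel_i == 4 & map$parcel_j == 3)
  # the signed band-averaged imaginary coherency (the physical quantity a
  # lag would shift) is indistinguishable between the zero-lag-coupled and
  # an uncoupled edge at alpha = 0.01
  f0s <- seizfc:::batch_imcoh_features_cpp(x0, 100, 1, 0.5, 1, 40, FALSE)
  expect_gt(t.test(f0s[, coupled], f0s[, uncoupled])$p.value, 0.01)
  # the |Im|-convention value never rises above the uncoupled level either
  # (strong real coherence can only shrink the half-normal noise floor)
  f0a <- seizfc:::batch_imcoh_features_cpp(x0, 100, 1, 0.5, 1, 40, TRUE)
  expect_lte(mean(f0a[, coupled]), mean(f0a[, uncoupled]) +
               2 * sd(f0a[, uncoupled]) / sqrt(nrow(f0a)))
  # positive control: the same coupling with a real lag is clearly visible
  act2 <- data.frame(from = 1L, to = 2L, lag_smp = 2L, strength = 0.6)
  x2 <- seizfc:::simulate_segment_array(200, 4, 400, 100, act2, 0.5, c(1, 45))
  f2 <- seizfc:::batch_imcoh_features_cpp(x2, 100, 1, 0.5, 1, 40, TRUE)
  expect_lt(t.test(f2[, coupled], f2[, uncoupled])$p.value, 1e-6)
})

test_that("edge FC grows monotonically with coupling strength", {
  set.seed(7)
  map <- fc_index_map(4)
  coupled <- which(map$parcel_i == 2 & map$parcel_j == 1)
  stats <- t(vapply(c(0, 0.3, 0.6, 0.9), function(s) {
    act <- data.frame(from = 1L, to = 2L, lag_smp = 2L, strength = s)
    x <- seizfc:::simulate_segment_array(200, 4, 400, 100, act, 0.5, c(1, 45))
    f <- seizfc:::batch_imcoh_features_cpp(x, 100, 1, 0.5, 1, 40, TRUE)
    c(mean(f[, coupled]), sd(f[, coupled]) / sqrt(nrow(f)))
  }, numeric(2)))
  for (k in 1:3)
    expect_gte(stats[k + 1, 1], stats[k, 1] - (stats[k, 2] + stats[k + 1, 2]))
})
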