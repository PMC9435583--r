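test_that("event-window exclusion returns the maximal clean intervals", {
  expect_equal(exclude_event_windows(120, numeric()),
               data.frame(start_s = 0, end_s = 120))
  expect_equal(exclude_event_windows(120, 60),
               data.frame(start_s = c(0, 70), end_s = c(50, 120)))
  # overlapping windows merge: events at 5 and 8 exclude [0, 18)
  expect_equal(exclude_event_windows(120, c(5, 8)),
               data.frame(start_s = 18, end_s = 120))
  # event outside the block only removes what intersects it
  expect_equal(exclude_event_windows(120, 125),
               data.frame(start_s = 0, end_s = 115))
  expect_error(exclude_event_windows(120, 60, pad_s = 0), "pad_s")
})

test_that("partition tiles, keeps long-enough remainders, and trims", {
  p <- partition_segments(data.frame(start_s = 0, end_s = 120))
  expect_equal(nrow(p), 12L)
  expect_equal(p$start_s, seq(0, 110, by = 10))
  expect_true(all(p$end_s - p$start_s == 4))
  p2 <- partition_segments(data.frame(start_s = c(0, 70), end_s = c(50, 120)))
  expect_equal(nrow(p2), 10L)
  expect_equal(nrow(partition_segments(data.frame(start_s = 0, end_s = 3))), 0L)
  # trailing remainder of exactly min_keep_s survives
  p3 <- partition_segments(data.frame(start_s = 0, end_s = 14))
  expect_equal(p3$start_s, c(0, 10))
  expect_error(partition_segments(data.frame(start_s = 0, end_s = 10),
                                  cut_len_s = 3, trim_len_s = 4), "cut_len_s")
})

test_that("segment counts match a 1 ms-grid brute force on random layouts", {
  set.seed(99)
  for (i in 1:40) {
    dur <- sample(c(60, 90, 120), 1)
    ev <- sample(seq(0.01, dur - 0.01, by = 0.01), rpois(1, 3))
    got <- nrow(partition_segments(exclude_event_windows(dur, ev)))
    expect_equal(got, oracle_segment_count(dur, ev), info = paste("case", i))
  }
})

test_that("no kept segment intersects an exclusion window", {
  set.seed(17)
  for (i in 1:20) {
    dur <- 120
    ev <- runif(rpois(1, 4), 0, dur)
    segs <- partition_segments(exclude_event_windows(dur, ev))
    for (e in ev)
      expect_true(all(segs$end_s <= e - 10 | segs$start_s >= e + 10))
  }
})

test_that("band-pass and notch behave as designed", {
  fs <- 1200
  t20 <- seq(0, 20, by = 1 / fs)[-1]      # block-length signal
  s50 <- sin(2 * pi * 50 * t20)
  expect_lt(sd(filter_signal(s50, fs)) / sd(s50), 0.05)
  s10 <- sin(2 * pi * 10 * t20)
  expect_equal(sd(filter_signal(s10, fs)) / sd(s10), 1, tolerance = 0.05)
  expect_equal(max(abs(filter_signal(rep(1, 4800), fs))), 0)  # DC rejection
  expect_error(filter_signal(rnorm(100), sample_rate_hz = 120), "sample_rate")
})

test_that("filtering is idempotent on in-band content", {
  set.seed(1)
  fs <- 1200
  x <- c(test_noise(4800, 1, fs, band = c(2, 40)))
  f1 <- filter_signal(x, fs)
  f2 <- filter_signal(f1, fs)
  expect_lt(abs(sd(f2) - sd(f1)) / sd(f1), 0.01)
})

test_that("resampling decimates with effective anti-aliasing", {
  fs <- 1200
  t4 <- seq(0, 4, by = 1 / fs)[-1]
  r <- resample_to(sin(2 * pi * 45 * t4), fs, 100)
  expect_length(r, 400L)                  # 4 s at 100 Hz
  expect_lt(var(r[100:300]) / var(sin(2 * pi * 45 * t4)), 0.01)
  # passband untouched
  r10 <- resample_to(sin(2 * pi * 10 * t4), fs, 100)
  expect_equal(sd(r10[100:300]) / sd(sin(2 * pi * 10 * t4)), 1,
               tolerance = 0.05)
  # identity when rates match; upsampling refused
  x <- rnorm(500)
  expect_identical(resample_to(x, 100, 100), x)
  expect_error(resample_to(x, 100, 200), "target_hz")
})

test_that("artifact rejection drops exactly the contaminated segments", {
  set.seed(5)
  segs <- lapply(1:10, function(i) matrix(rnorm(4 * 400), 4, 400))
  expect_identical(reject_artifact_segments(segs), segs)
  expect_identical(reject_artifact_segments(segs, Inf, Inf), segs)
  bad <- segs
  bad[[4]][2, 100] <- 50                   # amplitude burst
  kept <- reject_artifact_segments(bad)
  expect_identical(kept, bad[-4])
  jump <- segs
  jump[[7]][1, 200:400] <- jump[[7]][1, 200:400] + 30   # step / jump artifact
  kept2 <- reject_artifact_segments(jump)
  expect_false(any(vapply(kept2, identical, logical(1), jump[[7]])))
})

test_that("preprocess_recording yields 4-s 100 Hz segments clear of spikes", {
  cfg <- cohort_config(n_subjects_per_group = 1, n_parcels = 3, mode = "raw",
                       n_blocks = 2, block_duration_s = 60,
                       segments_per_subject_range = c(2, 10), seed = 13)
  rec <- generate_recording("S", "CPS", coupling_spec(), cfg, seed = 4)
  segs <- preprocess_recording(rec)
  expect_gt(length(segs), 0L)
  for (s in segs) {
    expect_equal(dim(s$signals), c(3L, 400L))
    expect_equal(s$sample_rate_hz, 100)
    ev <- rec$annotations$time_s[rec$annotations$block == s$origin$block]
    if (length(ev))
      expect_true(all(s$origin$start_s + 4 <= ev - 10 |
                        s$origin$start_s >= ev + 10))
  }
})
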