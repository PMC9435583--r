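# Segment extraction and signal conditioning: spike-window exclusion,
# non-overlapping partition with trimming, zero-phase filtering, and
# anti-aliased downsampling.

new_segment <- function(signals, subject_id, group_label, sample_rate_hz,
                        origin = list(block = NA_integer_, start_s = NA_real_)) {
  structure(list(subject_id = subject_id, group_label = group_label,
                 signals = signals, sample_rate_hz = sample_rate_hz,
                 origin = origin),
            class = "meg_segment")
}

#' Clean intervals of a block after event-window exclusion
#'
#' Removes a symmetric pad around every annotated event (interictal spike
#' or abnormal discharge) from a recording block and returns the maximal
#' remaining clean intervals. Intervals are half-open `[start, end)`,
#' sorted, and disjoint; event windows extending beyond the block are
#' clipped to it.
#'
#' @param block_duration_s Block duration in seconds.
#' @param event_times_s Numeric vector of event times (seconds, block
#'   relative); may be empty.
#' @param pad_s Half-width of the exclusion window around each event
#'   (default 10, i.e. `[t - 10, t + 10]` is dropped).
#' @return Data frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @examples
#' exclude_event_windows(120, c(60))        # [0,50) and [70,120)
#' exclude_event_windows(120, c(5, 8))      # [18,120)
#' @export
exclude_event_windows <- function(block_duration_s, event_times_s = numeric(),
                                  pad_s = 10) {
  stopifnot_scalar_number(block_duration_s, "block_duration_s", min = 0)
  stopifnot_scalar_number(pad_s, "pad_s")
  if (pad_s <= 0) stop("`pad_s` must be > 0")
  ev <- sort(as.numeric(event_times_s))
  lo <- pmax(ev - pad_s, 0)
  hi <- pmin(ev + pad_s, block_duration_s)
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  # merge overlapping exclusion windows, then complement within the block
  starts <- numeric(); ends <- numeric()
  cur_lo <- NA_real_; cur_hi <- NA_real_
  for (i in seq_along(lo)) {
    if (is.na(cur_lo)) {
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      starts <- c(starts, cur_lo); ends <- c(ends, cur_hi)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  if (!is.na(cur_lo)) { starts <- c(starts, cur_lo); ends <- c(ends, cur_hi) }
  edges <- c(0, rbind(starts, ends), block_duration_s)
  out_lo <- edges[seq(1, length(edges), by = 2)]
  out_hi <- edges[seq(2, length(edges), by = 2)]
  keep <- out_hi > out_lo
  data.frame(start_s = out_lo[keep], end_s = out_hi[keep])
}

#' Partition clean intervals into fixed-length trimmed segments
#'
#' Tiles each clean interval with consecutive non-overlapping windows of
#' `cut_len_s` seconds anchored at the interval's left edge. A final
#' partial window is kept only if it is at least `min_keep_s` long. Every
#' kept window is then trimmed to its first `trim_len_s` seconds, so all
#' returned intervals have equal length.
#'
#' @param intervals Data frame with `start_s`, `end_s` columns (as returned
#'   by [exclude_event_windows()]).
#' @param cut_len_s Tiling window length in seconds (default 10).
#' @param min_keep_s Minimum length for a trailing partial window to be
#'   kept (default 4).
#' @param trim_len_s Length every kept window is trimmed to (default 4).
#' @return Data frame with `start_s`, `end_s`: the segment intervals.
#' @examples
#' partition_segments(data.frame(start_s = 0, end_s = 120))  # 12 segments
#' @export
partition_segments <- function(intervals, cut_len_s = 10, min_keep_s = 4,
                               trim_len_s = 4) {
  stopifnot(is.data.frame(intervals),
            all(c("start_s", "end_s") %in% names(intervals)))
  if (cut_len_s < trim_len_s) stop("`cut_len_s` must be >= `trim_len_s`")
  if (min_keep_s > cut_len_s) stop("`min_keep_s` must be <= `cut_len_s`")
  out_lo <- numeric(); out_hi <- numeric()
  for (r in seq_len(nrow(intervals))) {
    a <- intervals$start_s[r]; b <- intervals$end_s[r]
    if (b <= a) stop("intervals must satisfy end_s > start_s")
    starts <- seq(a, b, by = cut_len_s)
    starts <- starts[starts < b]
    len <- pmin(starts + cut_len_s, b) - starts
    starts <- starts[len >= min_keep_s]
    len <- len[len >= min_keep_s]
    out_lo <- c(out_lo, starts)
    out_hi <- c(out_hi, starts + pmin(trim_len_s, len))
  }
  data.frame(start_s = out_lo, end_s = out_hi)
}

# Zero-phase filtering with odd-reflection end padding (the usual remedy
# for filtfilt start-up transients on finite windows).
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0L) {
    c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  } else {
    x
  }
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1L):(pad + n)]
}

# Zero-phase biquad notch (standard audio-EQ cookbook design).
notch_coefficients <- function(freq_hz, sample_rate_hz, q = 30) {
  w0 <- 2 * pi * freq_hz / sample_rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies, forward and backward (zero phase, so that filtering cannot
#' distort the cross-spectral phase that imaginary coherency depends on):
#' a 4th-order Butterworth high-pass at `low_hz`, a 4th-order Butterworth
#' low-pass at `high_hz`, and a biquad notch at `notch_hz` with quality
#' factor `notch_q`. The band edges are realised as a high-pass/low-pass
#' cascade, which is numerically robust when the band is wide relative to
#' the sampling rate.
#'
#' @param signals Numeric matrix, channels x samples (a single channel may
#'   be passed as a vector).
#' @param sample_rate_hz Sampling rate in Hz; must exceed `2 * high_hz`.
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 1 and 70).
#' @param notch_hz Notch centre frequency in Hz (default 50; `NULL` skips
#'   the notch).
#' @param notch_q Notch quality factor (default 30).
#' @return Filtered signals, same shape as the input.
#' @export
filter_signal <- function(signals, sample_rate_hz, low_hz = 1, high_hz = 70,
                          notch_hz = 50, notch_q = 30) {
  vec_in <- is.null(dim(signals))
  x <- if (vec_in) matrix(signals, nrow = 1) else as.matrix(signals)
  if (!all(is.finite(x))) stop("`signals` must be finite")
  if (sample_rate_hz <= 2 * high_hz)
    stop("`sample_rate_hz` must exceed twice the low-pass edge `high_hz`")
  nyq <- sample_rate_hz / 2
  hp <- signal::butter(4, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  nt <- if (!is.null(notch_hz)) notch_coefficients(notch_hz, sample_rate_hz,
                                                   notch_q) else NULL
  # pad by a few time constants of the slowest (high-pass) filter
  pad <- as.integer(round(3 * sample_rate_hz / low_hz))
  out <- t(apply(x, 1, function(ch) {
    y <- ch - mean(ch)                 # exact DC removal
    y <- filtfilt_padded(hp, y, pad)
    y <- filtfilt_padded(lp, y, pad)
    if (!is.null(nt))
      y <- filtfilt_padded(signal::Arma(b = nt$b, a = nt$a), y, pad)
    y
  }))
  if (vec_in) drop(out) else out
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at `antialias_hz` with a zero-phase windowed-sinc
#' (Hamming) FIR filter and then resamples to `target_hz`. The anti-alias
#' cutoff defaults to 40 Hz: with a 100 Hz target rate the post-decimation
#' Nyquist is 50 Hz, and only the 1--40 Hz band is analysed downstream, so
#' a 40 Hz cutoff prevents aliasing without touching the analysis band.
#' The FIR length scales with the sampling rate (about 0.6 s of taps),
#' giving a transition band of a few hertz and > 50 dB stop-band
#' attenuation; being linear-phase, the filter is made exactly zero-phase
#' by compensating its group delay. Integer rate ratios decimate by sample
#' picking; non-integer ratios interpolate linearly on the target grid.
#'
#' @param signals Channels x samples matrix (or a vector).
#' @param sample_rate_hz Input sampling rate in Hz.
#' @param target_hz Output rate (default 100); must not exceed
#'   `sample_rate_hz`.
#' @param antialias_hz Anti-alias low-pass cutoff (default 40). Must be
#'   below the target Nyquist.
#' @return Resampled signals with `round(n * target_hz / sample_rate_hz)`
#'   samples per channel.
#' @export
resample_to <- function(signals, sample_rate_hz, target_hz = 100,
                        antialias_hz = 40) {
  if (target_hz > sample_rate_hz)
    stop("`target_hz` must not exceed `sample_rate_hz`")
  if (antialias_hz >= target_hz / 2)
    stop("`antialias_hz` must lie below the target Nyquist rate")
  vec_in <- is.null(dim(signals))
  x <- if (vec_in) matrix(signals, nrow = 1) else as.matrix(signals)
  if (target_hz == sample_rate_hz) return(if (vec_in) drop(x) else x)
  n <- ncol(x)
  half <- round(0.3 * sample_rate_hz)
  ntaps <- 2L * as.integer(half) + 1L     # odd: exact integer group delay
  h <- signal::fir1(ntaps - 1L, antialias_hz / (sample_rate_hz / 2),
                    type = "low")
  n_out <- as.integer(round(n * target_hz / sample_rate_hz))
  ratio <- sample_rate_hz / target_hz
  idx <- (seq_len(n_out) - 1) * ratio + 1
  out <- t(apply(x, 1, function(ch) {
    y <- signal::fftfilt(h, c(ch, numeric(half)))
    y <- y[(half + 1L):(half + n)]        # compensate the linear-phase delay
    if (all(abs(idx - round(idx)) < 1e-9)) y[round(idx)]
    else approx(seq_len(n), y, xout = idx, rule = 2)$y
  }))
  if (vec_in) drop(out) else out
}

#' Drop segments with jump-like or high-amplitude artifacts
#'
#' Automated stand-in for manual artifact review: for each channel,
#' amplitudes and first differences are z-scored against that channel's
#' pooled mean and standard deviation across all of the subject's
#' segments. A segment is dropped when any channel's peak `|z|` amplitude
#' exceeds `amp_z_max` (muscular-artifact proxy) or any channel's peak
#' `|z|` first difference exceeds `grad_z_max` (SQUID-jump proxy).
#'
#' @param segments List of `meg_segment` objects (or bare channels x
#'   samples matrices) from one subject.
#' @param amp_z_max,grad_z_max Positive rejection thresholds in z-score
#'   units (defaults 6 and 6). `Inf` disables a criterion.
#' @return The surviving segments, original order preserved.
#' @export
reject_artifact_segments <- function(segments, amp_z_max = 6, grad_z_max = 6) {
  if (amp_z_max <= 0 || grad_z_max <= 0)
    stop("rejection thresholds must be > 0")
  if (length(segments) == 0L) return(segments)
  mats <- lapply(segments, function(s)
    if (inherits(s, "meg_segment")) s$signals else as.matrix(s))
  amp_all <- do.call(cbind, mats)
  mu_a <- rowMeans(amp_all)
  sd_a <- apply(amp_all, 1, sd); sd_a[sd_a == 0] <- Inf
  diffs <- lapply(mats, function(m) m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  diff_all <- do.call(cbind, diffs)
  mu_d <- rowMeans(diff_all)
  sd_d <- apply(diff_all, 1, sd); sd_d[sd_d == 0] <- Inf
  keep <- vapply(seq_along(mats), function(k) {
    za <- abs((mats[[k]] - mu_a) / sd_a)
    zd <- abs((diffs[[k]] - mu_d) / sd_d)
    max(za) <= amp_z_max && max(zd) <= grad_z_max
  }, logical(1))
  segments[keep]
}

#' Full preprocessing of one raw recording
#'
#' Runs the segment-extraction pipeline on a continuous annotated
#' recording: per block, spike-window exclusion ([exclude_event_windows()])
#' and partition into trimmed segments ([partition_segments()]); zero-phase
#' filtering ([filter_signal()]) and anti-aliased downsampling
#' ([resample_to()]) of the block signal; extraction of the segment
#' windows; and finally subject-level artifact rejection
#' ([reject_artifact_segments()]).
#'
#' @param recording A `meg_recording` from [generate_recording()] (or any
#'   list with the same fields).
#' @param pad_s,cut_len_s,min_keep_s,trim_len_s Segmentation parameters,
#'   see [exclude_event_windows()] and [partition_segments()].
#' @param low_hz,high_hz,notch_hz,notch_q Filtering parameters, see
#'   [filter_signal()].
#' @param target_hz,antialias_hz Resampling parameters, see
#'   [resample_to()].
#' @param amp_z_max,grad_z_max Artifact thresholds, see
#'   [reject_artifact_segments()].
#' @return List of `meg_segment` objects (channels x samples at
#'   `target_hz`, each `trim_len_s` seconds long) with block and start-time
#'   provenance.
#' @export
preprocess_recording <- function(recording, pad_s = 10, cut_len_s = 10,
                                 min_keep_s = 4, trim_len_s = 4,
                                 low_hz = 1, high_hz = 70, notch_hz = 50,
                                 notch_q = 30, target_hz = 100,
                                 antialias_hz = 40,
                                 amp_z_max = 6, grad_z_max = 6) {
  fs <- recording$sample_rate_hz
  ns_block <- as.integer(round(recording$block_duration_s * fs))
  n_per_seg <- as.integer(round(trim_len_s * target_hz))
  segs <- list()
  for (b in seq_len(recording$n_blocks)) {
    cols <- ((b - 1L) * ns_block + 1L):(b * ns_block)
    ev <- recording$annotations$time_s[recording$annotations$block == b]
    ivals <- partition_segments(
      exclude_event_windows(recording$block_duration_s, ev, pad_s),
      cut_len_s, min_keep_s, trim_len_s)
    if (nrow(ivals) == 0L) next
    blk <- filter_signal(recording$signals[, cols, drop = FALSE], fs,
                         low_hz, high_hz, notch_hz, notch_q)
    blk <- resample_to(blk, fs, target_hz, antialias_hz)
    for (r in seq_len(nrow(ivals))) {
      s0 <- as.integer(round(ivals$start_s[r] * target_hz)) + 1L
      idx <- s0:(s0 + n_per_seg - 1L)
      if (max(idx) > ncol(blk)) next
      segs[[length(segs) + 1L]] <- new_segment(
        blk[, idx, drop = FALSE], recording$subject_id,
        recording$group_label, target_hz,
        origin = list(block = b, start_s = ivals$start_s[r]))
    }
  }
  reject_artifact_segments(segs, amp_z_max, grad_z_max)
}
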