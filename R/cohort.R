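# Synthetic two-group cohort generator.
#
# Group differences are planted as *lagged* linear coupling between chosen
# parcel pairs: imaginary coherency is blind to instantaneous mixing, so a
# time lag is the only way a recoverable FC signal can be planted.

#' Specify lagged coupling between parcel pairs
#'
#' Defines the parcel pairs that carry a lagged linear coupling in the
#' synthetic cohort, the lag, the coupling strength, and which group
#' expresses each edge. Edges restricted to one group (`"CPS"` or `"SPS"`)
#' are the planted group difference; edges marked `"both"` are shared
#' background coupling.
#'
#' @param edges Two-column matrix or data frame of 1-based parcel index
#'   pairs (source, target), one row per coupled edge, or `NULL` for a
#'   coupling-free specification.
#' @param lag_ms Positive lag in milliseconds applied to the source signal
#'   before it is added into the target (recycled across edges). A zero lag
#'   is rejected: it produces no imaginary coherence by construction.
#' @param strength Coupling coefficient in `[0, 1]` (recycled).
#' @param group `"CPS"`, `"SPS"`, or `"both"`: which group expresses each
#'   edge (recycled).
#' @return A `coupling_spec` object (data frame with columns `from`, `to`,
#'   `lag_ms`, `strength`, `group`).
#' @examples
#' coupling_spec(rbind(c(3, 8), c(11, 30)), lag_ms = 20, strength = 0.6,
#'               group = "CPS")
#' @export
coupling_spec <- function(edges = NULL, lag_ms = 20, strength = 0.6,
                          group = "both") {
  if (is.null(edges) || NROW(edges) == 0L) {
    spec <- data.frame(from = integer(), to = integer(), lag_ms = numeric(),
                       strength = numeric(), group = character(),
                       stringsAsFactors = FALSE)
    class(spec) <- c("coupling_spec", class(spec))
    return(spec)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns (from, to)")
  ne <- nrow(edges)
  from <- as.integer(edges[, 1]); to <- as.integer(edges[, 2])
  if (any(from < 1L) || any(to < 1L)) stop("parcel indices must be >= 1")
  if (any(from == to)) stop("self-coupling (from == to) is not allowed")
  lag_ms <- rep_len(as.numeric(lag_ms), ne)
  strength <- rep_len(as.numeric(strength), ne)
  group <- rep_len(as.character(group), ne)
  if (any(!is.finite(lag_ms)) || any(lag_ms <= 0))
    stop("`lag_ms` must be > 0: zero-lag coupling carries no imaginary coherence")
  if (any(!is.finite(strength)) || any(strength < 0) || any(strength > 1))
    stop("`strength` must lie in [0, 1]")
  if (!all(group %in% c("CPS", "SPS", "both")))
    stop('`group` must be one of "CPS", "SPS", "both"')
  spec <- data.frame(from = from, to = to, lag_ms = lag_ms,
                     strength = strength, group = group,
                     stringsAsFactors = FALSE)
  class(spec) <- c("coupling_spec", class(spec))
  spec
}

#' Configure a synthetic cohort
#'
#' Collects the study-design parameters of the simulated cohort. Defaults
#' mirror a resting-state MEG protocol: two groups of 16 subjects, 74
#' cortical parcels, twenty 120-s recording blocks per subject acquired at
#' 1200 Hz (raw mode), and per-subject clean-segment yields between 33 and
#' 169 four-second segments.
#'
#' @param n_subjects_per_group Subjects per group (default 16).
#' @param n_parcels Number of cortical parcels (default 74).
#' @param mode `"segments"` generates clean 4-s segments at 100 Hz directly
#'   (the unit the analysis stages consume); `"raw"` generates continuous
#'   annotated blocks that must pass through [preprocess_recording()].
#' @param sample_rate_hz Sampling rate; defaults to 100 in segment mode and
#'   1200 in raw mode.
#' @param n_blocks,block_duration_s Raw mode: number and duration of
#'   recording blocks (defaults 20 and 120).
#' @param segments_per_subject_range Two integers: the range the per-subject
#'   clean-segment yield is drawn from (default `c(33, 169)`).
#' @param spike_rate_per_min Raw mode: initial rate of the Poisson process
#'   for interictal spike annotations (default 2). Per-subject rates are
#'   then adjusted so the post-exclusion segment yield lands in
#'   `segments_per_subject_range`.
#' @param segment_len_s Segment duration in seconds (default 4).
#' @param noise_band_hz Band of the underlying parcel noise in Hz (default
#'   `c(1, 45)`, populating the 1--40 Hz analysis band).
#' @param noise_sd Observation-noise standard deviation added on top of the
#'   unit-variance band-limited parcel signals (default 0.5).
#' @param seed Mandatory integer root seed; every random draw in the
#'   generator derives from it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects_per_group = 16, n_parcels = 74,
                          mode = c("segments", "raw"), sample_rate_hz = NULL,
                          n_blocks = 20, block_duration_s = 120,
                          segments_per_subject_range = c(33, 169),
                          spike_rate_per_min = 2, segment_len_s = 4,
                          noise_band_hz = c(1, 45), noise_sd = 0.5,
                          seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  seed <- as.integer(seed)
  sample_rate_hz <- sample_rate_hz %||% if (mode == "segments") 100 else 1200
  stopifnot_scalar_number(n_subjects_per_group, "n_subjects_per_group", min = 1)
  stopifnot_scalar_number(n_parcels, "n_parcels", min = 2)
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", min = 1)
  stopifnot_scalar_number(n_blocks, "n_blocks", min = 1)
  stopifnot_scalar_number(block_duration_s, "block_duration_s", min = 1)
  stopifnot_scalar_number(spike_rate_per_min, "spike_rate_per_min", min = 0)
  stopifnot_scalar_number(segment_len_s, "segment_len_s", min = 0.5)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  r <- segments_per_subject_range
  if (length(r) != 2L || any(r < 1) || r[1] > r[2])
    stop("`segments_per_subject_range` must be c(min, max) with 1 <= min <= max")
  if (length(noise_band_hz) != 2L || noise_band_hz[1] <= 0 ||
      noise_band_hz[2] <= noise_band_hz[1] ||
      noise_band_hz[2] >= sample_rate_hz / 2)
    stop("`noise_band_hz` must satisfy 0 < low < high < Nyquist")
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_parcels = as.integer(n_parcels), mode = mode,
    sample_rate_hz = sample_rate_hz, n_blocks = as.integer(n_blocks),
    block_duration_s = block_duration_s,
    segments_per_subject_range = as.integer(round(r)),
    spike_rate_per_min = spike_rate_per_min, segment_len_s = segment_len_s,
    noise_band_hz = noise_band_hz, noise_sd = noise_sd, seed = seed
  ), class = "cohort_config")
}

# Band-limited unit-variance Gaussian noise, synthesised in the frequency
# domain (flat spectrum on [band[1], band[2]] Hz, zero outside). Columns are
# independent. Returns an n x ncol matrix.
band_noise <- function(n, ncol, fs, band = c(1, 45)) {
  fr <- (0:(n - 1)) * fs / n
  half <- floor(n / 2) + 1L
  pos <- which(fr >= band[1] & fr <= band[2] & seq_len(n) <= half)
  if (length(pos) == 0L) stop("noise band contains no frequency bins")
  spec <- matrix(0 + 0i, n, ncol)
  z <- matrix(complex(real = rnorm(length(pos) * ncol),
                      imaginary = rnorm(length(pos) * ncol)),
              length(pos), ncol)
  spec[pos, ] <- z
  conj_idx <- n - pos + 2L                    # Hermitian partner of bin k > 1
  ok <- pos > 1L & conj_idx >= half & conj_idx <= n & conj_idx != pos
  spec[conj_idx[ok], ] <- Conj(z[ok, , drop = FALSE])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  # the synthesised spectrum has no DC component, so columns are zero-mean
  sds <- sqrt(colSums(x^2) / (n - 1))
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

# Lag in samples for a coupling spec at a given sampling rate; errors when a
# requested lag is shorter than one sample (the coupling would collapse to
# instantaneous mixing, which imaginary coherency cannot see).
coupling_lag_samples <- function(coupling, sample_rate_hz) {
  if (nrow(coupling) == 0L) return(integer())
  lag <- as.integer(round(coupling$lag_ms / 1000 * sample_rate_hz))
  bad <- coupling$strength > 0 & lag < 1L
  if (any(bad))
    stop(sprintf(
      "coupling lag of %g ms is shorter than one sample at %g Hz",
      min(coupling$lag_ms[bad]), sample_rate_hz))
  lag
}

# Core segment synthesiser shared by both modes. `active` is a data frame
# with columns from, to, lag_smp, strength. Returns an array
# (n_samples x n_parcels x n_segments). Caller owns the RNG state.
simulate_segment_array <- function(n_segments, n_parcels, n_samples, fs,
                                   active, noise_sd, noise_band) {
  pad <- if (nrow(active)) max(active$lag_smp) else 0L
  base <- band_noise(n_samples + pad, n_parcels * n_segments, fs, noise_band)
  dim(base) <- c(n_samples + pad, n_parcels, n_segments)
  x <- base[(pad + 1L):(pad + n_samples), , , drop = FALSE]
  if (nrow(active)) {
    for (e in seq_len(nrow(active))) {
      L <- active$lag_smp[e]
      src <- base[(pad + 1L - L):(pad + n_samples - L),
                  active$from[e], , drop = FALSE]
      x[, active$to[e], ] <- x[, active$to[e], , drop = FALSE] +
        active$strength[e] * src
    }
  }
  if (noise_sd > 0)
    x <- x + rnorm(length(x), sd = noise_sd)
  x
}

# Edges a given group expresses.
active_edges <- function(coupling, group_label, sample_rate_hz) {
  lag <- coupling_lag_samples(coupling, sample_rate_hz)
  keep <- coupling$group %in% c("both", group_label) & coupling$strength > 0
  data.frame(from = coupling$from[keep], to = coupling$to[keep],
             lag_smp = lag[keep], strength = coupling$strength[keep])
}

#' Generate one continuous annotated recording
#'
#' Simulates one subject's raw-mode recording: `n_blocks` blocks of
#' band-limited Gaussian parcel noise at `sample_rate_hz`, with the
#' coupling edges active for the subject's group added as lagged copies of
#' the source parcel, observation noise on top, and interictal spike
#' annotations drawn as a Poisson process.
#'
#' @param subject_id Subject identifier string.
#' @param group_label `"CPS"` or `"SPS"`.
#' @param coupling A [coupling_spec()].
#' @param config A [cohort_config()]; its `n_blocks`, `block_duration_s`,
#'   `sample_rate_hz`, `noise_sd` and `spike_rate_per_min` are used.
#' @param seed Integer seed; the recording is bit-reproducible given it.
#' @param spike_times Optional list (one numeric vector per block) of
#'   pinned block-relative spike times in seconds, bypassing the Poisson
#'   draw; used by [generate_cohort()] to tune per-subject segment yields.
#' @return A `meg_recording`: list with `subject_id`, `group_label`,
#'   `signals` (n_parcels x n_samples, blocks concatenated),
#'   `sample_rate_hz`, `n_blocks`, `block_duration_s`, and `annotations`
#'   (data frame of block index and block-relative spike time).
#' @export
generate_recording <- function(subject_id, group_label, coupling, config,
                               seed, spike_times = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(coupling, "coupling_spec"))
  group_label <- match.arg(group_label, c("CPS", "SPS"))
  if (any(coupling$from > config$n_parcels) || any(coupling$to > config$n_parcels))
    stop("coupling edge indices exceed `n_parcels`")
  fs <- config$sample_rate_hz
  ns_block <- as.integer(round(config$block_duration_s * fs))
  act <- active_edges(coupling, group_label, fs)
  with_seed(seed, {
    blocks <- vector("list", config$n_blocks)
    ann <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      x <- simulate_segment_array(1L, config$n_parcels, ns_block, fs, act,
                                  config$noise_sd, config$noise_band_hz)
      blocks[[b]] <- t(x[, , 1])
      st <- if (is.null(spike_times)) {
        n_sp <- rpois(1, config$spike_rate_per_min * config$block_duration_s / 60)
        sort(runif(n_sp, 0, config$block_duration_s))
      } else {
        spike_times[[b]]
      }
      ann[[b]] <- if (length(st))
        data.frame(block = b, time_s = st) else NULL
    }
    annotations <- do.call(rbind, ann)
    if (is.null(annotations))
      annotations <- data.frame(block = integer(), time_s = numeric())
    structure(list(
      subject_id = subject_id, group_label = group_label,
      signals = do.call(cbind, blocks), sample_rate_hz = fs,
      n_blocks = config$n_blocks, block_duration_s = config$block_duration_s,
      annotations = annotations
    ), class = "meg_recording")
  })
}

# Adjust a block-wise spike set until the post-exclusion segment yield lands
# in [lo, target]; spikes are added (removed) one at a time while the yield
# is above target (below lo). Caller owns the RNG state.
tune_spike_times <- function(n_blocks, dur, rate_per_min, target, lo,
                             pad_s = 10, cut_len_s = 10, min_keep_s = 4,
                             trim_len_s = 4) {
  yield <- function(sp) {
    sum(vapply(sp, function(tt) {
      nrow(partition_segments(exclude_event_windows(dur, tt, pad_s),
                              cut_len_s, min_keep_s, trim_len_s))
    }, integer(1)))
  }
  spikes <- lapply(seq_len(n_blocks), function(b) {
    sort(runif(rpois(1, rate_per_min * dur / 60), 0, dur))
  })
  for (iter in seq_len(2000L)) {
    y <- yield(spikes)
    if (y > target) {
      b <- sample.int(n_blocks, 1)
      spikes[[b]] <- sort(c(spikes[[b]], runif(1, 0, dur)))
    } else if (y < lo) {
      nb <- which(lengths(spikes) > 0)
      if (!length(nb)) break
      b <- nb[sample.int(length(nb), 1)]
      spikes[[b]] <- spikes[[b]][-sample.int(length(spikes[[b]]), 1)]
    } else {
      return(spikes)
    }
  }
  y <- yield(spikes)
  if (y >= lo && y <= target) return(spikes)
  stop("could not tune spike annotations to the requested segment yield; ",
       "the configured range is infeasible for this block layout")
}

#' Generate a two-group synthetic cohort
#'
#' Simulates `n_subjects_per_group` subjects per group. In segment mode each
#' subject receives a drawn number of independent clean 4-s segments; in raw
#' mode each subject receives continuous annotated blocks whose spike
#' annotations are tuned so that the downstream exclusion and partition
#' rules yield a segment count inside `segments_per_subject_range`.
#'
#' @param config A [cohort_config()].
#' @param coupling A [coupling_spec()]; edges restricted to one group are
#'   returned as the ground-truth differential edges.
#' @return A `meg_cohort`: list with `subjects` (list of `meg_recording` in
#'   raw mode or per-subject segment sets in segment mode), `ground_truth`
#'   (data frame of planted differential edges with canonical feature
#'   indices), `config`, and `coupling`.
#' @export
generate_cohort <- function(config, coupling = coupling_spec()) {
  stopifnot(inherits(config, "cohort_config"), inherits(coupling, "coupling_spec"))
  if (nrow(coupling) &&
      (any(coupling$from > config$n_parcels) || any(coupling$to > config$n_parcels)))
    stop("coupling edge indices exceed `n_parcels`")
  coupling_lag_samples(coupling, config$sample_rate_hz)   # validates lags
  n <- config$n_subjects_per_group
  rng <- config$segments_per_subject_range
  ids <- c(sprintf("CPS_%02d", seq_len(n)), sprintf("SPS_%02d", seq_len(n)))
  groups <- rep(c("CPS", "SPS"), each = n)
  seeds <- derive_seeds(config$seed, 2L * n + 1L)

  if (config$mode == "raw") {
    per_block <- nrow(partition_segments(
      data.frame(start_s = 0, end_s = config$block_duration_s)))
    if (per_block * config$n_blocks < rng[1])
      stop("infeasible `segments_per_subject_range`: even spike-free blocks ",
           "yield fewer segments than the requested minimum")
  }

  subjects <- vector("list", 2L * n)
  for (k in seq_len(2L * n)) {
    subjects[[k]] <- with_seed(seeds[k], {
      target <- sample(seq.int(rng[1], rng[2]), 1)
      if (config$mode == "segments") {
        ns <- as.integer(round(config$segment_len_s * config$sample_rate_hz))
        act <- active_edges(coupling, groups[k], config$sample_rate_hz)
        x <- simulate_segment_array(target, config$n_parcels, ns,
                                    config$sample_rate_hz, act,
                                    config$noise_sd, config$noise_band_hz)
        segs <- lapply(seq_len(target), function(s) {
          new_segment(t(x[, , s]), ids[k], groups[k], config$sample_rate_hz,
                      origin = list(block = NA_integer_, start_s = NA_real_))
        })
        structure(list(subject_id = ids[k], group_label = groups[k],
                       segments = segs, n_segments = target,
                       sample_rate_hz = config$sample_rate_hz),
                  class = "meg_subject_segments")
      } else {
        spikes <- tune_spike_times(config$n_blocks, config$block_duration_s,
                                   config$spike_rate_per_min, target, rng[1])
        generate_recording(ids[k], groups[k], coupling, config,
                           seed = sample.int(.Machine$integer.max - 1L, 1),
                           spike_times = spikes)
      }
    })
  }
  structure(list(subjects = subjects,
                 ground_truth = ground_truth_edges(coupling),
                 config = config, coupling = coupling),
            class = "meg_cohort")
}

#' Ground-truth differential edges of a coupling specification
#'
#' Edges expressed by only one group (and with positive strength) are the
#' planted group difference a recovery analysis should find. Edge indices
#' are mapped to the canonical lower-triangle feature indexing used by
#' [vectorize_fc()].
#'
#' @param coupling A [coupling_spec()].
#' @return Data frame with columns `parcel_i` (larger index), `parcel_j`,
#'   `group`, and `feature` (canonical feature index).
#' @export
ground_truth_edges <- function(coupling) {
  stopifnot(inherits(coupling, "coupling_spec"))
  keep <- coupling$group != "both" & coupling$strength > 0
  i <- pmax(coupling$from[keep], coupling$to[keep])
  j <- pmin(coupling$from[keep], coupling$to[keep])
  data.frame(parcel_i = i, parcel_j = j, group = coupling$group[keep],
             feature = (i * (i - 1L)) %/% 2L + j)
}

#' Simulate a cohort and return its per-segment FC feature table
#'
#' Streaming convenience for the full analysis on synthetic data: generates
#' a segment-mode cohort subject by subject, computes each segment's
#' band-averaged imaginary-coherency FC matrix, vectorises it, and stacks
#' the results into a [feature_table()], discarding the raw signals as it
#' goes (a full cohort never has to fit in memory at once).
#'
#' @param config A [cohort_config()] with `mode = "segments"`.
#' @param coupling A [coupling_spec()].
#' @param window_s,overlap Welch parameters passed to the FC estimator.
#' @param band_hz Analysis band in Hz (default `c(1, 40)`).
#' @param absolute Average `|Im coherency|` (default) rather than the signed
#'   imaginary part.
#' @return List with `features` (a `fc_feature_table`), `subjects` (data
#'   frame: `subject_id`, `group_label`, `n_segments`), `ground_truth`
#'   (as [ground_truth_edges()]), `config`, `coupling`.
#' @export
simulate_fc_cohort <- function(config, coupling = coupling_spec(),
                               window_s = 1, overlap = 0.5,
                               band_hz = c(1, 40), absolute = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode != "segments")
    stop('`simulate_fc_cohort()` requires `mode = "segments"`; raw-mode ',
         "recordings go through `preprocess_recording()` first")
  if (nrow(coupling) &&
      (any(coupling$from > config$n_parcels) || any(coupling$to > config$n_parcels)))
    stop("coupling edge indices exceed `n_parcels`")
  coupling_lag_samples(coupling, config$sample_rate_hz)
  n <- config$n_subjects_per_group
  rng <- config$segments_per_subject_range
  ids <- c(sprintf("CPS_%02d", seq_len(n)), sprintf("SPS_%02d", seq_len(n)))
  groups <- rep(c("CPS", "SPS"), each = n)
  seeds <- derive_seeds(config$seed, 2L * n)
  ns <- as.integer(round(config$segment_len_s * config$sample_rate_hz))
  p <- config$n_parcels
  m <- (p * (p + 1L)) %/% 2L

  counts <- integer(2L * n)
  rows <- vector("list", 2L * n)
  for (k in seq_len(2L * n)) {
    rows[[k]] <- with_seed(seeds[k], {
      nk <- sample(seq.int(rng[1], rng[2]), 1)
      counts[k] <- nk
      act <- active_edges(coupling, groups[k], config$sample_rate_hz)
      x <- simulate_segment_array(nk, p, ns, config$sample_rate_hz, act,
                                  config$noise_sd, config$noise_band_hz)
      batch_imcoh_features_cpp(x, config$sample_rate_hz, window_s, overlap,
                               band_hz[1], band_hz[2], absolute)
    })
  }
  X <- do.call(rbind, rows)
  ft <- feature_table(X,
                      labels = rep(groups, counts),
                      subject_ids = rep(ids, counts))
  list(features = ft,
       subjects = data.frame(subject_id = ids, group_label = groups,
                             n_segments = counts),
       ground_truth = ground_truth_edges(coupling),
       config = config, coupling = coupling)
}
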