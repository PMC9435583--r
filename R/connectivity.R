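# Per-segment functional connectivity: Welch cross-spectral density and
# band-averaged imaginary coherency, with node-to-parcel merging for users
# supplying finer source grids.

as_signal_matrix <- function(x) {
  if (inherits(x, "meg_segment")) x$signals else as.matrix(x)
}

#' Welch cross-spectral density of a segment
#'
#' Averaged cross-spectral density over Hann-tapered, demeaned windows
#' (Welch's method). With the default 1-s windows and 50% overlap, a 4-s
#' segment at 100 Hz yields 7 windows and a 1 Hz frequency grid from 0 to
#' 50 Hz. The result is Hermitian at every frequency with a real,
#' non-negative diagonal (the per-channel PSD).
#'
#' @param x A `meg_segment` or a channels x samples numeric matrix.
#' @param sample_rate_hz Sampling rate in Hz (taken from the segment when
#'   `x` is a `meg_segment`).
#' @param window_s Welch window length in seconds (default 1; sets the
#'   frequency resolution to `1 / window_s`).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return A `csd_estimate`: list with `csd` (complex array, channels x
#'   channels x frequencies), `freqs_hz`, and the estimator settings.
#' @export
estimate_csd <- function(x, sample_rate_hz = NULL, window_s = 1,
                         overlap = 0.5) {
  if (inherits(x, "meg_segment"))
    sample_rate_hz <- sample_rate_hz %||% x$sample_rate_hz
  if (is.null(sample_rate_hz)) stop("`sample_rate_hz` is required")
  m <- as_signal_matrix(x)
  if (!all(is.finite(m))) stop("signals must be finite")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  if (ncol(m) < window_s * sample_rate_hz)
    stop("segment is shorter than the analysis window")
  res <- welch_csd_cpp(t(m), sample_rate_hz, window_s, overlap)
  structure(list(csd = res$csd, freqs_hz = drop(res$freqs_hz),
                 sample_rate_hz = sample_rate_hz, window_s = window_s,
                 overlap = overlap),
            class = "csd_estimate")
}

#' Band-averaged imaginary-coherency FC matrix
#'
#' Coherency at frequency f is the normalised cross-spectrum
#' `C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`. The FC value of a channel
#' pair is the mean over the band's frequency bins of `|Im C_ij(f)|`
#' (or of the signed imaginary part when `absolute = FALSE`). The imaginary
#' part is insensitive to instantaneous (volume-conduction-like) mixing,
#' which is the reason this estimator is used. Entries lie in `[0, 1]`; the
#' diagonal is identically 0 because self-coherency is real.
#'
#' @param csd A `csd_estimate` from [estimate_csd()].
#' @param band_hz Analysis band `[low, high]` in Hz, endpoints included
#'   (default `c(1, 40)`).
#' @param absolute Average the absolute imaginary part per bin (default
#'   `TRUE`); signed averaging cancels across bins.
#' @return Symmetric channels x channels matrix with attribute `band_hz`.
#' @export
imaginary_coherency_fc <- function(csd, band_hz = c(1, 40), absolute = TRUE) {
  stopifnot(inherits(csd, "csd_estimate"))
  if (band_hz[1] < min(csd$freqs_hz) - 1e-9 ||
      band_hz[2] > max(csd$freqs_hz) + 1e-9)
    stop("`band_hz` lies outside the estimated frequency grid")
  fc <- imcoh_band_cpp(csd$csd, csd$freqs_hz, band_hz[1], band_hz[2],
                       absolute)
  attr(fc, "band_hz") <- band_hz
  fc
}

#' One-call FC matrix of a segment
#'
#' Fused [estimate_csd()] + [imaginary_coherency_fc()] for one segment,
#' using a single compiled pass that only accumulates the band bins.
#'
#' @inheritParams estimate_csd
#' @inheritParams imaginary_coherency_fc
#' @return Symmetric channels x channels FC matrix with attribute
#'   `band_hz`.
#' @export
segment_fc <- function(x, sample_rate_hz = NULL, window_s = 1, overlap = 0.5,
                       band_hz = c(1, 40), absolute = TRUE) {
  if (inherits(x, "meg_segment"))
    sample_rate_hz <- sample_rate_hz %||% x$sample_rate_hz
  if (is.null(sample_rate_hz)) stop("`sample_rate_hz` is required")
  m <- as_signal_matrix(x)
  if (!all(is.finite(m))) stop("signals must be finite")
  fc <- segment_imcoh_cpp(t(m), sample_rate_hz, window_s, overlap,
                          band_hz[1], band_hz[2], absolute)
  attr(fc, "band_hz") <- band_hz
  fc
}

#' Merge a node-level FC matrix to parcels
#'
#' For users supplying a source grid finer than the parcel scheme: the FC
#' value of a parcel pair is the mean of the node-level FC values over all
#' node pairs spanning the two parcels. Within-parcel (diagonal) values are
#' set to 0, consistent with the zero self-connectivity of imaginary
#' coherency.
#'
#' @param fc_nodes Symmetric nodes x nodes FC matrix.
#' @param parcel_of Integer vector, `parcel_of[node]` = parcel index in
#'   `1..n_parcels`; every parcel must receive at least one node.
#' @param n_parcels Number of parcels (default `max(parcel_of)`).
#' @return Symmetric `n_parcels` x `n_parcels` FC matrix.
#' @export
merge_to_parcels <- function(fc_nodes, parcel_of,
                             n_parcels = max(parcel_of)) {
  fc_nodes <- as.matrix(fc_nodes)
  parcel_of <- as.integer(parcel_of)
  if (length(parcel_of) != nrow(fc_nodes))
    stop("`parcel_of` must map every node")
  if (any(parcel_of < 1L) || any(parcel_of > n_parcels))
    stop("`parcel_of` entries must lie in 1..n_parcels")
  counts <- tabulate(parcel_of, nbins = n_parcels)
  if (any(counts == 0L))
    stop("every parcel must contain at least one node")
  M <- matrix(0, length(parcel_of), n_parcels)
  M[cbind(seq_along(parcel_of), parcel_of)] <- 1
  S <- t(M) %*% fc_nodes %*% M
  N <- outer(counts, counts)
  out <- S / N
  diag(out) <- 0
  out
}
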