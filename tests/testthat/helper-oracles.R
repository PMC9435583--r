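# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, without touching the package's code paths.

# Direct Welch CSD in base R (same estimator contract: Hann taper, demeaned
# windows, one-sided doubling).
oracle_welch_csd <- function(x, fs, window_s = 1, overlap = 0.5) {
  xt <- t(x)
  n <- nrow(xt); nc <- ncol(xt)
  nwin <- round(window_s * fs)
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, n - nwin + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  nf <- nwin %/% 2 + 1
  csd <- array(0 + 0i, c(nc, nc, nf))
  for (s in starts) {
    seg <- xt[s:(s + nwin - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Fw <- mvfft(seg * w)[1:nf, , drop = FALSE]
    for (f in 1:nf) csd[, , f] <- csd[, , f] + Fw[f, ] %*% t(Conj(Fw[f, ]))
  }
  csd <- csd / (length(starts) * sum(w^2) * fs)
  for (f in 2:nf) if (!(nwin %% 2 == 0 && f == nf)) csd[, , f] <- 2 * csd[, , f]
  list(csd = csd, freqs_hz = (0:(nf - 1)) * fs / nwin)
}

oracle_imcoh <- function(csd, freqs, band = c(1, 40), absolute = TRUE) {
  keep <- which(freqs >= band[1] & freqs <= band[2])
  nc <- dim(csd)[1]
  fc <- matrix(0, nc, nc)
  for (f in keep) {
    d <- Re(diag(csd[, , f]))
    im <- Im(csd[, , f]) / sqrt(outer(d, d))
    fc <- fc + if (absolute) abs(im) else im
  }
  fc <- fc / length(keep)
  diag(fc) <- 0
  fc
}

# Two-pass per-feature F-score straight from the definition.
oracle_fscore <- function(X, labels, positive = "CPS") {
  pos <- labels == positive
  vapply(seq_len(ncol(X)), function(i) {
    xp <- X[pos, i]; xn <- X[!pos, i]; xa <- X[, i]
    num <- (mean(xn) - mean(xa))^2 + (mean(xp) - mean(xa))^2
    den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
      sum((xn - mean(xn))^2) / (length(xn) - 1)
    if (den > 0) num / den else 0
  }, numeric(1))
}

# Segment count by brute force on a 1 ms grid (events drawn on a 10 ms
# lattice so grid and interval arithmetic agree exactly).
oracle_segment_count <- function(dur, events, pad = 10, cut = 10, keep = 4) {
  dt <- 1e-3
  n <- round(dur / dt)
  t0 <- (0:(n - 1)) * dt
  clean <- rep(TRUE, n)
  for (e in events) {
    lo <- max(e - pad, 0); hi <- min(e + pad, dur)
    clean[t0 >= lo - 1e-9 & t0 < hi - 1e-9] <- FALSE
  }
  r <- rle(clean)
  runs <- r$lengths[r$values] * dt
  sum(vapply(runs, function(len) {
    full <- floor(len / cut + 1e-9)
    rem <- len - full * cut
    full + (rem >= keep - 1e-9)
  }, numeric(1)))
}

# Band-limited test noise matching the generator's spectral support.
test_noise <- function(n, ncol, fs, band = c(1, 45)) {
  seizfc:::band_noise(n, ncol, fs, band)
}

# Small labelled feature table with random content.
random_ft <- function(n = 40, m = 30, seed = 1, n_subjects = 4) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * m), n, m),
                labels = rep(c("CPS", "SPS"), length.out = n),
                subject_ids = rep(sprintf("S%02d", seq_len(n_subjects)),
                                  length.out = n))
}
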