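// Welch cross-spectral density and band-averaged imaginary coherency.
// Signals arrive time-by-channel; windows are Hann-tapered, demeaned,
// and averaged with the usual one-sided PSD normalisation (the scale
// cancels in coherency but keeps the diagonal interpretable as a PSD).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static vec hann_window(uword n) {
  vec w(n);
  for (uword t = 0; t < n; ++t)
    w(t) = 0.5 - 0.5 * std::cos(2.0 * M_PI * (double)t / (double)(n - 1));
  return w;
}

// [[Rcpp::export]]
Rcpp::List welch_csd_cpp(const arma::mat& x, double fs, double window_s,
                         double overlap) {
  const uword n = x.n_rows, nc = x.n_cols;
  const uword nwin = (uword)std::lround(window_s * fs);
  if (nwin < 4) Rcpp::stop("analysis window too short");
  if (n < nwin) Rcpp::stop("segment shorter than the analysis window");
  uword step = (uword)std::lround((double)nwin * (1.0 - overlap));
  if (step < 1) step = 1;
  const uword nf = nwin / 2 + 1;
  const vec w = hann_window(nwin);
  const double U = accu(square(w));
  const uword nseg = (n - nwin) / step + 1;

  cx_cube csd(nc, nc, nf, fill::zeros);
  for (uword s = 0; s < nseg; ++s) {
    mat seg = x.rows(s * step, s * step + nwin - 1);
    seg.each_row() -= mean(seg, 0);
    seg.each_col() %= w;
    cx_mat Fw = fft(seg);
    for (uword f = 0; f < nf; ++f)
      csd.slice(f) += Fw.row(f).st() * conj(Fw.row(f));
  }
  csd /= (double)nseg * U * fs;
  // one-sided doubling, DC and Nyquist excepted
  for (uword f = 1; f < nf; ++f)
    if (!(nwin % 2 == 0 && f == nf - 1)) csd.slice(f) *= 2.0;

  vec freqs = regspace<vec>(0, (double)nf - 1) * fs / (double)nwin;
  return Rcpp::List::create(Rcpp::Named("csd") = csd,
                            Rcpp::Named("freqs_hz") = freqs);
}

// [[Rcpp::export]]
arma::mat imcoh_band_cpp(const arma::cx_cube& csd, const arma::vec& freqs,
                         double lo, double hi, bool absolute) {
  const uword nc = csd.n_rows;
  mat fc(nc, nc, fill::zeros);
  uword nb = 0;
  for (uword f = 0; f < freqs.n_elem; ++f) {
    if (freqs(f) < lo || freqs(f) > hi) continue;
    vec d = real(csd.slice(f).diag());
    if (any(d <= 0.0))
      Rcpp::stop("degenerate channel: zero auto-spectrum inside the band");
    mat den = sqrt(d * d.t());
    mat im = imag(csd.slice(f)) / den;
    fc += absolute ? abs(im) : im;
    ++nb;
  }
  if (nb == 0) Rcpp::stop("no frequency bins fall inside the band");
  fc /= (double)nb;
  fc.diag().zeros();
  return fc;
}

// Fused per-segment path: accumulates the CSD only on the band bins,
// reuses caller-owned workspaces, and never materialises the full cube on
// the R side. Identical (to rounding) to welch_csd_cpp + imcoh_band_cpp.
static std::vector<uword> band_bins(double fs, uword nwin, double lo,
                                    double hi) {
  const uword nf = nwin / 2 + 1;
  std::vector<uword> band;
  for (uword f = 0; f < nf; ++f) {
    double fr = (double)f * fs / (double)nwin;
    if (fr >= lo && fr <= hi) band.push_back(f);
  }
  if (band.empty()) Rcpp::stop("no frequency bins fall inside the band");
  return band;
}

static void imcoh_one(const arma::mat& x, double fs, double window_s,
                      double overlap, const std::vector<uword>& band,
                      bool absolute, arma::cx_cube& csd, arma::mat& fc) {
  const uword n = x.n_rows, nc = x.n_cols;
  const uword nwin = (uword)std::lround(window_s * fs);
  if (nwin < 4) Rcpp::stop("analysis window too short");
  if (n < nwin) Rcpp::stop("segment shorter than the analysis window");
  uword step = (uword)std::lround((double)nwin * (1.0 - overlap));
  if (step < 1) step = 1;
  const vec w = hann_window(nwin);
  const uword nseg = (n - nwin) / step + 1;
  const uword nb = band.size();

  csd.zeros();
  fc.zeros();
  for (uword s = 0; s < nseg; ++s) {
    mat seg = x.rows(s * step, s * step + nwin - 1);
    seg.each_row() -= mean(seg, 0);
    seg.each_col() %= w;
    cx_mat Fw = fft(seg);
    for (uword k = 0; k < nb; ++k)
      csd.slice(k) += Fw.row(band[k]).st() * conj(Fw.row(band[k]));
  }

  std::vector<double> invd(nc);
  for (uword k = 0; k < nb; ++k) {
    const cx_mat& S = csd.slice(k);
    for (uword c = 0; c < nc; ++c) {
      double d = S(c, c).real();
      if (d <= 0.0)
        Rcpp::stop("degenerate channel: zero auto-spectrum inside the band");
      invd[c] = 1.0 / std::sqrt(d);
    }
    for (uword c = 1; c < nc; ++c)
      for (uword r = 0; r < c; ++r) {
        double v = S(r, c).imag() * invd[r] * invd[c];
        fc(r, c) += absolute ? std::fabs(v) : v;
      }
  }
  fc /= (double)nb;
  // mirror: |Im C| is symmetric, the signed imaginary part antisymmetric
  for (uword c = 1; c < nc; ++c)
    for (uword r = 0; r < c; ++r)
      fc(c, r) = absolute ? fc(r, c) : -fc(r, c);
}

// [[Rcpp::export]]
arma::mat segment_imcoh_cpp(const arma::mat& x, double fs, double window_s,
                            double overlap, double lo, double hi,
                            bool absolute) {
  const uword nwin = (uword)std::lround(window_s * fs);
  if (nwin < 4) Rcpp::stop("analysis window too short");
  std::vector<uword> band = band_bins(fs, nwin, lo, hi);
  cx_cube csd(x.n_cols, x.n_cols, band.size());
  mat fc(x.n_cols, x.n_cols);
  imcoh_one(x, fs, window_s, overlap, band, absolute, csd, fc);
  return fc;
}

// Batch path for the cohort simulator: one slice per segment
// (n_samples x n_parcels x n_segments in, n_segments x p(p+1)/2 out,
// canonical lower-triangle feature order).
// [[Rcpp::export]]
arma::mat batch_imcoh_features_cpp(const arma::cube& x, double fs,
                                   double window_s, double overlap,
                                   double lo, double hi, bool absolute) {
  const uword nseg = x.n_slices, nc = x.n_cols;
  const uword m = nc * (nc + 1) / 2;
  const uword nwin = (uword)std::lround(window_s * fs);
  if (nwin < 4) Rcpp::stop("analysis window too short");
  std::vector<uword> band = band_bins(fs, nwin, lo, hi);
  cx_cube csd(nc, nc, band.size());
  mat fc(nc, nc);
  mat out(nseg, m);
  for (uword s = 0; s < nseg; ++s) {
    imcoh_one(x.slice(s), fs, window_s, overlap, band, absolute, csd, fc);
    uword k = 0;
    for (uword c = 0; c < nc; ++c)
      for (uword r = 0; r <= c; ++r) out(s, k++) = fc(r, c);
  }
  return out;
}
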