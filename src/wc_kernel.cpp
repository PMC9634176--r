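// Band-averaged wavelet coherence kernel used by the shuffled-surrogate
// null: the permutation loop evaluates the smoothed-coherence band mean
// thousands of times per session, so the inner transform runs in C++.
// Geometry (wavelet filters, Gaussian time-smoothing multipliers, boxcar
// width, band rows) is prepared in R and passed in; this file only
// executes it.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// smoothed-coherence band mean for one pair of (already permuted) series;
// filters/gmult arrive as complex matrices so every FFT runs column-wise
// over whole matrices
static double band_mean_one(const vec& x, const vec& y,
                            const cx_mat& filters, const cx_mat& gmult,
                            const vec& inv_scale, const ivec& band_rows,
                            int boxw) {
  const int nfft = filters.n_rows;
  const int ns = filters.n_cols;
  const int n = x.n_elem;

  cx_vec fx = fft(join_cols(x - mean(x), zeros<vec>(nfft - n)));
  cx_vec fy = fft(join_cols(y - mean(y), zeros<vec>(nfft - n)));

  // CWT of both series at every scale in two batched inverse FFTs
  cx_mat A = filters;
  A.each_col() %= fx;
  const cx_mat X = ifft(A);
  A = filters;
  A.each_col() %= fy;
  const cx_mat Y = ifft(A);

  // scale-normalized cross spectrum, and both auto spectra packed into
  // one complex matrix (real = |X|^2/s, imag = |Y|^2/s): the smoothing
  // kernel is real and symmetric, so it smooths both channels at once
  cx_mat Wxy(nfft, ns, fill::zeros), P(nfft, ns, fill::zeros);
  for (int j = 0; j < ns; ++j) {
    const double is = inv_scale[j];
    for (int i = 0; i < n; ++i) {
      const std::complex<double> a = X(i, j), b = Y(i, j);
      Wxy(i, j) = a * std::conj(b) * is;
      P(i, j) = std::complex<double>(std::norm(a) * is, std::norm(b) * is);
    }
  }

  // time smoothing: Gaussian of SD = scale, in the Fourier domain on the
  // zero-padded columns
  Wxy = fft(Wxy);
  Wxy %= gmult;
  Wxy = ifft(Wxy);
  P = fft(P);
  P %= gmult;
  P = ifft(P);

  // scale smoothing (boxcar) fused with the band average; the boxcar's
  // 1/m factors cancel between numerator and denominator
  const int h = boxw / 2;
  double acc = 0.0;
  long cnt = 0;
  for (uword bi = 0; bi < band_rows.n_elem; ++bi) {
    const int j = band_rows[bi];
    const int lo = std::max(0, j - h);
    const int hi = std::min(ns - 1, j + h);
    for (int i = 0; i < n; ++i) {
      std::complex<double> sxy(0.0, 0.0);
      double sxx = 0.0, syy = 0.0;
      for (int k = lo; k <= hi; ++k) {
        sxy += Wxy(i, k);
        sxx += P(i, k).real();
        syy += P(i, k).imag();
      }
      double w = std::norm(sxy) / (sxx * syy);
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      acc += w;
      ++cnt;
    }
  }
  return acc / cnt;
}

// [[Rcpp::export(name = ".wc_band_mean_cpp")]]
double wc_band_mean_cpp(const arma::vec& x, const arma::vec& y,
                        const arma::mat& filters, const arma::mat& gmult,
                        const arma::vec& inv_scale,
                        const arma::ivec& band_rows0, int boxw) {
  const cx_mat fc = conv_to<cx_mat>::from(filters);
  const cx_mat gc = conv_to<cx_mat>::from(gmult);
  return band_mean_one(x, y, fc, gc, inv_scale, band_rows0, boxw);
}

// [[Rcpp::export(name = ".wc_band_mean_perm_cpp")]]
arma::vec wc_band_mean_perm_cpp(const arma::vec& x, const arma::vec& y,
                                const arma::mat& filters,
                                const arma::mat& gmult,
                                const arma::vec& inv_scale,
                                const arma::ivec& band_rows0, int boxw,
                                const arma::imat& perm_x,
                                const arma::imat& perm_y) {
  const int n_iter = perm_x.n_cols;
  const int n = x.n_elem;
  const cx_mat fc = conv_to<cx_mat>::from(filters);
  const cx_mat gc = conv_to<cx_mat>::from(gmult);
  vec out(n_iter);
  vec xp(n), yp(n);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      xp[i] = x[perm_x(i, it) - 1];  // 1-based indices from R
      yp[i] = y[perm_y(i, it) - 1];
    }
    out[it] = band_mean_one(xp, yp, fc, gc, inv_scale, band_rows0, boxw);
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
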