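// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

// Sampled stretched Mexican-hat kernel, truncated at |dx|,|dy| <= box*a.
// Offsets are in pixel units with mesh spacing `step`; the returned matrix
// has odd side length 2*half+1 and is centred on the wavelet origin.
// xi = 1 recovers the isotropic Mexican hat for any theta.
// When `demean` is true the box mean is subtracted so the truncated,
// sampled kernel satisfies the zero-mean wavelet condition exactly on the
// mesh (a uniform image then transforms to exactly zero away from edges).
// [[Rcpp::export]]
arma::mat stretched_kernel_cpp(double a, double xi, double theta_deg,
                               double step, double box = 3.0,
                               bool demean = true) {
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const int half = (int)std::ceil(box * a / step);
  const int n = 2 * half + 1;
  arma::mat K(n, n);
  for (int j = 0; j < n; j++) {      // columns: x
    const double dx = (j - half) * step;
    for (int i = 0; i < n; i++) {    // rows: y
      const double dy = (i - half) * step;
      const double rp = dx * ct - dy * st;
      const double rq = dx * st + dy * ct;
      const double q = (rp * rp + rq * rq / (xi * xi)) / (a * a);
      K(i, j) = (2.0 - q) * std::exp(-q / 2.0);
    }
  }
  if (demean) K -= arma::accu(K) / (double)(n * (arma::uword)n);
  return K;
}

static int next_fast(int n) {
  // smallest integer >= n whose prime factors are all in {2,3,5}
  while (true) {
    int m = n;
    while (m % 2 == 0) m /= 2;
    while (m % 3 == 0) m /= 3;
    while (m % 5 == 0) m /= 5;
    if (m == 1) return n;
    n++;
  }
}

// "Same"-size correlation of img with a centred symmetric kernel, zero
// intensity assumed outside the image, computed by zero-padded FFT.
// Exactly equal (to roundoff) to the truncated direct sum because the
// kernel is already truncated. `scale` multiplies the result (dr/a).
// [[Rcpp::export]]
arma::mat corr_fft_cpp(const arma::mat& img, const arma::mat& kern,
                       double scale) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int kr = kern.n_rows, kc = kern.n_cols;
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  const int P = next_fast(nr + kr - 1), Q = next_fast(nc + kc - 1);
  arma::cx_mat FI = arma::fft2(img, P, Q);
  arma::cx_mat FK = arma::fft2(kern, P, Q);
  arma::cx_mat full = arma::ifft2(FI % FK);
  // kernel is even (two-fold symmetric), so convolution == correlation
  arma::mat out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      out(i, j) = scale * full(i + hr, j + hc).real();
  return out;
}

// Coefficient stack for one (a, xi) over many orientations.
// The image FFT is computed once and two real kernels are packed into the
// real/imaginary parts of a single complex FFT, so each orientation costs
// about half an FFT pair.  Results equal corr_fft_cpp slice by slice.
// [[Rcpp::export]]
arma::cube cwt_stack_cpp(const arma::mat& img, double a, double xi,
                         const arma::vec& thetas, double step,
                         double box = 3.0, bool demean = true) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int half = (int)std::ceil(box * a / step);
  const int kn = 2 * half + 1;
  const int P = next_fast(nr + kn - 1), Q = next_fast(nc + kn - 1);
  const double scale = step * step / a;
  arma::cx_mat FI = arma::fft2(img, P, Q);
  const int nt = thetas.n_elem;
  arma::cube out(nr, nc, nt);
  arma::cx_mat pair(P, Q);
  for (int t = 0; t < nt; t += 2) {
    const bool two = (t + 1 < nt);
    pair.zeros();
    arma::mat K1 = stretched_kernel_cpp(a, xi, thetas(t), step, box, demean);
    if (two) {
      arma::mat K2 = stretched_kernel_cpp(a, xi, thetas(t + 1), step, box,
                                          demean);
      pair.submat(0, 0, kn - 1, kn - 1) = arma::cx_mat(K1, K2);
    } else {
      pair.submat(0, 0, kn - 1, kn - 1) =
        arma::cx_mat(K1, arma::mat(kn, kn, arma::fill::zeros));
    }
    arma::cx_mat R = arma::ifft2(FI % arma::fft2(pair));
    for (int j = 0; j < nc; j++)
      for (int i = 0; i < nr; i++) {
        const std::complex<double> v = R(i + half, j + half);
        out(i, j, t) = scale * v.real();
        if (two) out(i, j, t + 1) = scale * v.imag();
      }
  }
  return out;
}

// Reference semantics: truncated direct sum (same contract as corr_fft_cpp).
// [[Rcpp::export]]
arma::mat corr_direct_cpp(const arma::mat& img, const arma::mat& kern,
                          double scale) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int kr = kern.n_rows, kc = kern.n_cols;
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double acc = 0.0;
      const int i0 = std::max(0, i - hr), i1 = std::min(nr - 1, i + hr);
      const int j0 = std::max(0, j - hc), j1 = std::min(nc - 1, j + hc);
      for (int jj = j0; jj <= j1; jj++)
        for (int ii = i0; ii <= i1; ii++)
          acc += img(ii, jj) * kern(ii - i + hr, jj - j + hc);
      out(i, j) = scale * acc;
    }
  }
  return out;
}

// Single coefficient T(a, b) at mesh point (row, col) (1-based indices)
// by the truncated direct sum on the image's own mesh.
// [[Rcpp::export]]
double cwt_point_cpp(const arma::mat& img, double a, double xi,
                     double theta_deg, int row, int col,
                     double step = 1.0, double box = 3.0,
                     bool demean = true) {
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const int half = (int)std::ceil(box * a / step);
  const int nr = img.n_rows, nc = img.n_cols;
  const int i0 = std::max(0, row - 1 - half), i1 = std::min(nr - 1, row - 1 + half);
  const int j0 = std::max(0, col - 1 - half), j1 = std::min(nc - 1, col - 1 + half);
  double m = 0.0;
  if (demean) {
    // mean over the full (unclipped) truncation box, matching the
    // demeaned kernel used by the field-wide transforms
    for (int j = -half; j <= half; j++) {
      const double dx = j * step;
      for (int i = -half; i <= half; i++) {
        const double dy = i * step;
        const double rp = dx * ct - dy * st;
        const double rq = dx * st + dy * ct;
        const double q = (rp * rp + rq * rq / (xi * xi)) / (a * a);
        m += (2.0 - q) * std::exp(-q / 2.0);
      }
    }
    const double n = 2.0 * half + 1.0;
    m /= n * n;
  }
  double acc = 0.0;
  for (int j = j0; j <= j1; j++) {
    const double dx = (j - (col - 1)) * step;
    for (int i = i0; i <= i1; i++) {
      const double dy = (i - (row - 1)) * step;
      const double rp = dx * ct - dy * st;
      const double rq = dx * st + dy * ct;
      const double q = (rp * rp + rq * rq / (xi * xi)) / (a * a);
      acc += img(i, j) * ((2.0 - q) * std::exp(-q / 2.0) - m);
    }
  }
  return acc * step * step / a;
}

// 4-connected component labelling of a logical mask.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      cur++;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = cur;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; k++) {
          const int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Render a sum of oriented anisotropic Gaussian blobs onto a frame.
// blobs: columns x, y, sigma_par, sigma_perp, theta_deg, amplitude, beta
// where beta is an offset of the blob centre along the +axis direction.
// [[Rcpp::export]]
arma::mat render_blobs_cpp(int nrow, int ncol, const arma::mat& blobs) {
  arma::mat out(nrow, ncol, arma::fill::zeros);
  for (arma::uword b = 0; b < blobs.n_rows; b++) {
    const double x0 = blobs(b, 0), y0 = blobs(b, 1);
    const double sp = blobs(b, 2), sq = blobs(b, 3);
    const double th = blobs(b, 4) * M_PI / 180.0;
    const double A = blobs(b, 5), beta = blobs(b, 6);
    const double ct = std::cos(th), st = std::sin(th);
    // centre shifted by beta along the axis (r_par direction)
    const double cx = x0 + beta * ct, cy = y0 - beta * st;
    const double ext = 4.0 * std::max(sp, sq);
    const int j0 = std::max(0, (int)std::floor(cx - ext) - 1);
    const int j1 = std::min(ncol - 1, (int)std::ceil(cx + ext) - 1);
    const int i0 = std::max(0, (int)std::floor(cy - ext) - 1);
    const int i1 = std::min(nrow - 1, (int)std::ceil(cy + ext) - 1);
    for (int j = j0; j <= j1; j++) {
      const double dx = (j + 1) - cx;
      for (int i = i0; i <= i1; i++) {
        const double dy = (i + 1) - cy;
        const double rp = dx * ct - dy * st;
        const double rq = dx * st + dy * ct;
        out(i, j) += A * std::exp(-rp * rp / (2 * sp * sp)
                                  - rq * rq / (2 * sq * sq));
      }
    }
  }
  return out;
}
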