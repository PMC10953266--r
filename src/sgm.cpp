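#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gamma-shaped ensemble response, Fourier domain: F(w) = 1/(1 + i w tau)^2.
// tau in seconds, w in rad/s.
static inline cx_double gamma_ft(double w, double tau) {
  cx_double d(1.0, w * tau);
  return cx_double(1.0, 0.0) / (d * d);
}

// Local E-I transfer function H_local(w) = X_e + X_i for unit white drive.
// All time constants in seconds.
static inline cx_double local_transfer_c(double w, double tau_e, double tau_i,
                                         double g_ei, double g_ii,
                                         double g_ee) {
  const cx_double iw(0.0, w);
  const cx_double Fe = gamma_ft(w, tau_e);
  const cx_double Fi = gamma_ft(w, tau_i);
  const cx_double a = iw + (g_ee / tau_e) * Fe;
  const cx_double b = (g_ei / tau_e) * Fe;
  const cx_double c = (g_ei / tau_i) * Fi;
  const cx_double d = iw + (g_ii / tau_i) * Fi;
  const cx_double det = a * d + b * c;
  return ((d - b) + (c + a)) / det;
}

// Assemble A(w) = i w I + (F_G(w)/tau_g) L(w) in place.
static void build_system(cx_mat& A, const mat& wnorm, const mat& delay,
                         double w, double alpha, cx_double c) {
  const uword n = wnorm.n_rows;
  const double* wn = wnorm.memptr();
  const double* dl = delay.memptr();
  cx_double* a = A.memptr();
  for (uword k = 0; k < n * n; ++k) {
    const double mag = alpha * wn[k];
    const double ph = w * dl[k];
    a[k] = c * cx_double(-mag * std::cos(ph), mag * std::sin(ph));
  }
  A.diag() += cx_double(0.0, w) + c;
}

// Network frequency response. With iid_drive = false, columns of `drive`
// are per-frequency complex drive vectors and the response is
// G(w) H drive (used for surrogate time series and the printed scalar-
// drive form). With iid_drive = true the expected PSD under independent
// per-region unit white noise is returned: sqrt(rowsum |G|^2) |H| as a
// real-valued magnitude (stored in the complex output).
//' @noRd
// [[Rcpp::export(name = ".sgm_response_cpp")]]
arma::cx_mat sgm_response_cpp(const arma::mat& wnorm, const arma::mat& dist_mm,
                              const arma::vec& freqs, double tau_e,
                              double tau_i, double tau_g, double g_ei,
                              double g_ii, double g_ee, double alpha, double v,
                              const arma::cx_mat& drive,
                              bool iid_drive = false) {
  const uword n = wnorm.n_rows;
  const uword nf = freqs.n_elem;
  cx_mat out(n, nf);
  // delay (s) between regions j,k: dist_mm / (1000 * v)
  const mat delay = dist_mm / (1000.0 * v);
  cx_mat A(n, n), G(n, n);
  for (uword m = 0; m < nf; ++m) {
    const double w = 2.0 * M_PI * freqs(m);
    const cx_double Fg = gamma_ft(w, tau_g);
    const cx_double H = local_transfer_c(w, tau_e, tau_i, g_ei, g_ii, g_ee);
    build_system(A, wnorm, delay, w, alpha, Fg / tau_g);
    if (iid_drive) {
      if (!inv(G, A)) { out.fill(datum::nan); return out; }
      const vec rms = sqrt(sum(square(abs(G)), 1)) * std::abs(H);
      out.col(m) = conv_to<cx_vec>::from(rms);
    } else {
      out.col(m) = solve(A, H * drive.col(m),
                         solve_opts::fast + solve_opts::no_approx);
    }
  }
  return out;
}

// Fast fitting objective: -(spectral + spatial correlation) of the SGM
// forward prediction against a fixed empirical PSD. emp_c holds the
// row-centered empirical dB spectra (cortical regions x freqs) with
// row norms emp_norm; smooth_y is M %*% zscore(empirical alpha power),
// so the spatial term reduces to dot(zscore(model alpha power),
// smooth_y) / n_cort. Returns 4.0 (worse than any correlation sum) on
// non-finite or degenerate responses.
//' @noRd
// [[Rcpp::export(name = ".sgm_objective_cpp")]]
double sgm_objective_cpp(const arma::mat& wnorm, const arma::mat& dist_mm,
                         const arma::vec& freqs, const arma::vec& par,
                         const arma::uvec& mask_idx,
                         const arma::mat& emp_c, const arma::vec& emp_norm,
                         const arma::uvec& band_idx,
                         const arma::vec& smooth_y) {
  const double tau_e = par(0) / 1000.0, tau_i = par(1) / 1000.0;
  const double alpha = par(2), v = par(3);
  const double g_ei = par(4), g_ii = par(5);
  const double tau_g = par(6) / 1000.0, g_ee = 1.0;
  const uword n = wnorm.n_rows, nf = freqs.n_elem;
  const uword nc = mask_idx.n_elem;
  const mat delay = dist_mm / (1000.0 * v);

  mat db(nc, nf);
  mat pow_band(nc, band_idx.n_elem);
  cx_mat A(n, n), G(n, n);
  uword bcol = 0;
  for (uword m = 0; m < nf; ++m) {
    const double w = 2.0 * M_PI * freqs(m);
    const cx_double Fg = gamma_ft(w, tau_g);
    const cx_double H = local_transfer_c(w, tau_e, tau_i, g_ei, g_ii, g_ee);
    build_system(A, wnorm, delay, w, alpha, Fg / tau_g);
    if (!inv(G, A)) return 4.0;
    const double habs = std::abs(H);
    const bool in_band = bcol < band_idx.n_elem && band_idx(bcol) == m;
    for (uword j = 0; j < nc; ++j) {
      const double mg =
          std::sqrt(accu(square(abs(G.row(mask_idx(j)))))) * habs;
      if (!std::isfinite(mg) || mg <= 0.0) return 4.0;
      db(j, m) = 20.0 * std::log10(mg);
      if (in_band) pow_band(j, bcol) = mg * mg;
    }
    if (in_band) ++bcol;
  }
  // spectral correlation: mean Pearson of db rows vs emp_c rows
  double sc = 0.0;
  for (uword j = 0; j < nc; ++j) {
    rowvec r = db.row(j) - mean(db.row(j));
    const double nr = norm(r, 2);
    if (nr <= 0.0) return 4.0;
    sc += dot(r, emp_c.row(j)) / (nr * emp_norm(j));
  }
  sc /= nc;
  // spatial correlation: zscore model alpha power, dot with smooth_y / nc
  vec mp = sum(pow_band, 1);
  const double mmean = mean(mp);
  const double msd = std::sqrt(mean(square(mp - mmean)));
  if (msd <= 0.0 || !std::isfinite(msd)) return 4.0;
  const double sp = dot((mp - mmean) / msd, smooth_y) / nc;
  const double val = -(sc + sp);
  return std::isfinite(val) ? val : 4.0;
}
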