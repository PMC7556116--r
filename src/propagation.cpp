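// Dense-matrix propagation primitives for small spin systems (<= 2^9).
// Piecewise-constant Hamiltonians are exponentiated exactly through
// Hermitian eigendecomposition; multi-period evolution reuses powers of the
// one-rotor-period propagator.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static cx_mat step_exponential(const cx_mat& H, double dt) {
  vec eval;
  cx_mat evec;
  eig_sym(eval, evec, H);
  cx_vec phase = exp(cx_double(0.0, -1.0) * conv_to<cx_vec>::from(eval) * dt);
  return evec * diagmat(phase) * evec.t();
}

// Propagator over one rotor period (or an arbitrary piecewise-constant
// schedule): H(step s) = H0 + sum_k coeff(s, k) * A_k, each step of length dt.
// [[Rcpp::export]]
arma::cx_mat propagate_piecewise_cpp(const arma::cx_mat& H0,
                                     const Rcpp::List& ops,
                                     const arma::mat& coeff,
                                     double dt) {
  const int n_steps = coeff.n_rows;
  const int n_ops = coeff.n_cols;
  cx_mat U(H0.n_rows, H0.n_cols, fill::eye);
  for (int s = 0; s < n_steps; ++s) {
    cx_mat H = H0;
    for (int k = 0; k < n_ops; ++k) {
      double c = coeff(s, k);
      if (c != 0.0) H += c * Rcpp::as<cx_mat>(ops[k]);
    }
    U = step_exponential(H, dt) * U;
  }
  return U;
}

static cx_mat mat_power(const cx_mat& U, long k) {
  cx_mat result(U.n_rows, U.n_cols, fill::eye);
  cx_mat base = U;
  while (k > 0) {
    if (k & 1L) result = result * base;
    base = base * base;
    k >>= 1;
  }
  return result;
}

// Rotor-synchronized spin echo: for each half-echo length of k rotor periods,
// amplitude = Re Tr(D * (U^k P U^k) rho (U^k P U^k)^dagger), normalized later
// in R against k = 0.
// [[Rcpp::export]]
arma::vec echo_amplitudes_cpp(const arma::cx_mat& Urot,
                              const arma::cx_mat& Ppulse,
                              const arma::cx_mat& rho0,
                              const arma::cx_mat& Dop,
                              const arma::ivec& k_half) {
  const int npts = k_half.n_elem;
  vec amps(npts);
  for (int p = 0; p < npts; ++p) {
    cx_mat Uk = mat_power(Urot, k_half(p));
    cx_mat E = Uk * Ppulse * Uk;
    cx_mat rho = E * rho0 * E.t();
    amps(p) = real(trace(Dop * rho));
  }
  return amps;
}

// Site-resolved (peak-height) spin echo: the echo amplitude is the
// Lorentzian-weighted sum of transition sticks around the resonance
// position nu0, i.e. the spectral peak intensity that a site-specific decay
// measurement follows. Components dephased into broad wings by coherent
// multi-spin terms do not contribute.
// [[Rcpp::export]]
arma::vec echo_peak_amplitudes_cpp(const arma::cx_mat& Urot,
                                   const arma::cx_mat& Ppulse,
                                   const arma::cx_mat& rho0,
                                   const arma::cx_mat& Dop,
                                   const arma::ivec& k_half,
                                   double period,
                                   double lb,
                                   double nu0) {
  cx_vec lambda;
  cx_mat V;
  eig_gen(lambda, V, Urot);
  cx_mat Vi = inv(V);
  cx_mat Dpp = Vi * Dop * V;
  vec theta = arg(lambda);
  const int n = lambda.n_elem;
  mat L(n, n);
  const double hw = lb / 2.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dth = theta(j) - theta(i);
      while (dth > M_PI) dth -= 2.0 * M_PI;
      while (dth <= -M_PI) dth += 2.0 * M_PI;
      double nu = dth / (2.0 * M_PI * period);
      L(i, j) = hw * hw / ((nu - nu0) * (nu - nu0) + hw * hw);
    }
  }
  const int npts = k_half.n_elem;
  vec amps(npts);
  for (int p = 0; p < npts; ++p) {
    cx_mat Uk = mat_power(Urot, k_half(p));
    cx_mat E = Uk * Ppulse * Uk;
    cx_mat rhoe = E * rho0 * E.t();
    cx_mat rpp = Vi * rhoe * V;
    amps(p) = accu(real(Dpp % rpp.st()) % L);
  }
  return amps;
}

// Stick spectrum of stroboscopic (rotor-synchronized) detection:
// a(p) = Tr(D U^p rho U^-p) = sum_ij w_ij exp(i (th_j - th_i) p), where
// U = V diag(lambda) V^-1. Frequencies are returned in Hz within the
// +-1/(2 T) window; weights are complex (detection operator is typically I+).
// [[Rcpp::export]]
Rcpp::List strobe_sticks_cpp(const arma::cx_mat& U,
                             const arma::cx_mat& rho0,
                             const arma::cx_mat& Dop,
                             double period,
                             double weight_tol) {
  cx_vec lambda;
  cx_mat V;
  eig_gen(lambda, V, U);
  cx_mat Vi = inv(V);
  cx_mat Dp = Vi * Dop * V;
  cx_mat rp = Vi * rho0 * V;
  vec theta = arg(lambda);
  const int n = lambda.n_elem;
  std::vector<double> freqs;
  std::vector<double> wre, wim;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      cx_double w = Dp(i, j) * rp(j, i);
      if (std::abs(w) > weight_tol) {
        double dth = theta(j) - theta(i);
        // wrap to (-pi, pi]
        while (dth > M_PI) dth -= 2.0 * M_PI;
        while (dth <= -M_PI) dth += 2.0 * M_PI;
        freqs.push_back(dth / (2.0 * M_PI * period));
        wre.push_back(w.real());
        wim.push_back(w.imag());
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("freq") = freqs,
                            Rcpp::Named("w_re") = wre,
                            Rcpp::Named("w_im") = wim);
}

// Stick spectrum of a static Hamiltonian: transition frequencies from
// eigenvalue differences (rad/s -> Hz), no aliasing window.
// [[Rcpp::export]]
Rcpp::List static_sticks_cpp(const arma::cx_mat& H,
                             const arma::cx_mat& rho0,
                             const arma::cx_mat& Dop,
                             double weight_tol) {
  vec eval;
  cx_mat V;
  eig_sym(eval, V, H);
  cx_mat Dp = V.t() * Dop * V;
  cx_mat rp = V.t() * rho0 * V;
  const int n = eval.n_elem;
  std::vector<double> freqs;
  std::vector<double> wre, wim;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      cx_double w = Dp(i, j) * rp(j, i);
      if (std::abs(w) > weight_tol) {
        freqs.push_back((eval(i) - eval(j)) / (2.0 * M_PI));
        wre.push_back(w.real());
        wim.push_back(w.imag());
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("freq") = freqs,
                            Rcpp::Named("w_re") = wre,
                            Rcpp::Named("w_im") = wim);
}
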