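// Variational mode decomposition, ADMM solver in the frequency domain.
// Operates on the mirror-extended signal (half the length reflected at each
// end) and crops after inversion to suppress edge ringing. Only the
// positive-frequency half-spectrum is stored during iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".vmd_core")]]
Rcpp::List vmd_core(const arma::vec& signal,
                    int K,
                    double alpha,
                    double tau,
                    double tol,
                    int max_iter,
                    std::string init,
                    bool dc_mode,
                    int seed,
                    Rcpp::NumericVector omega_init) {
  const int N = signal.n_elem;
  const int h = N / 2;        // left mirror length
  const int h2 = N - h;       // right mirror length
  const int T = 2 * N;
  const int half = T / 2;     // active (nonnegative-frequency) bins

  // mirror extension: [flip(f[0:h-1]), f, flip(f[N-h2:N-1])]
  vec f(T);
  for (int i = 0; i < h; ++i) f(i) = signal(h - 1 - i);
  for (int i = 0; i < N; ++i) f(h + i) = signal(i);
  for (int i = 0; i < h2; ++i) f(h + N + i) = signal(N - 1 - i);

  // frequency axis after fftshift: freqs(j) = (j+1)/T - 0.5 - 1/T;
  // the top half (bins half..T-1) covers [0, 0.5) cycles/sample
  vec freqs_top(half);
  for (int j = 0; j < half; ++j) {
    freqs_top(j) = (double)(half + j + 1) / T - 0.5 - 1.0 / T;
  }

  cx_vec f_hat_full = fft(conv_to<cx_vec>::from(f));
  // fftshifted positive half: shifted index j corresponds to full index
  // (j + half) mod T; for j >= half that is j - half
  cx_vec f_top(half);
  for (int j = 0; j < half; ++j) f_top(j) = f_hat_full(j);

  // center-frequency initialization (cycles/sample)
  vec omega(K, fill::zeros);
  if (init == "given" && omega_init.size() == K) {
    for (int k = 0; k < K; ++k) omega(k) = omega_init[k];
  } else if (init == "uniform") {
    for (int k = 0; k < K; ++k) omega(k) = (0.5 / K) * k;
  } else if (init == "random") {
    std::mt19937 rng(seed);
    std::uniform_real_distribution<double> unif(0.0, 0.5);
    for (int k = 0; k < K; ++k) omega(k) = unif(rng);
    omega = sort(omega);
  }
  if (dc_mode) omega(0) = 0.0;

  cx_mat U(half, K, fill::zeros);      // mode half-spectra
  cx_vec lam(half, fill::zeros);       // dual variable (half-spectrum)
  cx_vec sum_top(half, fill::zeros);   // running sum of all modes but one

  int n_iter = 0;
  bool converged = false;
  const double alpha2 = 2.0 * alpha;

  for (int n = 0; n < max_iter; ++n) {
    double num = 0.0, den = 0.0;
    for (int k = 0; k < K; ++k) {
      sum_top += U.col(k == 0 ? K - 1 : k - 1) - U.col(k);
      cx_vec old = U.col(k);
      U.col(k) = (f_top - sum_top - lam / 2.0) /
                 (1.0 + alpha2 * square(freqs_top - omega(k)));
      if (!(dc_mode && k == 0)) {
        vec p = square(abs(U.col(k)));
        double ptot = accu(p);
        if (ptot > 0.0) omega(k) = dot(freqs_top, p) / ptot;
      }
      num += std::pow(norm(U.col(k) - old), 2);
      den += std::pow(norm(old), 2);
    }
    if (tau > 0.0) lam += tau * (sum(U, 1) - f_top);
    n_iter = n + 1;
    if (n > 0 && num / (den + 1e-300) < tol) { converged = true; break; }
  }

  // hermitian symmetrization, inverse transform, crop the center N samples.
  // full (unshifted) spectrum: bins 0..half-1 are the positive side.
  mat imfs(K, N);
  for (int k = 0; k < K; ++k) {
    cx_vec spec(T, fill::zeros);
    for (int j = 0; j < half; ++j) spec(j) = U(j, k);
    for (int j = 1; j < half; ++j) spec(T - j) = std::conj(U(j, k));
    vec u = real(ifft(spec));
    for (int i = 0; i < N; ++i) imfs(k, i) = u(h + i);
  }

  return Rcpp::List::create(
      Rcpp::Named("imfs") = imfs,
      Rcpp::Named("omega") = omega,   // cycles/sample
      Rcpp::Named("n_iters") = n_iter,
      Rcpp::Named("converged") = converged);
}
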