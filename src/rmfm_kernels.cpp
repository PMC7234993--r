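#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal population transfer function H(x) = (a*x - b) / (1 - exp(-d*(a*x - b))).
// The singularity at a*x = b is removable; a short series keeps the evaluation
// stable in its neighbourhood: H = 1/d + y/2 + d*y^2/12 + O(y^3), y = a*x - b.
inline double firing_rate_scalar(double x, double a, double b, double d) {
  double y = a * x - b;
  if (std::fabs(y) < 1e-4) {
    return 1.0 / d + y / 2.0 + d * y * y / 12.0;
  }
  return y / (1.0 - std::exp(-d * y));
}

// [[Rcpp::export]]
NumericVector cpp_firing_rate(NumericVector x, double a, double b, double d) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = firing_rate_scalar(x[i], a, b, d);
  return out;
}

// Total input current x_i = w_i*J*S_i + G*J*sum_j C_ij*S_j + I_i.
// C has zero diagonal by contract, so the network sum excludes self-input.
static void input_current_inplace(const double* C, const double* S,
                                  const double* w, const double* I,
                                  double G, double J, int N, double* x) {
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    const double* Ci = C + (size_t)i * N; // column i of column-major C == row i (symmetric)
    for (int j = 0; j < N; ++j) acc += Ci[j] * S[j];
    x[i] = w[i] * J * S[i] + G * J * acc + I[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_input_current(NumericMatrix C, NumericVector S,
                                NumericVector w, NumericVector I,
                                double G, double J) {
  int N = C.nrow();
  NumericVector x(N);
  input_current_inplace(C.begin(), S.begin(), w.begin(), I.begin(), G, J, N,
                        x.begin());
  return x;
}

// Euler-Maruyama integration of dS_i = (-S_i/tau_s + r*(1-S_i)*H(x_i)) dt
// + sigma*sqrt(dt)*dW_i, with S clamped to [0,1] after each step.
// Noise is drawn from R's RNG (one standard normal per region per step, in
// region order), so set.seed() on the R side fixes the trajectory.
// Returns the trajectory at every `thin`-th step (state after the update).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_neural(NumericMatrix C, NumericVector w,
                                  NumericVector I, double G, double sigma,
                                  double J, double a, double b, double d,
                                  double tau_s, double r_kin, double dt,
                                  int n_steps, NumericVector S0, int thin) {
  int N = C.nrow();
  int n_out = n_steps / thin;
  NumericMatrix out(n_out, N);
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> x(N);
  double sqdt = std::sqrt(dt);
  RNGScope scope;
  int row = 0;
  for (int t = 1; t <= n_steps; ++t) {
    input_current_inplace(C.begin(), S.data(), w.begin(), I.begin(), G, J, N,
                          x.data());
    for (int i = 0; i < N; ++i) {
      double drift = -S[i] / tau_s +
                     r_kin * (1.0 - S[i]) * firing_rate_scalar(x[i], a, b, d);
      double Si = S[i] + dt * drift;
      if (sigma > 0.0) Si += sigma * sqdt * norm_rand();
      if (Si < 0.0) Si = 0.0;
      if (Si > 1.0) Si = 1.0;
      S[i] = Si;
    }
    if (t % thin == 0) {
      for (int i = 0; i < N; ++i) out(row, i) = S[i];
      ++row;
    }
  }
  return out;
}

// One explicit-Euler step of the Balloon-Windkessel system for all regions.
// State per region: vasodilatory signal s, inflow f, venous volume v,
// deoxyhemoglobin q; neural drive z.
static inline void bw_step(double z, double dt, double kappa, double gamma_f,
                           double tau_v, double inv_alpha, double rho,
                           double log1mrho, double& s, double& f, double& v,
                           double& q) {
  double fout = std::exp(inv_alpha * std::log(v)); // v^(1/alpha)
  double E = 1.0 - std::exp(log1mrho / f);         // 1-(1-rho)^(1/f)
  double ds = z - kappa * s - gamma_f * (f - 1.0);
  double df = s;
  double dv = (f - fout) / tau_v;
  double dq = (f * E / rho - fout * q / v) / tau_v;
  s += dt * ds;
  f += dt * df;
  v += dt * dv;
  q += dt * dq;
  if (f < 1e-6) f = 1e-6;
  if (v < 1e-6) v = 1e-6;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_bold(NumericMatrix S, double dt, double kappa,
                                double gamma_f, double tau_v, double alpha,
                                double rho, double V0, double k1, double k2,
                                double k3, int stride) {
  int T = S.nrow(), N = S.ncol();
  NumericMatrix y(T, N);
  double inv_alpha = 1.0 / alpha;
  double log1mrho = std::log(1.0 - rho);
  double dt_h = dt * stride;
  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    double yi = 0.0;
    for (int t = 0; t < T; ++t) {
      if ((t + 1) % stride == 0) {
        bw_step(S(t, i), dt_h, kappa, gamma_f, tau_v, inv_alpha, rho,
                log1mrho, s, f, v, q);
        if (!std::isfinite(q) || !std::isfinite(v)) {
          stop("hemodynamic state became non-finite in region %d at step %d",
               i + 1, t + 1);
        }
        yi = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      }
      y(t, i) = yi;
    }
  }
  return y;
}

// Fused neural + hemodynamic integration that only stores BOLD at scan
// resolution: after `burn_steps` neural steps, every `keep_every`-th step is
// emitted. Bit-identical to chaining cpp_simulate_neural (thin = 1),
// cpp_simulate_bold and the TR downsampler, but without materialising the
// full-rate trajectories; this is the path the model inversion hammers.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_bold_tr(NumericMatrix C, NumericVector w,
                                   NumericVector I, double G, double sigma,
                                   double J, double a, double b, double d,
                                   double tau_s, double r_kin, double dt,
                                   int n_steps, NumericVector S0,
                                   int burn_steps, int keep_every,
                                   double kappa, double gamma_f, double tau_v,
                                   double alpha, double rho, double V0,
                                   double k1, double k2, double k3,
                                   int stride) {
  int N = C.nrow();
  int n_keep = (n_steps - burn_steps) / keep_every;
  if (n_keep < 0) n_keep = 0;
  NumericMatrix y(n_keep, N);
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> x(N), hs(N, 0.0), hf(N, 1.0), hv(N, 1.0), hq(N, 1.0);
  double sqdt = std::sqrt(dt);
  double inv_alpha = 1.0 / alpha;
  double log1mrho = std::log(1.0 - rho);
  double dt_h = dt * stride;
  RNGScope scope;
  int row = 0;
  for (int t = 1; t <= n_steps; ++t) {
    input_current_inplace(C.begin(), S.data(), w.begin(), I.begin(), G, J, N,
                          x.data());
    bool bw_now = t % stride == 0;
    for (int i = 0; i < N; ++i) {
      double drift = -S[i] / tau_s +
                     r_kin * (1.0 - S[i]) * firing_rate_scalar(x[i], a, b, d);
      double Si = S[i] + dt * drift;
      if (sigma > 0.0) Si += sigma * sqdt * norm_rand();
      if (Si < 0.0) Si = 0.0;
      if (Si > 1.0) Si = 1.0;
      S[i] = Si;
      if (bw_now) {
        bw_step(Si, dt_h, kappa, gamma_f, tau_v, inv_alpha, rho, log1mrho,
                hs[i], hf[i], hv[i], hq[i]);
      }
    }
    bool keep = t > burn_steps && (t - burn_steps) % keep_every == 0;
    if (keep && row < n_keep) {
      for (int i = 0; i < N; ++i) {
        double qi = hq[i], vi = hv[i];
        if (!std::isfinite(qi) || !std::isfinite(vi)) {
          stop("hemodynamic state became non-finite in region %d at step %d",
               i + 1, t);
        }
        y(row, i) =
            V0 * (k1 * (1.0 - qi) + k2 * (1.0 - qi / vi) + k3 * (1.0 - vi));
      }
      ++row;
    }
  }
  return y;
}
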