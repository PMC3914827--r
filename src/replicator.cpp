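// Batched fixed-step RK4 integration of replicator dynamics on the simplex.
// States are rows of F (n trajectories x K phenotypes); after every step the
// state is clamped to non-negative values and renormalised to sum one.

#include <Rcpp.h>
using namespace Rcpp;

// field: df_i = f_i * ((M f)_i - f' M f), written into out
static inline void repl_field(const double* f, const double* M, int K,
                              double* g, double* out) {
  double phi = 0.0;
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < K; ++j) s += M[i + j * K] * f[j];
    g[i] = s;
    phi += f[i] * s;
  }
  for (int i = 0; i < K; ++i) out[i] = f[i] * (g[i] - phi);
}

// [[Rcpp::export(name = ".replicator_rk4")]]
List replicator_rk4(NumericMatrix M, NumericMatrix F0, double dt,
                    double max_steps, double tol, int record_every) {
  const int n = F0.nrow(), K = F0.ncol();
  if (M.nrow() != K || M.ncol() != K) stop("M must be K x K");
  NumericMatrix F = clone(F0);
  std::vector<double> g(K), k1(K), k2(K), k3(K), k4(K), tmp(K);
  std::vector<double> row(K);
  std::vector<double> rec_times;
  std::vector<double> rec_states; // row-major blocks of n*K per record
  LogicalVector converged(n);
  bool all_done = false;
  double steps_done = 0.0;

  if (record_every > 0) {
    rec_times.push_back(0.0);
    for (int r = 0; r < n; ++r)
      for (int j = 0; j < K; ++j) rec_states.push_back(F(r, j));
  }

  for (double s = 1.0; s <= max_steps; s += 1.0) {
    double vmax = 0.0;
    // first stage doubles as the convergence measure
    bool any_active = false;
    for (int r = 0; r < n; ++r) {
      for (int j = 0; j < K; ++j) row[j] = F(r, j);
      repl_field(row.data(), M.begin(), K, g.data(), k1.data());
      double m = 0.0;
      for (int j = 0; j < K; ++j) m = std::max(m, std::fabs(k1[j]));
      if (m > vmax) vmax = m;
      if (m >= tol) any_active = true;
      // RK4 stages
      for (int j = 0; j < K; ++j) tmp[j] = row[j] + 0.5 * dt * k1[j];
      repl_field(tmp.data(), M.begin(), K, g.data(), k2.data());
      for (int j = 0; j < K; ++j) tmp[j] = row[j] + 0.5 * dt * k2[j];
      repl_field(tmp.data(), M.begin(), K, g.data(), k3.data());
      for (int j = 0; j < K; ++j) tmp[j] = row[j] + dt * k3[j];
      repl_field(tmp.data(), M.begin(), K, g.data(), k4.data());
      double sum = 0.0;
      for (int j = 0; j < K; ++j) {
        double v = row[j] + dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (v < 0.0) v = 0.0;
        tmp[j] = v;
        sum += v;
      }
      if (!(sum > 0.0) || !std::isfinite(sum))
        stop("non-finite replicator state at step %g", s);
      for (int j = 0; j < K; ++j) F(r, j) = tmp[j] / sum;
    }
    steps_done = s;
    if (record_every > 0 && (((long long)s) % record_every == 0)) {
      rec_times.push_back(s * dt);
      for (int r = 0; r < n; ++r)
        for (int j = 0; j < K; ++j) rec_states.push_back(F(r, j));
    }
    if (vmax < tol) { all_done = true; break; }
    if (!any_active) { all_done = true; break; }
  }

  // per-trajectory convergence at the final state
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < K; ++j) row[j] = F(r, j);
    repl_field(row.data(), M.begin(), K, g.data(), k1.data());
    double m = 0.0;
    for (int j = 0; j < K; ++j) m = std::max(m, std::fabs(k1[j]));
    converged[r] = m < tol;
  }

  List out = List::create(_["F"] = F, _["steps"] = steps_done,
                          _["converged"] = converged,
                          _["all_done"] = all_done);
  if (record_every > 0) {
    int nt = rec_times.size();
    NumericVector times(rec_times.begin(), rec_times.end());
    NumericVector st(rec_states.begin(), rec_states.end());
    st.attr("dim") = IntegerVector::create(K, n, nt); // filled K-fastest
    out["times"] = times;
    out["states"] = st;
  }
  return out;
}
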