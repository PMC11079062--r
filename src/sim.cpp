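#include <Rcpp.h>
using namespace Rcpp;

struct Pars {
  double tau_e, tau_i, tau_a, g_e, g_i, th_e, th_i;
  double w_ee, w_ei, w_ie, w_ii, w_ea, w_ae;
  double cap;
};

static inline double omega_cap(double x, double g, double th, double cap) {
  double y = g * (x - th);
  if (y <= 0.0) return 0.0;
  return (y >= cap) ? cap : y;
}

// deterministic drift at frozen noise/drive (noise enters the response
// argument, so it is part of the "current", not additive on dE/dt)
static inline void deriv(const Pars &p, double E, double I, double A,
                         double xe, double xi, double ie,
                         double &dE, double &dI, double &dA) {
  dE = (-E + omega_cap(p.w_ee * E - p.w_ei * I - p.w_ea * A + xe + ie,
                       p.g_e, p.th_e, p.cap)) / p.tau_e;
  dI = (-I + omega_cap(p.w_ie * E - p.w_ii * I + xi, p.g_i, p.th_i, p.cap)) / p.tau_i;
  dA = (-A + p.w_ae * E) / p.tau_a;
}

// Integrate one network for n_steps of dt (ms).
//
// The noise current is an exactly discretized Ornstein-Uhlenbeck process
// (stationary SD `sigma`, correlation time `tau_noise` ms) feeding the
// excitatory response argument; the inhibitory population receives
// `sigma_i_frac` times an independent OU stream (or the same stream when
// `shared_noise`). The OU update happens once per step and the value is
// held constant across the RK4 substeps, as is the drive sample.
//
// `cap` > 0 applies the hard saturation ceiling of the response at that
// value (the textbook form); `cap` <= 0 integrates the threshold-linear
// response without a ceiling, which is the reference operating point:
// there the excitatory activity stays far below 1 and runaway excitation
// is terminated by the fast inhibitory loop rather than by the ceiling.
//
// Records (E, I, A) every `record_every` steps starting at step 0, and
// optionally the per-step E trajectory (used as the drive of a
// downstream network).
// [[Rcpp::export]]
List sim_network_cpp(NumericVector par, int n_steps, double dt,
                     int record_every, NumericVector drive,
                     NumericVector init, double sigma, double tau_noise,
                     double sigma_i_frac, bool shared_noise,
                     double cap, bool full_e, bool euler) {
  Pars p;
  p.tau_e = par[0]; p.tau_i = par[1]; p.tau_a = par[2];
  p.g_e = par[3]; p.g_i = par[4]; p.th_e = par[5]; p.th_i = par[6];
  p.w_ee = par[7]; p.w_ei = par[8]; p.w_ie = par[9]; p.w_ii = par[10];
  p.w_ea = par[11]; p.w_ae = par[12];
  p.cap = cap > 0 ? cap : std::numeric_limits<double>::infinity();

  const bool has_drive = drive.size() > 0;
  if (has_drive && drive.size() < n_steps)
    stop("drive trace shorter than the number of steps");

  int n_rec = n_steps / record_every + 1;
  NumericVector E_r(n_rec), I_r(n_rec), A_r(n_rec);
  NumericVector E_full(full_e ? n_steps : 0);

  // exact OU discretization: x' = a x + b N(0,1)
  const double a_ou = std::exp(-dt / tau_noise);
  const double b_ou = sigma * std::sqrt(1.0 - a_ou * a_ou);

  double E = init[0], I = init[1], A = init[2];
  double xe = 0.0, xi = 0.0;
  int ir = 0;
  RNGScope scope;
  if (sigma > 0.0) {  // start the OU streams at stationarity
    xe = R::norm_rand() * sigma;
    xi = shared_noise ? xe : R::norm_rand() * sigma;
  }
  for (int k = 0; k < n_steps; ++k) {
    if (k % record_every == 0) { E_r[ir] = E; I_r[ir] = I; A_r[ir] = A; ++ir; }
    if (full_e) E_full[k] = E;
    if (sigma > 0.0) {
      xe = a_ou * xe + b_ou * R::norm_rand();
      xi = shared_noise ? xe : a_ou * xi + b_ou * R::norm_rand();
    }
    double xi_eff = shared_noise ? xi : sigma_i_frac * xi;
    double ie = has_drive ? drive[k] : 0.0;
    double dE1, dI1, dA1;
    if (euler) {
      deriv(p, E, I, A, xe, xi_eff, ie, dE1, dI1, dA1);
      E += dt * dE1; I += dt * dI1; A += dt * dA1;
    } else {
      double dE2, dI2, dA2, dE3, dI3, dA3, dE4, dI4, dA4;
      deriv(p, E, I, A, xe, xi_eff, ie, dE1, dI1, dA1);
      deriv(p, E + 0.5 * dt * dE1, I + 0.5 * dt * dI1, A + 0.5 * dt * dA1,
            xe, xi_eff, ie, dE2, dI2, dA2);
      deriv(p, E + 0.5 * dt * dE2, I + 0.5 * dt * dI2, A + 0.5 * dt * dA2,
            xe, xi_eff, ie, dE3, dI3, dA3);
      deriv(p, E + dt * dE3, I + dt * dI3, A + dt * dA3,
            xe, xi_eff, ie, dE4, dI4, dA4);
      E += dt / 6.0 * (dE1 + 2 * dE2 + 2 * dE3 + dE4);
      I += dt / 6.0 * (dI1 + 2 * dI2 + 2 * dI3 + dI4);
      A += dt / 6.0 * (dA1 + 2 * dA2 + 2 * dA3 + dA4);
    }
    // activities are non-negative; clip the tiny RK undershoot
    if (E < 0.0) E = 0.0;
    if (I < 0.0) I = 0.0;
    if (A < 0.0) A = 0.0;
    if (!R_finite(E) || !R_finite(I) || !R_finite(A))
      stop("non-finite trajectory at step %d", k + 1);
  }
  if (n_steps % record_every == 0 && ir < n_rec) {
    E_r[ir] = E; I_r[ir] = I; A_r[ir] = A; ++ir;
  }
  if (ir < n_rec) { E_r.erase(ir, n_rec); I_r.erase(ir, n_rec); A_r.erase(ir, n_rec); }
  return List::create(_["E"] = E_r, _["I"] = I_r, _["A"] = A_r,
                      _["E_full"] = E_full);
}

// fraction of steps whose response arguments reached the saturation knee
// (diagnostic: the reference operating point never saturates)
// [[Rcpp::export]]
double saturation_fraction_cpp(NumericVector E, NumericVector I,
                               NumericVector A, NumericVector drive_rec,
                               NumericVector par) {
  Pars p;
  p.tau_e = par[0]; p.tau_i = par[1]; p.tau_a = par[2];
  p.g_e = par[3]; p.g_i = par[4]; p.th_e = par[5]; p.th_i = par[6];
  p.w_ee = par[7]; p.w_ei = par[8]; p.w_ie = par[9]; p.w_ii = par[10];
  p.w_ea = par[11]; p.w_ae = par[12];
  int n = E.size(), nsat = 0;
  bool has_drive = drive_rec.size() == n;
  for (int k = 0; k < n; ++k) {
    double ie = has_drive ? drive_rec[k] : 0.0;
    double xe = p.w_ee * E[k] - p.w_ei * I[k] - p.w_ea * A[k] + ie;
    double xi = p.w_ie * E[k] - p.w_ii * I[k];
    if (xe >= p.th_e + 1.0 / p.g_e || xi >= p.th_i + 1.0 / p.g_i) ++nsat;
  }
  return n > 0 ? (double)nsat / n : 0.0;
}

// Explicit-duration Viterbi for a two-state alternating chain.
// loglik: T x 2 per-sample emission log-likelihoods;
// logdur: D x 2 log duration pmf (row d-1 = duration d samples);
// logsurv: D x 2 log survival P(duration >= d), used for the final
// (right-censored) segment; logpi: log initial state probabilities.
// Returns 0/1 state per sample (0 = state in column 1).
// [[Rcpp::export]]
IntegerVector viterbi_ed_cpp(NumericMatrix loglik, NumericMatrix logdur,
                             NumericMatrix logsurv, NumericVector logpi) {
  const int T = loglik.nrow(), D = logdur.nrow();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> cum0(T + 1, 0.0), cum1(T + 1, 0.0);
  for (int t = 0; t < T; ++t) {
    cum0[t + 1] = cum0[t] + loglik(t, 0);
    cum1[t + 1] = cum1[t] + loglik(t, 1);
  }
  // delta[s][t]: best score of segmentation of x[1..t] whose last segment
  // has state s and ends at t (complete). psi[s][t]: its duration.
  std::vector<std::vector<double> > delta(2, std::vector<double>(T + 1, NEG));
  std::vector<std::vector<int> > psi(2, std::vector<int>(T + 1, 0));
  for (int t = 1; t <= T; ++t) {
    for (int s = 0; s < 2; ++s) {
      const std::vector<double> &cum = (s == 0) ? cum0 : cum1;
      double best = NEG; int bestd = 0;
      int dmax = std::min(D, t);
      for (int d = 1; d <= dmax; ++d) {
        double prev = (d == t) ? logpi[s] : delta[1 - s][t - d];
        if (prev == NEG) continue;
        double v = prev + logdur(d - 1, s) + cum[t] - cum[t - d];
        if (v > best) { best = v; bestd = d; }
      }
      delta[s][t] = best; psi[s][t] = bestd;
    }
  }
  // final segment right-censored: survival instead of pmf
  double best = NEG; int bs = 0, bd = 0;
  for (int s = 0; s < 2; ++s) {
    const std::vector<double> &cum = (s == 0) ? cum0 : cum1;
    int dmax = std::min(D, T);
    for (int d = 1; d <= dmax; ++d) {
      double prev = (d == T) ? logpi[s] : delta[1 - s][T - d];
      if (prev == NEG) continue;
      double v = prev + logsurv(d - 1, s) + cum[T] - cum[T - d];
      if (v > best) { best = v; bs = s; bd = d; }
    }
  }
  if (bd == 0) stop("no feasible duration-respecting path");
  IntegerVector path(T);
  int t = T, s = bs, d = bd;
  bool censored = true;
  while (t > 0) {
    for (int u = t - d; u < t; ++u) path[u] = s;
    t -= d;
    if (t == 0) break;
    s = 1 - s;
    d = psi[s][t];
    if (d == 0) stop("backtrack failure");
    censored = false;
  }
  (void)censored;
  return path;
}

// joint (path + data) log score of a given alternating segmentation,
// under the same censoring convention as viterbi_ed_cpp; used to track
// monotonicity of the segmental EM
// [[Rcpp::export]]
double path_score_cpp(IntegerVector path, NumericMatrix loglik,
                      NumericMatrix logdur, NumericMatrix logsurv,
                      NumericVector logpi) {
  const int T = path.size(), D = logdur.nrow();
  double score = 0.0;
  int start = 0;
  score += logpi[path[0]];
  for (int t = 1; t <= T; ++t) {
    if (t == T || path[t] != path[t - 1]) {
      int s = path[start], d = t - start;
      int dc = std::min(d, D);
      score += (t == T) ? logsurv(dc - 1, s) : logdur(dc - 1, s);
      start = t;
    }
  }
  for (int t = 0; t < T; ++t) score += loglik(t, path[t]);
  return score;
}
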