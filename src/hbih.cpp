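#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parameter vector layout shared with R (see param_vector() in R/parameters.R):
// 0 C_m, 1 g_d, 2 g_r, 3 g_sd, 4 g_sr, 5 g_l, 6 g_h,
// 7 V0_d, 8 V0_r, 9 V0_sd, 10 V0_h, 11 s_d, 12 s_r, 13 s_sd, 14 s_h,
// 15 tau_r, 16 tau_sd, 17 tau_sr, 18 tau_h,
// 19 E_d, 20 E_sd, 21 E_r, 22 E_sr, 23 E_l, 24 E_h,
// 25 kappa, 26 eta, 27 K_sr, 28 rho, 29 phi

struct HBParams {
  double C_m, g_d, g_r, g_sd, g_sr, g_l, g_h;
  double V0_d, V0_r, V0_sd, V0_h, s_d, s_r, s_sd, s_h;
  double tau_r, tau_sd, tau_sr, tau_h;
  double E_d, E_sd, E_r, E_sr, E_l, E_h;
  double kappa, eta, K_sr, rho, phi;
  bool slow;
};

static HBParams unpack(const NumericVector& pv, bool slow) {
  if (pv.size() != 30) stop("parameter vector must have 30 entries");
  HBParams p;
  p.C_m = pv[0];  p.g_d = pv[1];  p.g_r = pv[2];  p.g_sd = pv[3];
  p.g_sr = pv[4]; p.g_l = pv[5];  p.g_h = pv[6];
  p.V0_d = pv[7]; p.V0_r = pv[8]; p.V0_sd = pv[9]; p.V0_h = pv[10];
  p.s_d = pv[11]; p.s_r = pv[12]; p.s_sd = pv[13]; p.s_h = pv[14];
  p.tau_r = pv[15]; p.tau_sd = pv[16]; p.tau_sr = pv[17]; p.tau_h = pv[18];
  p.E_d = pv[19]; p.E_sd = pv[20]; p.E_r = pv[21]; p.E_sr = pv[22];
  p.E_l = pv[23]; p.E_h = pv[24];
  p.kappa = pv[25]; p.eta = pv[26]; p.K_sr = pv[27];
  p.rho = pv[28]; p.phi = pv[29];
  p.slow = slow;
  return p;
}

static inline double sigm(double s, double V, double V0) {
  return 1.0 / (1.0 + std::exp(-s * (V - V0)));
}

// State layout: 0 V, 1 a_r, 2 a_sd, 3 a_sr, 4 a_h.
static inline void hb_deriv(const double* x, double* dx, const HBParams& p) {
  const double V = x[0], a_r = x[1], a_sd = x[2], a_sr = x[3], a_h = x[4];
  double I_d = 0.0, I_r = 0.0;
  if (!p.slow) {
    const double a_d = sigm(p.s_d, V, p.V0_d);  // instantaneous gate
    I_d = p.rho * p.g_d * a_d * (V - p.E_d);
    I_r = p.rho * p.g_r * a_r * (V - p.E_r);
  }
  const double I_sd = p.rho * p.g_sd * a_sd * (V - p.E_sd);
  const double sr_gate = a_sr * a_sr / (a_sr * a_sr + p.K_sr);
  const double I_sr = p.rho * p.g_sr * sr_gate * (V - p.E_sr);
  const double I_h = p.rho * p.g_h * a_h * (V - p.E_h);
  const double I_l = p.rho * p.g_l * (V - p.E_l);
  dx[0] = -(I_sd + I_sr + I_h + I_d + I_r + I_l) / p.C_m;
  dx[1] = p.slow ? 0.0 : p.phi * (sigm(p.s_r, V, p.V0_r) - a_r) / p.tau_r;
  dx[2] = p.phi * (sigm(p.s_sd, V, p.V0_sd) - a_sd) / p.tau_sd;
  dx[3] = p.phi * (-p.eta * I_sd - p.kappa * a_sr) / p.tau_sr;
  dx[4] = p.phi * (sigm(p.s_h, V, p.V0_h) - a_h) / p.tau_h;
}

// Reference systems for validating the Lyapunov machinery.
static inline void linear_deriv(const double* x, double* dx, const double* sp, int dim) {
  for (int i = 0; i < dim; ++i) dx[i] = sp[0] * x[i];
}
static inline void lorenz_deriv(const double* x, double* dx, const double* sp) {
  dx[0] = sp[0] * (x[1] - x[0]);
  dx[1] = x[0] * (sp[1] - x[2]) - x[1];
  dx[2] = x[0] * x[1] - sp[2] * x[2];
}

// sys: 0 = HB+Ih (5 vars, slow flag in params), 1 = linear (1 var), 2 = Lorenz (3 vars)
static inline void sys_deriv(int sys, const double* x, double* dx,
                             const HBParams& hp, const double* sp, int dim) {
  switch (sys) {
  case 0: hb_deriv(x, dx, hp); break;
  case 1: linear_deriv(x, dx, sp, dim); break;
  case 2: lorenz_deriv(x, dx, sp); break;
  default: stop("unknown system id");
  }
}

static inline void rk4_step(int sys, double* x, double dt,
                            const HBParams& hp, const double* sp, int dim,
                            double* k1, double* k2, double* k3, double* k4, double* tmp) {
  sys_deriv(sys, x, k1, hp, sp, dim);
  for (int i = 0; i < dim; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  sys_deriv(sys, tmp, k2, hp, sp, dim);
  for (int i = 0; i < dim; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  sys_deriv(sys, tmp, k3, hp, sp, dim);
  for (int i = 0; i < dim; ++i) tmp[i] = x[i] + dt * k3[i];
  sys_deriv(sys, tmp, k4, hp, sp, dim);
  for (int i = 0; i < dim; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
NumericVector cpp_deriv(NumericVector state, NumericVector pv, bool slow) {
  HBParams p = unpack(pv, slow);
  NumericVector out(5);
  hb_deriv(REAL(state), REAL(out), p);
  return out;
}

// Fixed-step RK4 of the HB+Ih model. Integrates equil_steps (discarded), then
// n_steps with recording every `stride` steps. Upward crossings of `threshold`
// (and optionally `threshold2`) are detected at full resolution during the
// recording phase, times linearly interpolated and reported relative to the
// start of the recorded window.
// [[Rcpp::export]]
List cpp_simulate(NumericVector init, NumericVector pv, bool slow,
                  double dt, double equil_steps, double n_steps, int stride,
                  double threshold, double threshold2) {
  HBParams p = unpack(pv, slow);
  double x[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int i = 0; i < 5; ++i) x[i] = init[i];
  if (slow) x[1] = 0.0;

  const long long ne = (long long) equil_steps;
  const long long ns = (long long) n_steps;
  for (long long s = 0; s < ne; ++s) {
    rk4_step(0, x, dt, p, nullptr, 5, k1, k2, k3, k4, tmp);
    if (!std::isfinite(x[0]))
      stop("integration blew up during equilibration at t = %f ms", (s + 1) * dt);
  }

  const long long nrec = ns / stride + 1;
  NumericMatrix states(nrec, 5);
  std::vector<double> spikes, spikes2;
  const bool mon2 = std::isfinite(threshold2);

  long long irec = 0;
  for (int i = 0; i < 5; ++i) states(irec, i) = x[i];
  ++irec;
  double vprev = x[0];
  for (long long s = 0; s < ns; ++s) {
    rk4_step(0, x, dt, p, nullptr, 5, k1, k2, k3, k4, tmp);
    if (!std::isfinite(x[0]) || !std::isfinite(x[3]))
      stop("integration blew up at t = %f ms (V = %f)", (s + 1) * dt, x[0]);
    const double v = x[0];
    if (vprev < threshold && v >= threshold)
      spikes.push_back(s * dt + dt * (threshold - vprev) / (v - vprev));
    if (mon2 && vprev < threshold2 && v >= threshold2)
      spikes2.push_back(s * dt + dt * (threshold2 - vprev) / (v - vprev));
    vprev = v;
    if ((s + 1) % stride == 0 && irec < nrec) {
      for (int i = 0; i < 5; ++i) states(irec, i) = x[i];
      ++irec;
    }
  }

  NumericVector fin(5);
  for (int i = 0; i < 5; ++i) fin[i] = x[i];
  return List::create(_["states"] = states,
                      _["spike_times"] = wrap(spikes),
                      _["crossings2"] = wrap(spikes2),
                      _["final_state"] = fin,
                      _["n_recorded"] = (double) irec);
}

// Two-trajectory (Benettin-style) maximal Lyapunov exponent. The companion is
// offset by d0 along `direction` in per-variable scaled coordinates and pulled
// back to distance d0 every renorm_steps; the first 10% of accumulated
// log-stretches are discarded. Returns the exponent per unit time (1/dt units).
// [[Rcpp::export]]
List cpp_mle(int sys, NumericVector sysp, bool slow, NumericVector init,
             double dt, double equil_steps, double accum_steps, int renorm_steps,
             double d0, NumericVector scales, NumericVector direction,
             double sat_threshold) {
  const int dim = init.size();
  if (dim > 5) stop("state dimension above 5 unsupported");
  HBParams hp;
  const double* sp = nullptr;
  if (sys == 0) hp = unpack(sysp, slow); else sp = REAL(sysp);

  double x1[5], x2[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int i = 0; i < dim; ++i) x1[i] = init[i];
  if (sys == 0 && slow) x1[1] = 0.0;

  const long long ne = (long long) equil_steps;
  for (long long s = 0; s < ne; ++s) {
    rk4_step(sys, x1, dt, hp, sp, dim, k1, k2, k3, k4, tmp);
    if (!std::isfinite(x1[0])) stop("reference trajectory blew up during equilibration");
  }
  for (int i = 0; i < dim; ++i) x2[i] = x1[i] + d0 * direction[i] * scales[i];

  const long long n_ren = (long long) (accum_steps) / renorm_steps;
  if (n_ren < 10) stop("accumulation time too short relative to renormalization interval");
  std::vector<double> logs((size_t) n_ren);
  long long n_sat = 0;
  for (long long r = 0; r < n_ren; ++r) {
    for (int s = 0; s < renorm_steps; ++s) {
      rk4_step(sys, x1, dt, hp, sp, dim, k1, k2, k3, k4, tmp);
      rk4_step(sys, x2, dt, hp, sp, dim, k1, k2, k3, k4, tmp);
    }
    if (!std::isfinite(x1[0]) || !std::isfinite(x2[0]))
      stop("trajectory blew up during Lyapunov accumulation");
    double d2 = 0.0;
    for (int i = 0; i < dim; ++i) {
      const double u = (x2[i] - x1[i]) / scales[i];
      d2 += u * u;
    }
    double d = std::sqrt(d2);
    if (d <= 0.0) d = 1e-300;  // identical trajectories: log ratio -> -inf guard
    logs[(size_t) r] = std::log(d / d0);
    if (d > sat_threshold) ++n_sat;
    const double f = d0 / d;
    for (int i = 0; i < dim; ++i) x2[i] = x1[i] + (x2[i] - x1[i]) * f;
  }
  const long long drop = (long long) std::ceil(0.10 * (double) n_ren);
  double sum = 0.0;
  for (long long r = drop; r < n_ren; ++r) sum += logs[(size_t) r];
  const long long n_kept = n_ren - drop;
  const double mle = sum / ((double) n_kept * renorm_steps * dt);
  return List::create(_["mle"] = mle,
                      _["n_renorm"] = (double) n_ren,
                      _["n_kept"] = (double) n_kept,
                      _["sat_fraction"] = (double) n_sat / (double) n_ren);
}

// Kantz-style stretching profile of a delay-1 embedded scalar series.
// For each admissible reference point, its k nearest neighbours (Theiler
// window excluded) are found in the m-dimensional embedding; the statistic at
// horizon s is the mean over reference points of log(mean distance between
// the s-step-advanced images). References with any zero mean distance
// (exact duplicates, i.e. periodic series) are skipped.
// [[Rcpp::export]]
List cpp_isi_profile(NumericVector x, int m, int r, int k, int theiler) {
  const int n = x.size();
  const int N = n - m + 1;       // embedded points
  const int M = N - r;           // points with r-step futures
  if (M < k + 1 || M < 2) stop("series too short for embedding dimension %d", m);
  const double* xs = REAL(x);

  std::vector<double> sums((size_t) r + 1, 0.0);
  long long n_used = 0;
  std::vector<std::pair<double, int> > cand;
  cand.reserve((size_t) M);

  for (int i = 0; i < M; ++i) {
    cand.clear();
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) < theiler) continue;
      double d2 = 0.0;
      for (int q = 0; q < m; ++q) {
        const double u = xs[i + q] - xs[j + q];
        d2 += u * u;
      }
      cand.push_back(std::make_pair(d2, j));
    }
    if ((int) cand.size() < k) continue;
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    // Stretching statistic (Kantz): neighborhoods live in the m-dimensional
    // embedding, but the horizon-s distance is measured on the scalar series
    // at the window's reference time (its last coordinate) advanced by s.
    // Using the full advanced-window distance instead smears divergence over
    // the window and underestimates the slope, increasingly so for larger m.
    bool ok = true;
    double prof[64];
    for (int s = 0; s <= r; ++s) {
      double acc = 0.0;
      for (int q = 0; q < k; ++q) {
        const int j = cand[(size_t) q].second;
        acc += std::abs(xs[i + m - 1 + s] - xs[j + m - 1 + s]);
      }
      const double dmean = acc / k;
      if (dmean <= 0.0) { ok = false; break; }
      prof[s] = std::log(dmean);
    }
    if (!ok) continue;
    for (int s = 0; s <= r; ++s) sums[(size_t) s] += prof[s];
    ++n_used;
  }

  NumericVector profile(r + 1, NA_REAL);
  if (n_used > 0)
    for (int s = 0; s <= r; ++s) profile[s] = sums[(size_t) s] / (double) n_used;
  return List::create(_["profile"] = profile, _["n_used"] = (double) n_used);
}

// Kaspar-Schuster production-step count c(n) of a binary (0/1) word.
// [[Rcpp::export]]
int cpp_lz(IntegerVector word) {
  const int n = word.size();
  if (n < 2) stop("word must have length >= 2");
  const int* s = INTEGER(word);
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
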