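// Core integrators for the 4-D neural mass model.
// State ordering: (R_e, V_e, R_i, V_i); internal units: time in ms, rates in 1/ms.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct MFPars {
  double gee, gei, gie, gii;   // coupling magnitudes g0^{(ab)}
  double I0e, I0i;             // rescaled DC currents
  double sqrtK;                // sqrt of median in-degree
  double dee, dii;             // heterogeneity widths Delta0^{(aa)}
  double taue, taui;           // membrane time constants (ms)
};

static MFPars unpack(const NumericVector& p) {
  MFPars q;
  q.gee = p["g0_ee"]; q.gei = p["g0_ei"]; q.gie = p["g0_ie"]; q.gii = p["g0_ii"];
  q.I0e = p["I0_e"];  q.I0i = p["I0_i"];
  q.sqrtK = std::sqrt((double)p["K"]);
  q.dee = p["delta0_ee"]; q.dii = p["delta0_ii"];
  q.taue = p["tau_m_e"];  q.taui = p["tau_m_i"];
  return q;
}

static inline void mf_rhs(const double* s, double* ds, const MFPars& p) {
  const double Re = s[0], Ve = s[1], Ri = s[2], Vi = s[3];
  ds[0] = Re * (2.0 * Ve + p.gee * p.dee / M_PI) / p.taue;
  ds[1] = (Ve * Ve - std::pow(M_PI * Re * p.taue, 2)
           + p.sqrtK * (p.I0e + (p.gee * Re - p.gei * Ri) * p.taue)) / p.taue;
  ds[2] = Ri * (2.0 * Vi + p.gii * p.dii / M_PI) / p.taui;
  ds[3] = (Vi * Vi - std::pow(M_PI * Ri * p.taui, 2)
           + p.sqrtK * (p.I0i + (p.gie * Re - p.gii * Ri) * p.taui)) / p.taui;
}

// Jacobian of the vector field at state s (4x4, row-major)
static inline void mf_jac(const double* s, double J[4][4], const MFPars& p) {
  const double Re = s[0], Ve = s[1], Ri = s[2], Vi = s[3];
  for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) J[i][j] = 0.0;
  J[0][0] = (2.0 * Ve + p.gee * p.dee / M_PI) / p.taue;
  J[0][1] = 2.0 * Re / p.taue;
  J[1][0] = -2.0 * M_PI * M_PI * p.taue * Re + p.sqrtK * p.gee;
  J[1][1] = 2.0 * Ve / p.taue;
  J[1][2] = -p.sqrtK * p.gei;
  J[2][2] = (2.0 * Vi + p.gii * p.dii / M_PI) / p.taui;
  J[2][3] = 2.0 * Ri / p.taui;
  J[3][0] = p.sqrtK * p.gie;
  J[3][2] = -2.0 * M_PI * M_PI * p.taui * Ri - p.sqrtK * p.gii;
  J[3][3] = 2.0 * Vi / p.taui;
}

static inline bool escaped(const double* s, const MFPars& p, double guard) {
  return !(std::fabs(s[1]) < guard && std::fabs(s[3]) < guard &&
           std::fabs(s[0]) * p.taue < guard && std::fabs(s[2]) * p.taui < guard);
}

// One RK4 step of the state; returns clip count (negative-rate round-off)
static inline int rk4_step(double* s, double dt, const MFPars& p) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  mf_rhs(s, k1, p);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  mf_rhs(tmp, k2, p);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  mf_rhs(tmp, k3, p);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + dt * k3[i];
  mf_rhs(tmp, k4, p);
  for (int i = 0; i < 4; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  int nclip = 0;
  if (s[0] < 0) { s[0] = 0.0; ++nclip; }
  if (s[2] < 0) { s[2] = 0.0; ++nclip; }
  return nclip;
}

// [[Rcpp::export]]
List cpp_mf_derivative(NumericVector state, NumericVector pars) {
  MFPars p = unpack(pars);
  double s[4] = { state[0], state[1], state[2], state[3] };
  double ds[4];
  mf_rhs(s, ds, p);
  return List::create(_["deriv"] = NumericVector::create(ds[0], ds[1], ds[2], ds[3]));
}

// [[Rcpp::export]]
List cpp_integrate_mf(NumericVector state0, NumericVector pars, double dt,
                      int n_transient, int n_steps, int stride, double guard) {
  MFPars p = unpack(pars);
  double s[4] = { state0[0], state0[1], state0[2], state0[3] };
  long nclip = 0;
  bool esc = false; double t_esc = NA_REAL;
  for (int n = 0; n < n_transient && !esc; ++n) {
    nclip += rk4_step(s, dt, p);
    if (escaped(s, p, guard)) { esc = true; t_esc = (n + 1) * dt; }
  }
  int n_out = esc ? 0 : (n_steps / stride + 1);
  NumericMatrix out(n_out, 5);
  if (!esc) {
    int row = 0;
    out(row, 0) = 0.0; out(row, 1) = s[0]; out(row, 2) = s[1];
    out(row, 3) = s[2]; out(row, 4) = s[3];
    ++row;
    for (int n = 0; n < n_steps; ++n) {
      nclip += rk4_step(s, dt, p);
      if (escaped(s, p, guard)) { esc = true; t_esc = n_transient * dt + (n + 1) * dt; break; }
      if ((n + 1) % stride == 0 && row < n_out) {
        out(row, 0) = (n + 1) * dt;
        out(row, 1) = s[0]; out(row, 2) = s[1]; out(row, 3) = s[2]; out(row, 4) = s[3];
        ++row;
      }
    }
    if (esc) out = NumericMatrix(0, 5);
  }
  return List::create(_["trace"] = out, _["n_clip"] = (double)nclip,
                      _["escaped"] = esc, _["t_escape"] = t_esc,
                      _["final"] = NumericVector::create(s[0], s[1], s[2], s[3]));
}

// Benettin algorithm: reference trajectory + 4 tangent vectors, QR
// re-orthonormalisation by modified Gram-Schmidt every `renorm_every` steps.
// [[Rcpp::export]]
List cpp_lyapunov(NumericVector state0, NumericVector pars, double dt,
                  int n_transient, int n_steps, int renorm_every,
                  NumericMatrix Q0, double guard, int n_checkpoints) {
  MFPars p = unpack(pars);
  double s[4] = { state0[0], state0[1], state0[2], state0[3] };
  bool esc = false; double t_esc = NA_REAL;
  for (int n = 0; n < n_transient && !esc; ++n) {
    rk4_step(s, dt, p);
    if (escaped(s, p, guard)) { esc = true; t_esc = (n + 1) * dt; }
  }
  double Q[4][4];     // tangent vectors as columns: Q[i][k] = component i of vector k
  for (int i = 0; i < 4; ++i) for (int k = 0; k < 4; ++k) Q[i][k] = Q0(i, k);
  double logsum[4] = {0, 0, 0, 0};
  int n_done = 0;
  std::vector<double> chk_t, chk_l[4];
  int chk_every = n_steps / std::max(1, n_checkpoints);
  if (chk_every < renorm_every) chk_every = renorm_every;

  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  double K1[4][4], K2[4][4], K3[4][4], K4[4][4], Tq[4][4];
  double J[4][4];
  for (int n = 0; n < n_steps && !esc; ++n) {
    // augmented RK4: tangent stages use the Jacobian at the state stages
    mf_rhs(s, k1, p); mf_jac(s, J, p);
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      K1[i][k] = 0; for (int j = 0; j < 4; ++j) K1[i][k] += J[i][j] * Q[j][k];
    }
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    mf_rhs(tmp, k2, p); mf_jac(tmp, J, p);
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      Tq[i][k] = Q[i][k] + 0.5 * dt * K1[i][k];
    }
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      K2[i][k] = 0; for (int j = 0; j < 4; ++j) K2[i][k] += J[i][j] * Tq[j][k];
    }
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    mf_rhs(tmp, k3, p); mf_jac(tmp, J, p);
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      Tq[i][k] = Q[i][k] + 0.5 * dt * K2[i][k];
    }
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      K3[i][k] = 0; for (int j = 0; j < 4; ++j) K3[i][k] += J[i][j] * Tq[j][k];
    }
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + dt * k3[i];
    mf_rhs(tmp, k4, p); mf_jac(tmp, J, p);
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      Tq[i][k] = Q[i][k] + dt * K3[i][k];
    }
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i) {
      K4[i][k] = 0; for (int j = 0; j < 4; ++j) K4[i][k] += J[i][j] * Tq[j][k];
    }
    for (int i = 0; i < 4; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    if (s[0] < 0) s[0] = 0.0;
    if (s[2] < 0) s[2] = 0.0;
    for (int k = 0; k < 4; ++k) for (int i = 0; i < 4; ++i)
      Q[i][k] += dt / 6.0 * (K1[i][k] + 2 * K2[i][k] + 2 * K3[i][k] + K4[i][k]);
    if (escaped(s, p, guard)) { esc = true; t_esc = (n_transient + n + 1) * dt; break; }
    ++n_done;
    if ((n + 1) % renorm_every == 0) {
      // modified Gram-Schmidt on the columns of Q
      for (int k = 0; k < 4; ++k) {
        for (int j = 0; j < k; ++j) {
          double dot = 0;
          for (int i = 0; i < 4; ++i) dot += Q[i][j] * Q[i][k];
          for (int i = 0; i < 4; ++i) Q[i][k] -= dot * Q[i][j];
        }
        double nrm = 0;
        for (int i = 0; i < 4; ++i) nrm += Q[i][k] * Q[i][k];
        nrm = std::sqrt(nrm);
        logsum[k] += std::log(nrm);
        for (int i = 0; i < 4; ++i) Q[i][k] /= nrm;
      }
      if ((n + 1) % chk_every == 0) {
        double t = (n + 1) * dt;
        chk_t.push_back(t);
        for (int k = 0; k < 4; ++k) chk_l[k].push_back(logsum[k] / t);
      }
    }
  }
  NumericVector lambda(4);
  double t_tot = n_done * dt;
  for (int k = 0; k < 4; ++k) lambda[k] = t_tot > 0 ? logsum[k] / t_tot : NA_REAL;
  NumericMatrix trace(chk_t.size(), 5);
  for (size_t r = 0; r < chk_t.size(); ++r) {
    trace(r, 0) = chk_t[r];
    for (int k = 0; k < 4; ++k) trace(r, k + 1) = chk_l[k][r];
  }
  return List::create(_["lambda"] = lambda, _["trace"] = trace,
                      _["escaped"] = esc, _["t_escape"] = t_esc,
                      _["final"] = NumericVector::create(s[0], s[1], s[2], s[3]));
}

// Local maxima of R_e(t) (and of R_i(t)) after the transient, detected on the
// raw integration grid with parabolic refinement of the peak value.
// [[Rcpp::export]]
List cpp_mf_peaks(NumericVector state0, NumericVector pars, double dt,
                  int n_transient, int n_steps, double guard, int max_peaks) {
  MFPars p = unpack(pars);
  double s[4] = { state0[0], state0[1], state0[2], state0[3] };
  bool esc = false; double t_esc = NA_REAL;
  for (int n = 0; n < n_transient && !esc; ++n) {
    rk4_step(s, dt, p);
    if (escaped(s, p, guard)) { esc = true; t_esc = (n + 1) * dt; }
  }
  std::vector<double> pk_e, pt_e, pk_i, pt_i;
  double e2 = s[0], e1 = s[0], i2 = s[2], i1 = s[2];
  for (int n = 0; n < n_steps && !esc; ++n) {
    rk4_step(s, dt, p);
    if (escaped(s, p, guard)) { esc = true; t_esc = (n_transient + n + 1) * dt; break; }
    double e0 = s[0], i0 = s[2];
    if (n >= 1 && e1 > e2 && e1 >= e0 && (int)pk_e.size() < max_peaks) {
      double denom = e2 - 2 * e1 + e0;
      double off = (denom != 0.0) ? 0.5 * (e2 - e0) / denom : 0.0;
      pk_e.push_back(e1 - 0.25 * (e2 - e0) * off);
      pt_e.push_back((n) * dt + off * dt);
    }
    if (n >= 1 && i1 > i2 && i1 >= i0 && (int)pk_i.size() < max_peaks) {
      double denom = i2 - 2 * i1 + i0;
      double off = (denom != 0.0) ? 0.5 * (i2 - i0) / denom : 0.0;
      pk_i.push_back(i1 - 0.25 * (i2 - i0) * off);
      pt_i.push_back((n) * dt + off * dt);
    }
    e2 = e1; e1 = e0; i2 = i1; i1 = i0;
  }
  return List::create(_["peaks_e"] = wrap(pk_e), _["times_e"] = wrap(pt_e),
                      _["peaks_i"] = wrap(pk_i), _["times_i"] = wrap(pt_i),
                      _["escaped"] = esc, _["t_escape"] = t_esc);
}
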