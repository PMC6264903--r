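#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Saturating exponential: keeps Eq-4-style logistic rates finite.
static inline double sat_exp(double x) {
  if (x > 700.0) x = 700.0;
  if (x < -700.0) x = -700.0;
  return std::exp(x);
}

// Linear-interpolation percentile (R quantile type 7) of a copied vector.
static double percentile_lin(const std::vector<double>& h, double pct) {
  const size_t n = h.size();
  if (n == 1) return h[0];
  std::vector<double> s(h);
  std::sort(s.begin(), s.end());
  double idx = pct / 100.0 * (double)(n - 1);
  size_t lo = (size_t)std::floor(idx);
  size_t hi = (size_t)std::ceil(idx);
  double frac = idx - (double)lo;
  return s[lo] * (1.0 - frac) + s[hi] * frac;
}

// Gain-modulated input rates: kappa == 0 selects the peaked (Gaussian) gain,
// otherwise the sigmoidal gain with the stored signed kappa.
static void input_rates(const NumericVector& alpha, const NumericVector& beta,
                        const NumericVector& kappa, double sigma, double rho,
                        double r, double e, std::vector<double>& out) {
  const R_xlen_t ni = alpha.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double inv2r2 = (rho > 0.0) ? 1.0 / (2.0 * rho * rho) : 0.0;
  for (R_xlen_t j = 0; j < ni; ++j) {
    double dr = r - alpha[j];
    double ret = sat_exp(-dr * dr * inv2s2);
    double gain;
    if (kappa[j] == 0.0) {
      double de = e - beta[j];
      gain = sat_exp(-de * de * inv2r2);
    } else {
      gain = 1.0 / (1.0 + sat_exp(kappa[j] * (e - beta[j])));
    }
    out[j] = gain * ret;
  }
}

// Core simulator: advances the coupled activation/trace/rate system along a
// precomputed (eye, target) step sequence, optionally applying a learning rule
// with per-step weight renormalisation, and records the output rate vector at
// the requested step indices.
//
// pre:      K x N matrix of 0-based presynaptic input indices
// W:        K x N weight matrix (cloned; per-column Euclidean norm kept at 1
//           whenever learning is active)
// rule_id:  0 none, 1 standard trace, 2 hebbian, 3 delayed trace + anti-Hebb,
//           4 delayed rate + anti-Hebb, 5 current trace + anti-Hebb,
//           6 delayed trace only
// Learning-rate units are 1/s: one Euler step adds lrate * factor * v_in * dt/1000.
// [[Rcpp::export]]
List cpp_simulate(IntegerMatrix pre, NumericMatrix W_in,
                  NumericVector alpha, NumericVector beta, NumericVector kappa,
                  double sigma, double rho,
                  NumericVector eye, NumericVector target,
                  double tau_h, double tau_q, double phi, double theta,
                  double pi_pct, double dt,
                  int rule_id, double lrate, double beta_rule, int delay_steps,
                  IntegerVector record_at,
                  NumericVector h0, NumericVector q0,
                  NumericMatrix bufq0, NumericMatrix bufv0,
                  int buf_head0, int buf_count0) {
  const int K = pre.nrow();
  const int N = pre.ncol();
  const R_xlen_t NI = alpha.size();
  const R_xlen_t S = eye.size();
  const bool learn = rule_id > 0 && lrate != 0.0;
  const double dt_s = dt / 1000.0;  // learning-rule time unit is seconds

  NumericMatrix W = clone(W_in);
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> v(N, 0.0);
  std::vector<double> vin(NI, 0.0);
  std::vector<double> qdel(N, 0.0), vdel(N, 0.0);

  // Ring buffers (N x depth) for delayed trace / rate reads.
  const int depth = std::max(delay_steps, 1);
  NumericMatrix bufq(N, depth), bufv(N, depth);
  int head = 0, count = 0;
  if (bufq0.nrow() == N && bufq0.ncol() == depth) {
    bufq = clone(bufq0);
    bufv = clone(bufv0);
    head = buf_head0;
    count = buf_count0;
  }

  const int nrec = record_at.size();
  NumericMatrix records(N, std::max(nrec, 0));
  int rec_ptr = 0;

  // Stimuli are piecewise constant (fixations, test dwells): cache the input
  // rates, and — when weights are frozen — the drive vector as well.
  std::vector<double> drive(N, 0.0);
  double prev_r = R_PosInf, prev_e = R_PosInf;
  bool have_vin = false, have_drive = false;

  for (R_xlen_t s = 0; s < S; ++s) {
    const double e = eye[s];
    const double r = target[s] - e;  // retinal location, h = r + e
    const bool same_input = have_vin && r == prev_r && e == prev_e;
    if (!same_input) {
      input_rates(alpha, beta, kappa, sigma, rho, r, e, vin);
      prev_r = r;
      prev_e = e;
      have_vin = true;
      have_drive = false;
    }

    // Eq 3: leaky integration of the synaptic drive.
    if (learn || !have_drive) {
      for (int i = 0; i < N; ++i) {
        double d = 0.0;
        const int* pcol = &pre(0, i);
        const double* wcol = &W(0, i);
        for (int k = 0; k < K; ++k) d += wcol[k] * vin[pcol[k]];
        drive[i] = d;
      }
      have_drive = !learn;
    }
    for (int i = 0; i < N; ++i) h[i] += dt / tau_h * (-h[i] + drive[i]);

    // Eq 4: competition via the percentile threshold of the current activations.
    const double p_pi = percentile_lin(h, pi_pct);
    for (int i = 0; i < N; ++i)
      v[i] = 1.0 / (1.0 + sat_exp(-2.0 * phi * (h[i] - p_pi - theta)));

    // Eq 5: trace update from the current rates.
    for (int i = 0; i < N; ++i) q[i] += dt / tau_q * (-q[i] + v[i]);

    if (learn) {
      // Delayed reads: value from delay_steps steps ago, zeros before start.
      if (delay_steps == 0) {
        qdel = q;
        vdel = v;
      } else if (delay_steps <= count) {
        int pos = head - delay_steps;
        if (pos < 0) pos += depth;
        for (int i = 0; i < N; ++i) {
          qdel[i] = bufq(i, pos);
          vdel[i] = bufv(i, pos);
        }
      } else {
        std::fill(qdel.begin(), qdel.end(), 0.0);
        std::fill(vdel.begin(), vdel.end(), 0.0);
      }

      for (int i = 0; i < N; ++i) {
        double f;
        switch (rule_id) {
          case 1: f = lrate * q[i]; break;
          case 2: f = lrate * v[i]; break;
          case 3: f = lrate * (beta_rule * qdel[i] - v[i]); break;
          case 4: f = lrate * (beta_rule * vdel[i] - v[i]); break;
          case 5: f = lrate * (beta_rule * q[i] - v[i]); break;
          case 6: f = lrate * qdel[i]; break;
          default: f = 0.0;
        }
        const double step_f = f * dt_s;
        if (step_f == 0.0) continue;  // norm already 1, nothing changes
        double* wcol = &W(0, i);
        const int* pcol = &pre(0, i);
        double ss = 0.0;
        for (int k = 0; k < K; ++k) {
          double w = wcol[k] + step_f * vin[pcol[k]];
          if (w < 0.0) w = 0.0;  // synapses stay excitatory
          wcol[k] = w;
          ss += w * w;
        }
        if (ss <= 0.0)
          stop("weight vector of output neuron %d collapsed to zero during learning", i + 1);
        const double inv = 1.0 / std::sqrt(ss);  // Eq 7
        for (int k = 0; k < K; ++k) wcol[k] *= inv;
      }
    }

    // Push current q, v into the delay ring buffer.
    for (int i = 0; i < N; ++i) {
      bufq(i, head) = q[i];
      bufv(i, head) = v[i];
    }
    head = (head + 1) % depth;
    if (count < depth) ++count;

    if (rec_ptr < nrec && (int)(s + 1) == record_at[rec_ptr]) {
      for (int i = 0; i < N; ++i) records(i, rec_ptr) = v[i];
      ++rec_ptr;
    }
  }

  return List::create(_["W"] = W, _["h"] = NumericVector(h.begin(), h.end()),
                      _["q"] = NumericVector(q.begin(), q.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["records"] = records, _["bufq"] = bufq,
                      _["bufv"] = bufv, _["buf_head"] = head,
                      _["buf_count"] = count);
}

// Vectorised input-population rates for a single (r, e); mirrors the engine's
// internal evaluation so R-level code and the engine share one definition.
// [[Rcpp::export]]
NumericVector cpp_input_rates(NumericVector alpha, NumericVector beta,
                              NumericVector kappa, double sigma, double rho,
                              double r, double e) {
  std::vector<double> out(alpha.size());
  input_rates(alpha, beta, kappa, sigma, rho, r, e, out);
  return NumericVector(out.begin(), out.end());
}
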