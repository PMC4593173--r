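#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled double-column Jansen-Rit system.
//
// Per column j: three second-order PSP blocks (pyramidal -> interneurons,
// excitatory feedback + external input, inhibitory feedback) plus a fourth
// block carrying the delayed inter-column input (rate constant ad, gain
// K_in). Synapse numbers derive from the column's global constant C as
// (C, 0.8C, 0.25C, 0.25C). Pyramidal membrane potential
// v_j = y1_j + y6_j - y2_j is the recorded output u_j.
//
// State layout (16 doubles): per column j in {0,1}, offset 8*j:
//   [0] y0  [1] y0' [2] y1 [3] y1' [4] y2 [5] y2' [6] y6 [7] y6'

struct ColPar {
  double A, B, a, b, e0, v0, r, ad;
  double C;      // global intra-column connectivity constant
  double Kin;    // coupling gain from the other column into this one
};

static inline double sigm(double v, const ColPar &c) {
  return 2.0 * c.e0 / (1.0 + std::exp(c.r * (c.v0 - v)));
}

static inline void deriv(const double *x, double p1, double p2,
                         const ColPar &c1, const ColPar &c2, double *dx) {
  const ColPar *cc[2] = { &c1, &c2 };
  double pin[2] = { p1, p2 };
  // pyramidal firing rates of both columns (needed cross-wise)
  double v[2], sv[2];
  for (int j = 0; j < 2; ++j) {
    const double *y = x + 8 * j;
    v[j] = y[2] + y[6] - y[4];
    sv[j] = sigm(v[j], *cc[j]);
  }
  for (int j = 0; j < 2; ++j) {
    const ColPar &c = *cc[j];
    const double *y = x + 8 * j;
    double *d = dx + 8 * j;
    double C1 = c.C, C2 = 0.8 * c.C, C3 = 0.25 * c.C, C4 = 0.25 * c.C;
    double s_exc = sigm(C1 * y[0], c);   // excitatory interneuron firing
    double s_inh = sigm(C3 * y[0], c);   // inhibitory interneuron firing
    d[0] = y[1];
    d[1] = c.A * c.a * sv[j] - 2.0 * c.a * y[1] - c.a * c.a * y[0];
    d[2] = y[3];
    d[3] = c.A * c.a * (pin[j] + C2 * s_exc) - 2.0 * c.a * y[3] - c.a * c.a * y[2];
    d[4] = y[5];
    d[5] = c.B * c.b * C4 * s_inh - 2.0 * c.b * y[5] - c.b * c.b * y[4];
    d[6] = y[7];
    d[7] = c.A * c.ad * c.Kin * sv[1 - j] - 2.0 * c.ad * y[7] - c.ad * c.ad * y[6];
  }
}

static ColPar unpack(List cst, double C, double Kin) {
  ColPar c;
  c.A  = as<double>(cst["A"]);  c.B  = as<double>(cst["B"]);
  c.a  = as<double>(cst["a"]);  c.b  = as<double>(cst["b"]);
  c.e0 = as<double>(cst["e0"]); c.v0 = as<double>(cst["v0"]);
  c.r  = as<double>(cst["r"]);  c.ad = as<double>(cst["ad"]);
  c.C = C; c.Kin = Kin;
  return c;
}

// Fixed-step RK4 over the full input length; inputs held constant within
// each sample. Returns a 2 x (n - burn_samples) matrix (u1, u2), or a
// matrix with attribute diverged = TRUE if the state left the finite range.
// [[Rcpp::export]]
NumericMatrix dc_simulate_cpp(double C1, double C2, double K1, double K2,
                              List const1, List const2,
                              NumericVector p, NumericVector pp,
                              double fs, int substeps, int burn_samples) {
  int n = p.size();
  if (pp.size() != n) stop("p and p' must have equal length");
  if (burn_samples < 0 || burn_samples >= n)
    stop("burn_samples must be in [0, length(p) - 1]");
  ColPar c1 = unpack(const1, C1, K2);  // column 1 receives K2 * output of column 2
  ColPar c2 = unpack(const2, C2, K1);  // column 2 receives K1 * output of column 1
  double dt = 1.0 / (fs * substeps);
  double x[16], k1v[16], k2v[16], k3v[16], k4v[16], xt[16];
  for (int i = 0; i < 16; ++i) x[i] = 0.0;

  int nkeep = n - burn_samples;
  NumericMatrix out(2, nkeep);
  bool diverged = false;
  for (int i = 0; i < n && !diverged; ++i) {
    double p1 = p[i], p2 = pp[i];
    for (int s = 0; s < substeps; ++s) {
      deriv(x, p1, p2, c1, c2, k1v);
      for (int q = 0; q < 16; ++q) xt[q] = x[q] + 0.5 * dt * k1v[q];
      deriv(xt, p1, p2, c1, c2, k2v);
      for (int q = 0; q < 16; ++q) xt[q] = x[q] + 0.5 * dt * k2v[q];
      deriv(xt, p1, p2, c1, c2, k3v);
      for (int q = 0; q < 16; ++q) xt[q] = x[q] + dt * k3v[q];
      deriv(xt, p1, p2, c1, c2, k4v);
      for (int q = 0; q < 16; ++q)
        x[q] += dt / 6.0 * (k1v[q] + 2.0 * k2v[q] + 2.0 * k3v[q] + k4v[q]);
    }
    double u1 = x[2] + x[6] - x[4];
    double u2 = x[10] + x[14] - x[12];
    if (!std::isfinite(u1) || !std::isfinite(u2) ||
        std::fabs(u1) > 1e8 || std::fabs(u2) > 1e8) {
      diverged = true;
    }
    if (i >= burn_samples) {
      out(0, i - burn_samples) = u1;
      out(1, i - burn_samples) = u2;
    }
  }
  if (diverged) out.attr("diverged") = true;
  return out;
}
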