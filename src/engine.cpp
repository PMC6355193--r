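#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integrator for the population rate model.
//
// State layout: V[0..n-1], h[0..n-1], Inoise[0..n-1]  (h unused for
// non-oscillatory populations, kept for a uniform layout).
//
// Deterministic runs (sigma == 0 everywhere) use classical RK4 on (V, h);
// stochastic runs hold the Ornstein-Uhlenbeck noise current fixed within a
// step (it enters the membrane equation as a current) and advance it by one
// Euler-Maruyama update per step, drawing from R's RNG so that set.seed()
// governs reproducibility.

struct Net {
  int n;
  NumericVector C, gL, EL, Vthr, Vmax;
  LogicalVector isnap;
  NumericVector gNaP, ENa, Vm, km, Vh, kh, tauMax;
  IntegerVector csrc, ctgt;       // 0-based
  NumericVector cw;               // effective conductance weight, signed
  NumericVector gdrive;           // per-population drive conductance (>= 0)
  double EsynE, EsynI;
  NumericVector sigma, tauNoise;
};

static inline double fout(double V, double Vthr, double Vmax) {
  if (V < Vthr) return 0.0;
  if (V >= Vmax) return 1.0;
  return (V - Vthr) / (Vmax - Vthr);
}

// derivative of (V, h); noise currents held fixed
static void deriv(const Net &net, const std::vector<double> &V,
                  const std::vector<double> &h, const std::vector<double> &nz,
                  std::vector<double> &dV, std::vector<double> &dh,
                  std::vector<double> &f, std::vector<double> &gE,
                  std::vector<double> &gI) {
  const int n = net.n;
  for (int i = 0; i < n; ++i) {
    f[i] = fout(V[i], net.Vthr[i], net.Vmax[i]);
    gE[i] = net.gdrive[i];
    gI[i] = 0.0;
  }
  const int m = net.csrc.size();
  for (int k = 0; k < m; ++k) {
    const double w = net.cw[k];
    if (w >= 0)
      gE[net.ctgt[k]] += w * f[net.csrc[k]];
    else
      gI[net.ctgt[k]] -= w * f[net.csrc[k]];
  }
  for (int i = 0; i < n; ++i) {
    double I = net.gL[i] * (V[i] - net.EL[i]) +
               gE[i] * (V[i] - net.EsynE) + gI[i] * (V[i] - net.EsynI) +
               nz[i];
    if (net.isnap[i]) {
      const double minf = 1.0 / (1.0 + exp((V[i] - net.Vm[i]) / net.km[i]));
      const double hinf = 1.0 / (1.0 + exp((V[i] - net.Vh[i]) / net.kh[i]));
      const double tauh =
          net.tauMax[i] / cosh((V[i] - net.Vh[i]) / (2.0 * net.kh[i]));
      I += net.gNaP[i] * minf * h[i] * (V[i] - net.ENa[i]);
      dh[i] = (hinf - h[i]) / tauh;
    } else {
      dh[i] = 0.0;
    }
    dV[i] = -I / net.C[i];
  }
}

static Net unpack(const List &nl) {
  Net net;
  net.n = as<int>(nl["n"]);
  net.C = nl["C"]; net.gL = nl["gL"]; net.EL = nl["EL"];
  net.Vthr = nl["Vthr"]; net.Vmax = nl["Vmax"];
  net.isnap = nl["isnap"];
  net.gNaP = nl["gNaP"]; net.ENa = nl["ENa"];
  net.Vm = nl["Vm"]; net.km = nl["km"];
  net.Vh = nl["Vh"]; net.kh = nl["kh"]; net.tauMax = nl["tauMax"];
  net.csrc = nl["csrc"]; net.ctgt = nl["ctgt"]; net.cw = nl["cw"];
  net.gdrive = nl["gdrive"];
  net.EsynE = as<double>(nl["EsynE"]); net.EsynI = as<double>(nl["EsynI"]);
  net.sigma = nl["sigma"]; net.tauNoise = nl["tauNoise"];
  return net;
}

// [[Rcpp::export]]
List cpp_simulate(List nl, NumericVector state0, double duration, double dt,
                  double sampleEvery, IntegerVector record, bool useNoise) {
  Net net = unpack(nl);
  const int n = net.n;
  std::vector<double> V(n), h(n), nz(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state0[i];
    h[i] = state0[n + i];
    nz[i] = state0[2 * n + i];
  }
  const int nstep = (int)std::llround(duration / dt);
  const int kSamp = std::max(1, (int)std::llround(sampleEvery / dt));
  const int nrec = record.size();
  const int nsamp = nstep / kSamp + 1;
  NumericMatrix Vout(nsamp, nrec), Fout(nsamp, nrec);
  NumericVector tout(nsamp);

  std::vector<double> dV1(n), dh1(n), dV2(n), dh2(n), dV3(n), dh3(n),
      dV4(n), dh4(n), Vt(n), ht(n), f(n), gE(n), gI(n);

  int is = 0;
  for (int i = 0; i < nrec; ++i) {
    Vout(0, i) = V[record[i]];
    Fout(0, i) = fout(V[record[i]], net.Vthr[record[i]], net.Vmax[record[i]]);
  }
  tout[0] = 0.0;
  is = 1;

  bool blew = false;
  double blewAt = NA_REAL;
  RNGScope scope;

  for (int s = 1; s <= nstep; ++s) {
    if (useNoise) {
      // hybrid: RK4 on (V,h) with noise held, then EM update of noise
      deriv(net, V, h, nz, dV1, dh1, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * dV1[i]; ht[i] = h[i] + 0.5 * dt * dh1[i]; }
      deriv(net, Vt, ht, nz, dV2, dh2, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * dV2[i]; ht[i] = h[i] + 0.5 * dt * dh2[i]; }
      deriv(net, Vt, ht, nz, dV3, dh3, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + dt * dV3[i]; ht[i] = h[i] + dt * dh3[i]; }
      deriv(net, Vt, ht, nz, dV4, dh4, f, gE, gI);
      for (int i = 0; i < n; ++i) {
        V[i] += dt / 6.0 * (dV1[i] + 2 * dV2[i] + 2 * dV3[i] + dV4[i]);
        h[i] += dt / 6.0 * (dh1[i] + 2 * dh2[i] + 2 * dh3[i] + dh4[i]);
        const double tau = net.tauNoise[i];
        nz[i] += -nz[i] * dt / tau;
        if (net.sigma[i] > 0)
          nz[i] += net.sigma[i] * sqrt(2.0 * dt / tau) * R::norm_rand();
      }
    } else {
      deriv(net, V, h, nz, dV1, dh1, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * dV1[i]; ht[i] = h[i] + 0.5 * dt * dh1[i]; }
      deriv(net, Vt, ht, nz, dV2, dh2, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * dV2[i]; ht[i] = h[i] + 0.5 * dt * dh2[i]; }
      deriv(net, Vt, ht, nz, dV3, dh3, f, gE, gI);
      for (int i = 0; i < n; ++i) { Vt[i] = V[i] + dt * dV3[i]; ht[i] = h[i] + dt * dh3[i]; }
      deriv(net, Vt, ht, nz, dV4, dh4, f, gE, gI);
      for (int i = 0; i < n; ++i) {
        V[i] += dt / 6.0 * (dV1[i] + 2 * dV2[i] + 2 * dV3[i] + dV4[i]);
        h[i] += dt / 6.0 * (dh1[i] + 2 * dh2[i] + 2 * dh3[i] + dh4[i]);
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0) {
        blew = true; blewAt = s * dt; break;
      }
    }
    if (blew) break;
    if (s % kSamp == 0) {
      tout[is] = s * dt;
      for (int i = 0; i < nrec; ++i) {
        Vout(is, i) = V[record[i]];
        Fout(is, i) =
            fout(V[record[i]], net.Vthr[record[i]], net.Vmax[record[i]]);
      }
      ++is;
    }
  }

  NumericVector fin(3 * n);
  for (int i = 0; i < n; ++i) {
    fin[i] = V[i]; fin[n + i] = h[i]; fin[2 * n + i] = nz[i];
  }
  if (is < nsamp) {
    tout = head(tout, is);
    Vout = Vout(Range(0, std::max(is - 1, 0)), _);
    Fout = Fout(Range(0, std::max(is - 1, 0)), _);
  }
  return List::create(_["time"] = tout, _["V"] = Vout, _["f"] = Fout,
                      _["final"] = fin, _["blewUp"] = blew,
                      _["blewAt"] = blewAt);
}

// [[Rcpp::export]]
NumericVector cpp_state_derivative(List nl, NumericVector state) {
  Net net = unpack(nl);
  const int n = net.n;
  std::vector<double> V(n), h(n), nz(n), dV(n), dh(n), f(n), gE(n), gI(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state[i]; h[i] = state[n + i]; nz[i] = state[2 * n + i];
  }
  deriv(net, V, h, nz, dV, dh, f, gE, gI);
  NumericVector out(2 * n);
  for (int i = 0; i < n; ++i) { out[i] = dV[i]; out[n + i] = dh[i]; }
  return out;
}
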