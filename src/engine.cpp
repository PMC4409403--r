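// Clock-driven network engine: linear-Poisson and conductance-based
// LIF backends with per-synapse axonal/dendritic delays and online
// pairwise STDP (log-STDP at feedforward synapses; weight-independent
// Hebbian / anti-Hebbian / correlation-detector rules at lateral
// synapses).  All times are handled in grid bins of dt ms; PSPs are
// double-exponential state pairs; all-pairs pairing is implemented
// with lazily-decayed per-synapse traces.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rule {
  bool active = false;
  bool logstdp = false;
  double eta = 0, tp = 17, td = 34;
  double a1 = 0, a2 = 0, b1 = 0, b2 = 0;          // lateral branch coefs
  double Cp = 1, Cd = 0.5, alpha = 20, beta = 50; // log-STDP
  double wo = 2.5, wmax = 25, sigma = 0;
};

Rule parse_rule(Nullable<List> maybe) {
  Rule r;
  if (maybe.isNull()) return r;
  List L(maybe);
  r.active = true;
  r.eta = as<double>(L["eta"]);
  r.tp = as<double>(L["tau_p"]);
  r.td = as<double>(L["tau_d"]);
  std::string kind = as<std::string>(L["kind"]);
  if (kind == "log_stdp") {
    r.logstdp = true;
    r.Cp = as<double>(L["Cp"]); r.Cd = as<double>(L["Cd"]);
    r.alpha = as<double>(L["alpha"]); r.beta = as<double>(L["beta"]);
    r.wo = as<double>(L["w_o"]);
  } else {
    r.a1 = as<double>(L["a1"]); r.a2 = as<double>(L["a2"]);
    r.b1 = as<double>(L["b1"]); r.b2 = as<double>(L["b2"]);
  }
  r.wmax = as<double>(L["w_max"]);
  r.sigma = as<double>(L["sigma"]);
  return r;
}

// per-synapse lazy pairing traces for one connection class
struct Traces {
  int n = 0;
  double dt = 0.05;
  std::vector<double> pre_p, pre_d, post_p, post_d;
  std::vector<int> last;
  void init(int n_, double dt_) {
    n = n_; dt = dt_;
    pre_p.assign(n, 0); pre_d.assign(n, 0);
    post_p.assign(n, 0); post_d.assign(n, 0);
    last.assign(n, 0);
  }
  inline void decay_to(int s, int bin, const Rule& r) {
    int db = bin - last[s];
    if (db > 0) {
      double fp = std::exp(-db * dt / r.tp), fd = std::exp(-db * dt / r.td);
      pre_p[s] *= fp; pre_d[s] *= fd;
      post_p[s] *= fp; post_d[s] *= fd;
      last[s] = bin;
    }
  }
};

inline double noise_factor(const Rule& r) {
  if (r.sigma <= 0) return 1.0;
  double xi = norm_rand();
  double lim = 1.0 / r.sigma;
  if (xi > lim) xi = lim; else if (xi < -lim) xi = -lim;
  return 1.0 + r.sigma * xi;
}

inline double fp_log(const Rule& r, double w) {
  return r.Cp * std::exp(-w / (r.beta * r.wo));
}
inline double fd_log(const Rule& r, double w) {
  return -r.Cd * std::log(1.0 + r.alpha * w / r.wo) / std::log(1.0 + r.alpha);
}

// presynaptic at-synapse arrival: LTD read then pre-trace increment
inline void on_pre(Traces& tr, int s, int bin, const Rule& r, double* w) {
  tr.decay_to(s, bin, r);
  if (r.active) {
    double amp;
    if (r.logstdp) amp = r.eta * fd_log(r, *w) * tr.post_d[s];
    else amp = r.eta * (r.b1 * tr.post_p[s] + r.b2 * tr.post_d[s]);
    if (amp != 0) {
      *w += amp * noise_factor(r);
      if (*w < 0) *w = 0; else if (*w > r.wmax) *w = r.wmax;
    }
  }
  tr.pre_p[s] += 1; tr.pre_d[s] += 1;
}

// postsynaptic at-synapse arrival: LTP read then post-trace increment
inline void on_post(Traces& tr, int s, int bin, const Rule& r, double* w) {
  tr.decay_to(s, bin, r);
  if (r.active) {
    double amp;
    if (r.logstdp) amp = r.eta * fp_log(r, *w) * tr.pre_p[s];
    else amp = r.eta * (r.a1 * tr.pre_p[s] + r.a2 * tr.pre_d[s]);
    if (amp != 0) {
      *w += amp * noise_factor(r);
      if (*w < 0) *w = 0; else if (*w > r.wmax) *w = r.wmax;
    }
  }
  tr.post_p[s] += 1; tr.post_d[s] += 1;
}

struct SlotBuf {
  int len = 1;
  std::vector<std::vector<int>> v;
  void init(int maxdelay) { len = maxdelay + 2; v.assign(len, {}); }
  inline std::vector<int>& at(int bin) { return v[bin % len]; }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_network(IntegerVector in_neuron, IntegerVector in_bin,
                     int n_bins, double dt,
                     NumericMatrix WX, NumericMatrix WY, NumericMatrix WZ,
                     IntegerMatrix dXa, IntegerMatrix dXd,
                     IntegerMatrix dY, IntegerMatrix dZ,
                     NumericVector tausX, NumericVector tausY,
                     NumericVector tausZ,
                     double gainE, double gainI,
                     Nullable<List> stdpX, Nullable<List> stdpY,
                     Nullable<List> stdpZ,
                     int snap_every, bool record_u, int u_every,
                     int backend, Nullable<List> lif_params) {
  const int M = WX.nrow(), L = WX.ncol(), N = WY.nrow();
  Rule rX = parse_rule(stdpX), rY = parse_rule(stdpY), rZ = parse_rule(stdpZ);

  // working copies of the weights
  NumericMatrix wx = clone(WX), wy = clone(WY), wz = clone(WZ);

  Traces trX, trY, trZ;
  trX.init(M * L, dt); trY.init(N * M, dt); trZ.init(M * N, dt);

  int maxd = 0;
  for (int i = 0; i < M * L; ++i) {
    int d = dXa[i] + dXd[i];
    if (d > maxd) maxd = d;
    if (dXd[i] > maxd) maxd = dXd[i];
  }
  for (int i = 0; i < N * M; ++i) if (dY[i] > maxd) maxd = dY[i];
  for (int i = 0; i < M * N; ++i) if (dZ[i] > maxd) maxd = dZ[i];

  SlotBuf bufPreX, bufMemX, bufPostX, bufY, bufZ;
  bufPreX.init(maxd); bufMemX.init(maxd); bufPostX.init(maxd);
  bufY.init(maxd); bufZ.init(maxd);

  // double-exponential PSP state pairs (linear Poisson backend)
  std::vector<double> exA(M, 0), exB(M, 0);   // feedforward onto outputs
  std::vector<double> izA(M, 0), izB(M, 0);   // inhibition onto outputs
  std::vector<double> eyA(N, 0), eyB(N, 0);   // excitation onto laterals
  const double dxA = std::exp(-dt / tausX[0]), dxB = std::exp(-dt / tausX[1]);
  const double dyA = std::exp(-dt / tausY[0]), dyB = std::exp(-dt / tausY[1]);
  const double dzA = std::exp(-dt / tausZ[0]), dzB = std::exp(-dt / tausZ[1]);
  const double nx = tausX[0] - tausX[1], ny = tausY[0] - tausY[1],
               nz = tausZ[0] - tausZ[1];

  // LIF state
  bool lif = backend == 1;
  double VL = -70, VE = 0, VI = -80, Vref = -60, Vth = -50;
  double tmE = 20, tmI = 10, tsEE = 5, tsEI = 2.5, tsIE = 4, tsII = 5;
  double rII = 1000, wII = 0.005;
  if (lif && lif_params.isNotNull()) {
    List lp(lif_params);
    VL = as<double>(lp["V_L"]); VE = as<double>(lp["V_E"]);
    VI = as<double>(lp["V_I"]); Vref = as<double>(lp["V_ref"]);
    Vth = as<double>(lp["V_th"]);
    tmE = as<double>(lp["tau_m_E"]); tmI = as<double>(lp["tau_m_I"]);
    tsEE = as<double>(lp["tau_s_EE"]); tsEI = as<double>(lp["tau_s_EI"]);
    tsIE = as<double>(lp["tau_s_IE"]); tsII = as<double>(lp["tau_s_II"]);
    rII = as<double>(lp["r_o_II"]); wII = as<double>(lp["w_II"]);
  }
  std::vector<double> vEm(M, VL), vIm(N, VL);
  std::vector<double> gEE(M, 0), gEI(M, 0), gIE(N, 0), gII(N, 0);
  std::vector<int> refE(M, 0), refI(N, 0);
  const int ref_bins = (int)std::lround(1.0 / dt);
  const double dEE = std::exp(-dt / tsEE), dEI = std::exp(-dt / tsEI),
               dIE = std::exp(-dt / tsIE), dII = std::exp(-dt / tsII);
  const double pII = rII * dt / 1000.0;

  // outputs
  std::vector<int> out_n, out_b, inh_n, inh_b;
  std::vector<NumericMatrix> snapsX, snapsY, snapsZ;
  std::vector<int> snap_bins;
  int n_u = record_u ? ((n_bins + u_every - 1) / u_every) : 0;
  NumericMatrix utrace(record_u ? M : 0, n_u);
  int u_col = 0;
  long clamped = 0;

  int ptr = 0;  // pointer into the sorted input spike list
  const int n_in = in_neuron.size();

  for (int t = 0; t < n_bins; ++t) {
    // ---- schedule today's input spikes (bins are 1-based on entry) --
    // synapse ids are column-major linear indices into the weight
    // matrices: X (j,i) -> j + i*M; Y (k,j) -> k + j*N; Z (j,k) -> j + k*M
    while (ptr < n_in && in_bin[ptr] - 1 == t) {
      int i = in_neuron[ptr] - 1;
      for (int j = 0; j < M; ++j) {
        int s = j + i * M;
        bufPreX.at(t + dXa(j, i)).push_back(s);
        bufMemX.at(t + dXa(j, i) + dXd(j, i)).push_back(s);
      }
      ++ptr;
    }

    // ---- membrane decay -------------------------------------------
    if (!lif) {
      for (int j = 0; j < M; ++j) { exA[j] *= dxA; exB[j] *= dxB;
                                    izA[j] *= dzA; izB[j] *= dzB; }
      for (int k = 0; k < N; ++k) { eyA[k] *= dyA; eyB[k] *= dyB; }
    } else {
      for (int j = 0; j < M; ++j) { gEE[j] *= dEE; gEI[j] *= dEI; }
      for (int k = 0; k < N; ++k) { gIE[k] *= dIE; gII[k] *= dII; }
      for (int k = 0; k < N; ++k) if (unif_rand() < pII) gII[k] += wII;
    }

    // ---- deliver pre-arrival events (LTD + trace), then post --------
    {
      std::vector<int>& ev = bufPreX.at(t);
      for (int s : ev) on_pre(trX, s, t, rX, &wx[s]);
      ev.clear();
    }
    {
      std::vector<int>& ev = bufPostX.at(t);
      for (int s : ev) on_post(trX, s, t, rX, &wx[s]);
      ev.clear();
    }
    {
      std::vector<int>& ev = bufY.at(t);   // pre arrival == membrane arrival
      for (int s : ev) on_pre(trY, s, t, rY, &wy[s]);
      for (int s : ev) {
        int kk = s % N;                    // s = k + j * N
        if (!lif) { eyA[kk] += wy[s]; eyB[kk] += wy[s]; }
        else gIE[kk] += wy[s];
      }
      ev.clear();
    }
    {
      std::vector<int>& ev = bufZ.at(t);
      for (int s : ev) on_pre(trZ, s, t, rZ, &wz[s]);
      for (int s : ev) {
        int jj = s % M;                    // s = j + k * M
        if (!lif) { izA[jj] += wz[s]; izB[jj] += wz[s]; }
        else gEI[jj] += wz[s];
      }
      ev.clear();
    }
    {
      std::vector<int>& ev = bufMemX.at(t);
      for (int s : ev) {
        int jj = s % M;                    // s = j + i * M
        if (!lif) { exA[jj] += wx[s]; exB[jj] += wx[s]; }
        else gEE[jj] += wx[s];
      }
      ev.clear();
    }

    // ---- membranes and spikes --------------------------------------
    for (int j = 0; j < M; ++j) {
      bool spike = false;
      double u = 0;
      if (!lif) {
        u = (exA[j] - exB[j]) / nx - (izA[j] - izB[j]) / nz;
        double pr = gainE * u * dt;
        if (pr > 0) {
          if (pr >= 1) { pr = 1; ++clamped; }
          spike = unif_rand() < pr;
        }
      } else {
        if (refE[j] > 0) { --refE[j]; vEm[j] = Vref; }
        else {
          double v = vEm[j];
          auto f = [&](double vv) {
            return -(vv - VL) / tmE - gEE[j] * (vv - VE) - gEI[j] * (vv - VI);
          };
          double vmid = v + 0.5 * dt * f(v);
          v += dt * f(vmid);
          if (v >= Vth) { spike = true; v = Vref; refE[j] = ref_bins; }
          vEm[j] = v;
        }
        u = vEm[j];
      }
      if (record_u && t % u_every == 0) utrace(j, u_col) = u;
      if (spike) {
        out_n.push_back(j + 1); out_b.push_back(t + 1);
        // post events at X synapses after the dendritic delay
        for (int i = 0; i < L; ++i)
          bufPostX.at(t + dXd(j, i)).push_back(j + i * M);
        // excitation of lateral neurons; pre events for Y synapses
        for (int k = 0; k < N; ++k)
          bufY.at(t + dY(k, j)).push_back(k + j * N);
        // immediate post updates at Z synapses (no dendritic delay)
        for (int k = 0; k < N; ++k)
          on_post(trZ, j + k * M, t, rZ, &wz[j + k * M]);
      }
    }
    if (record_u && t % u_every == 0) ++u_col;

    for (int k = 0; k < N; ++k) {
      bool spike = false;
      if (!lif) {
        double u = (eyA[k] - eyB[k]) / ny;
        double pr = gainI * u * dt;
        if (pr > 0) {
          if (pr >= 1) { pr = 1; ++clamped; }
          spike = unif_rand() < pr;
        }
      } else {
        if (refI[k] > 0) { --refI[k]; vIm[k] = Vref; }
        else {
          double v = vIm[k];
          auto f = [&](double vv) {
            return -(vv - VL) / tmI - gIE[k] * (vv - VE) - gII[k] * (vv - VI);
          };
          double vmid = v + 0.5 * dt * f(v);
          v += dt * f(vmid);
          if (v >= Vth) { spike = true; v = Vref; refI[k] = ref_bins; }
          vIm[k] = v;
        }
      }
      if (spike) {
        inh_n.push_back(k + 1); inh_b.push_back(t + 1);
        // immediate post updates at Y synapses
        for (int j = 0; j < M; ++j)
          on_post(trY, k + j * N, t, rY, &wy[k + j * N]);
        // delayed inhibition onto outputs; pre events for Z synapses
        for (int j = 0; j < M; ++j)
          bufZ.at(t + dZ(j, k)).push_back(j + k * M);
      }
    }

    if (snap_every > 0 && (t + 1) % snap_every == 0) {
      snapsX.push_back(clone(wx));
      if (rY.active) snapsY.push_back(clone(wy));
      if (rZ.active) snapsZ.push_back(clone(wz));
      snap_bins.push_back(t + 1);
    }
  }

  List out = List::create(
    _["out_spk"] = DataFrame::create(_["neuron"] = wrap(out_n),
                                     _["bin"] = wrap(out_b)),
    _["inh_spk"] = DataFrame::create(_["neuron"] = wrap(inh_n),
                                     _["bin"] = wrap(inh_b)),
    _["W_X"] = wx, _["W_Y"] = wy, _["W_Z"] = wz,
    _["snapshots_X"] = wrap(snapsX), _["snapshots_Y"] = wrap(snapsY),
    _["snapshots_Z"] = wrap(snapsZ), _["snap_bins"] = wrap(snap_bins),
    _["clamped"] = (double)clamped);
  if (record_u) out["u_E"] = utrace;
  return out;
}
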