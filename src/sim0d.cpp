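// Zero-dimensional closed-loop circulation with a three-layer intramyocardial
// perfusion bed fed through a graft branch (lumped resistance + inertance +
// optional stenosis element).  Fixed-step classical RK4; the right-hand side
// lives here once and is exposed to R both directly (rhs0d_cpp) and through
// the integrator (sim0d_cpp).
//
// Units: mmHg, mL, s throughout.  The stenosis element's coefficients are
// pre-converted from CGS on the R side (see stenosis_coefficients()).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// --- context vector layout (see build_sim_context() in R/model.R) ----------
enum ctx_idx {
  C_T = 0, C_TSYS, C_EMAXL, C_EMINL, C_EMAXR, C_EMINR, C_V0LV, C_V0RV,
  C_RMV, C_RAV, C_RTV, C_RPV,
  C_CSA, C_LSA, C_RSVB, C_CSV,
  C_CPA, C_LPA, C_RPVB, C_CPV,
  C_RG, C_LG, C_STRV, C_STKT,
  C_VUSA, C_VUSV, C_VUPA, C_VUPU, C_VW,
  C_CCOR, C_VUCOR,     // distal (epicardial) node compliance + unstressed vol
  C_CGP, C_VUGP,       // proximal graft compliance + unstressed volume
  C_STEN,              // stenosis element switch (1 in, 0 out)
  C_DEPTH0,            // 34..36 layer mid-depth fractions (epi, mid, endo)
  C_C1_0   = 37,       // per-layer arterial-side compliances
  C_C2_0   = 40,       // per-layer venous-side compliances
  C_V01_0  = 43,       // per-layer arterial reference volumes
  C_V02_0  = 46,       // per-layer venous reference volumes
  C_R0A_0  = 49,       // per-layer arterial reference resistances
  C_R0M_0  = 52,       // per-layer middle reference resistances
  C_RV_0   = 55,       // per-layer venous (constant) resistances
  C_VU1_0  = 58,       // per-layer arterial unstressed volumes
  C_VU2_0  = 61,       // per-layer venous unstressed volumes
  CTX_LEN  = 64
};

// state vector layout
enum st_idx {
  S_VLV = 0, S_VRV, S_VSA, S_VSV, S_VPA, S_VPU,
  S_QSA, S_QPA, S_QG,
  S_VGP  = 9,          // proximal graft stored volume (probe side)
  S_VCOR = 10,         // distal epicardial node stored volume
  S_V1_0 = 11,         // layer arterial volumes
  S_V2_0 = 14,         // layer venous volumes
  ST_LEN = 17
};

static const int N_OUT = 17; // derived signals recorded alongside time

// Pressure-gated valve with a smoothing width w (mmHg): zero for reverse
// bias, asymptotically dp/R for dp >> w, C1-continuous at dp = 0.
static inline double valve_flow(double dp, double R, double w) {
  return dp > 0.0 ? dp * dp / ((dp + w) * R) : 0.0;
}

static void rhs(double t, const double *y, const double *c,
                double *dy, double *out) {
  const double T = c[C_T], Tsys = c[C_TSYS];
  double tb = t - T * std::floor(t / T);
  // rise-plateau-fall activation: half-cosine rise over 0.4 * Tsys, hold
  // at the peak until 0.75 * Tsys, half-cosine relaxation over the rest;
  // C1-continuous everywhere
  const double tr = 0.4 * Tsys, th = 0.75 * Tsys, tf = Tsys - th;
  double phi = 0.0;
  if (tb < tr)        phi = 0.5 * (1.0 - std::cos(M_PI * tb / tr));
  else if (tb < th)   phi = 1.0;
  else if (tb < Tsys) phi = 0.5 * (1.0 + std::cos(M_PI * (tb - th) / tf));
  const double EL = c[C_EMINL] + (c[C_EMAXL] - c[C_EMINL]) * phi;
  const double ER = c[C_EMINR] + (c[C_EMAXR] - c[C_EMINR]) * phi;

  const double plv = EL * (y[S_VLV] - c[C_V0LV]);
  const double prv = ER * (y[S_VRV] - c[C_V0RV]);
  const double psa = (y[S_VSA] - c[C_VUSA]) / c[C_CSA];
  const double psv = (y[S_VSV] - c[C_VUSV]) / c[C_CSV];
  const double ppa = (y[S_VPA] - c[C_VUPA]) / c[C_CPA];
  const double ppu = (y[S_VPU] - c[C_VUPU]) / c[C_CPV];

  const double w = c[C_VW];
  const double qmv = valve_flow(ppu - plv, c[C_RMV], w);
  const double qav = valve_flow(plv - psa, c[C_RAV], w);
  const double qtv = valve_flow(psv - prv, c[C_RTV], w);
  const double qpv = valve_flow(prv - ppa, c[C_RPV], w);

  // graft branch: proximal compliance (probe side), stenosis through-flow
  // (algebraic: its quadratic law needs no inertial state; the inertial
  // term is lumped into the graft inertance), distal epicardial node
  const bool sten_in = c[C_STEN] > 0.5;
  double pgp, pnode, Qs;
  if (sten_in) {
    pgp   = (y[S_VGP]  - c[C_VUGP])  / c[C_CGP];
    pnode = (y[S_VCOR] - c[C_VUCOR]) / c[C_CCOR];
    const double dps = pgp - pnode, adp = std::fabs(dps);
    const double Rv = c[C_STRV], Kt = c[C_STKT];
    double q;
    if (Kt * adp < 1e-12) q = adp / Rv;
    else q = (-Rv + std::sqrt(Rv * Rv + 4.0 * Kt * adp)) / (2.0 * Kt);
    Qs = (dps >= 0.0) ? q : -q;
  } else {
    // element switched out: the two nodes merge (zero pressure drop)
    pgp = pnode = (y[S_VGP] + y[S_VCOR] - c[C_VUGP] - c[C_VUCOR]) /
                  (c[C_CGP] + c[C_CCOR]);
    Qs = 0.0; // through-flow is implicit in the merged node
  }
  double qa_sum = 0.0, qv_sum = 0.0, Qm[3];
  for (int j = 0; j < 3; ++j) {
    const double V1 = y[S_V1_0 + j], V2 = y[S_V2_0 + j];
    const double pim = c[C_DEPTH0 + j] * plv;
    const double p1 = (V1 - c[C_VU1_0 + j]) / c[C_C1_0 + j] + pim;
    const double p2 = (V2 - c[C_VU2_0 + j]) / c[C_C2_0 + j] + pim;
    const double r1 = c[C_V01_0 + j] / V1;
    const double Ra = c[C_R0A_0 + j] * r1 * r1;
    const double r2 = (c[C_V01_0 + j] + c[C_V02_0 + j]) / (V1 + V2);
    const double Rm = c[C_R0M_0 + j] * r2 * r2;
    const double Qa = (pnode - p1) / Ra;
    Qm[j] = (p1 - p2) / Rm;
    const double Qv = (p2 - psv) / c[C_RV_0 + j];
    dy[S_V1_0 + j] = Qa - Qm[j];
    dy[S_V2_0 + j] = Qm[j] - Qv;
    qa_sum += Qa;
    qv_sum += Qv;
  }
  const double Qg = y[S_QG];
  if (sten_in) {
    dy[S_VGP]  = Qg - Qs;
    dy[S_VCOR] = Qs - qa_sum;
  } else {
    const double net = Qg - qa_sum;
    const double fgp = c[C_CGP] / (c[C_CGP] + c[C_CCOR]);
    dy[S_VGP]  = net * fgp;
    dy[S_VCOR] = net * (1.0 - fgp);
    Qs = Qg; // reported through-flow of the switched-out element
  }

  dy[S_VLV] = qmv - qav;
  dy[S_VRV] = qtv - qpv;
  dy[S_VSA] = qav - y[S_QSA] - Qg;
  dy[S_VSV] = y[S_QSA] + qv_sum - qtv;
  dy[S_VPA] = qpv - y[S_QPA];
  dy[S_VPU] = y[S_QPA] - qmv;
  dy[S_QSA] = (psa - psv - c[C_RSVB] * y[S_QSA]) / c[C_LSA];
  dy[S_QPA] = (ppa - ppu - c[C_RPVB] * y[S_QPA]) / c[C_LPA];
  dy[S_QG]  = (psa - pgp - c[C_RG] * Qg) / c[C_LG];

  if (out != nullptr) {
    out[0]  = psa;                    // aortic / systemic arterial pressure
    out[1]  = plv;
    out[2]  = prv;
    out[3]  = psv;
    out[4]  = ppa;
    out[5]  = ppu;
    out[6]  = pgp;                    // graft probe pressure (pre-stenosis)
    out[7]  = qav;
    out[8]  = qmv;
    out[9]  = Qg;                     // probe-site graft flow
    out[10] = Qm[0];                  // subepicardial layer flow
    out[11] = Qm[1];                  // mid-wall layer flow
    out[12] = Qm[2];                  // subendocardial layer flow
    out[13] = y[S_VLV];
    out[14] = y[S_VRV];
    double vtot = 0.0;
    for (int i = 0; i < ST_LEN; ++i)
      if (i != S_QSA && i != S_QPA && i != S_QG) vtot += y[i];
    out[15] = vtot;
    out[16] = Qs;                     // stenosis through-flow
  }
}

// [[Rcpp::export]]
NumericVector rhs0d_cpp(NumericVector y, double t, NumericVector ctx) {
  if (y.size() != ST_LEN) stop("state vector must have length %d", ST_LEN);
  if (ctx.size() != CTX_LEN) stop("context vector must have length %d", CTX_LEN);
  NumericVector dy(ST_LEN);
  rhs(t, y.begin(), ctx.begin(), dy.begin(), nullptr);
  return dy;
}

// [[Rcpp::export]]
NumericVector signals0d_cpp(NumericVector y, double t, NumericVector ctx) {
  if (y.size() != ST_LEN) stop("state vector must have length %d", ST_LEN);
  NumericVector dy(ST_LEN), out(N_OUT);
  rhs(t, y.begin(), ctx.begin(), dy.begin(), out.begin());
  return out;
}

// Classical RK4 with fixed step dt over n_steps steps, storing every
// `stride`-th sample (including step 0 and the final step).
// [[Rcpp::export]]
List sim0d_cpp(NumericVector y0, NumericVector ctx, double dt,
               int n_steps, int stride) {
  if (y0.size() != ST_LEN) stop("state vector must have length %d", ST_LEN);
  if (ctx.size() != CTX_LEN) stop("context vector must have length %d", CTX_LEN);
  if (stride < 1) stride = 1;

  const int n_store = n_steps / stride + 1;
  NumericMatrix sig(n_store, 1 + N_OUT);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ST_LEN), k2(ST_LEN), k3(ST_LEN), k4(ST_LEN),
      tmp(ST_LEN), out(N_OUT);

  bool ok = true;
  int fail_step = -1;
  int row = 0;

  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    if (step % stride == 0 && row < n_store) {
      rhs(t, y.data(), ctx.begin(), k1.data(), out.data());
      sig(row, 0) = t;
      for (int i = 0; i < N_OUT; ++i) sig(row, 1 + i) = out[i];
      ++row;
    }
    if (step == n_steps) break;

    rhs(t, y.data(), ctx.begin(), k1.data(), nullptr);
    for (int i = 0; i < ST_LEN; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(t + 0.5 * dt, tmp.data(), ctx.begin(), k2.data(), nullptr);
    for (int i = 0; i < ST_LEN; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    rhs(t + 0.5 * dt, tmp.data(), ctx.begin(), k3.data(), nullptr);
    for (int i = 0; i < ST_LEN; ++i) tmp[i] = y[i] + dt * k3[i];
    rhs(t + dt, tmp.data(), ctx.begin(), k4.data(), nullptr);
    for (int i = 0; i < ST_LEN; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    for (int i = 0; i < ST_LEN; ++i) {
      if (!std::isfinite(y[i])) { ok = false; break; }
    }
    // collapsed intramyocardial vessels leave the model's validity region
    for (int j = 0; j < 3 && ok; ++j)
      if (y[S_V1_0 + j] <= 0.0 || y[S_V2_0 + j] <= 0.0) ok = false;
    if (!ok) { fail_step = step + 1; break; }
  }

  return List::create(_["signals"] = sig,
                      _["y_final"] = NumericVector(y.begin(), y.end()),
                      _["ok"] = ok,
                      _["fail_step"] = fail_step,
                      _["rows"] = row);
}
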