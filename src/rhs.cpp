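#include <Rcpp.h>
using namespace Rcpp;

// Compiled core of the synovium model: right-hand side of the cell/mediator
// ODE system and a damped fixed-point (Picard) steady-state solver. The R
// layer packs the network + patient into flat arrays (see build_model());
// therapy exposure is evaluated in closed form from the linear PK model.

namespace {

struct Model {
  int nc, nm, ns, ne;
  NumericVector kg, kin, kdeg, clr, Fm;
  IntegerVector sec_cell, sec_med, sec_mtx_mode;
  NumericVector ksec;
  IntegerVector influx_mtx;
  double kdiff;
  int diff_src, diff_dst;
  IntegerVector e_tk, e_ti, e_reg, e_sign;
  NumericVector e_vm, e_km, e_sl;
  IntegerVector es_sec, es_med;
  NumericVector es_km, es_sl;
  int cam_med, cam_drv;
  double cam_km, cam_sl, cam_level, cam_krelax;
  double pro_limit, anti_limit;
  int tnfa_idx, il6_idx;

  explicit Model(const List& m)
      : nc(as<int>(m["nc"])), nm(as<int>(m["nm"])),
        ns(as<int>(m["ns"])), ne(as<int>(m["ne"])),
        kg(m["kg"]), kin(m["kin"]), kdeg(m["kdeg"]), clr(m["clr"]),
        Fm(m["Fm"]), sec_cell(m["sec_cell"]), sec_med(m["sec_med"]),
        sec_mtx_mode(m["sec_mtx_mode"]), ksec(m["ksec"]),
        influx_mtx(m["influx_mtx"]), kdiff(as<double>(m["kdiff"])),
        diff_src(as<int>(m["diff_src"])), diff_dst(as<int>(m["diff_dst"])),
        e_tk(m["e_tk"]), e_ti(m["e_ti"]), e_reg(m["e_reg"]),
        e_sign(m["e_sign"]), e_vm(m["e_vm"]), e_km(m["e_km"]),
        e_sl(m["e_sl"]), es_sec(m["es_sec"]), es_med(m["es_med"]),
        es_km(m["es_km"]), es_sl(m["es_sl"]),
        cam_med(as<int>(m["cam_med"])), cam_drv(as<int>(m["cam_drv"])),
        cam_km(as<double>(m["cam_km"])), cam_sl(as<double>(m["cam_sl"])),
        cam_level(as<double>(m["cam_level"])),
        cam_krelax(as<double>(m["cam_krelax"])),
        pro_limit(as<double>(m["pro_limit"])),
        anti_limit(as<double>(m["anti_limit"])),
        tnfa_idx(as<int>(m["tnfa_idx"])), il6_idx(as<int>(m["il6_idx"])) {}
};

// Drug exposure is evaluated exactly as a superposition of per-dose
// bi-exponential disposition terms (linear PK), so the forcing is smooth
// within dose intervals.
struct Therapy {
  bool active;
  double dose_mg, interval;
  int n_doses;
  double a1, l1, a2, l2;              // central conc per mg dose
  double mtx_scale, ada_scale, tcz_scale;
  double mtx_vm, mtx_km, mtx_slope, kd_ada, kd_tcz;

  Therapy() : active(false) {}
  explicit Therapy(const List& th)
      : active(true), dose_mg(as<double>(th["dose_mg"])),
        interval(as<double>(th["interval"])),
        n_doses(as<int>(th["n_doses"])),
        a1(as<double>(th["a1"])), l1(as<double>(th["l1"])),
        a2(as<double>(th["a2"])), l2(as<double>(th["l2"])),
        mtx_scale(as<double>(th["mtx_scale"])),
        ada_scale(as<double>(th["ada_scale"])),
        tcz_scale(as<double>(th["tcz_scale"])),
        mtx_vm(as<double>(th["mtx_vm"])), mtx_km(as<double>(th["mtx_km"])),
        mtx_slope(as<double>(th["mtx_slope"])),
        kd_ada(as<double>(th["kd_ada"])), kd_tcz(as<double>(th["kd_tcz"])) {}

  double central(double t) const {
    if (dose_mg <= 0) return 0;
    double c = 0;
    for (int d = 0; d < n_doses; ++d) {
      double dt = t - d * interval;
      if (dt < 0) break;
      c += a1 * std::exp(-l1 * dt) + a2 * std::exp(-l2 * dt);
    }
    return dose_mg * c;
  }
};

struct Exposure {
  double anti_cytsec = 0, pro_cytsec = 0, anti_influx = 0;
  double free_tnf_scale = 1; // free/total TNF-a under ADA binding
  double il6_clr_mult = 1;   // effective IL-6 clearance multiplier (>= 1)
};

Exposure exposure_at(const Model& mod, const Therapy& th, double t,
                     double tnf_total) {
  Exposure ex;
  if (!th.active) return ex;
  double cc = th.central(t);
  double c_mtx = th.mtx_scale * cc;
  if (c_mtx > 0) {
    double cs = std::pow(c_mtx, th.mtx_slope);
    double e = th.mtx_vm * cs / (cs + std::pow(th.mtx_km, th.mtx_slope));
    ex.anti_cytsec = ex.pro_cytsec = ex.anti_influx = e;
  }
  double c_ada = th.ada_scale * cc;
  if (c_ada > 0 && tnf_total > 0) {
    double b = tnf_total - c_ada - th.kd_ada;
    double free = 0.5 * (b + std::sqrt(b * b + 4 * th.kd_ada * tnf_total));
    if (free < 0) free = 0;
    if (free > tnf_total) free = tnf_total;
    ex.free_tnf_scale = free / tnf_total;
  }
  double c_tcz = th.tcz_scale * cc;
  if (c_tcz > 0)
    ex.il6_clr_mult = (c_tcz + th.kd_tcz) / th.kd_tcz;
  return ex;
}

inline double hillv(double c, double vm, double km, double sl) {
  if (c <= 0) return 0;
  double cs = std::pow(c, sl);
  return vm * cs / (cs + std::pow(km, sl));
}

// Compute per-process multiplicative factors at a state. Layout of `fac`:
// [0,nc) prolif, [nc,2nc) influx, [2nc,3nc) deg, [3nc,3nc+ns) secretion,
// [3nc+ns] differentiation. Secretion factors include essential gates.
void process_factors(const Model& mod, const double* cell,
                     const double* conc_eff, std::vector<double>& fac) {
  int nt = 3 * mod.nc + mod.ns + 1;
  static std::vector<double> pro, anti;
  pro.assign(nt, 0.0);
  anti.assign(nt, 0.0);
  for (int k = 0; k < mod.ne; ++k) {
    int slot;
    switch (mod.e_tk[k]) {
      case 0: slot = mod.e_ti[k]; break;
      case 1: slot = mod.nc + mod.e_ti[k]; break;
      case 2: slot = 2 * mod.nc + mod.e_ti[k]; break;
      case 3: slot = 3 * mod.nc + mod.e_ti[k]; break;
      default: slot = 3 * mod.nc + mod.ns;
    }
    double h = hillv(conc_eff[mod.e_reg[k]], mod.e_vm[k], mod.e_km[k],
                     mod.e_sl[k]);
    if (mod.e_sign[k] > 0) pro[slot] += h; else anti[slot] += h;
  }
  fac.assign(nt, 1.0);
  for (int s = 0; s < nt; ++s) {
    double p = pro[s] > mod.pro_limit ? mod.pro_limit : pro[s];
    double a = anti[s] > mod.anti_limit ? mod.anti_limit : anti[s];
    fac[s] = (1 + p) * (1 - a);
  }
  for (int g = 0; g < mod.es_sec.size(); ++g) {
    double c = conc_eff[mod.es_med[g]];
    double cs = c <= 0 ? 0 : std::pow(c, mod.es_sl[g]);
    double gate = cs / (cs + std::pow(mod.es_km[g], mod.es_sl[g]));
    fac[3 * mod.nc + mod.es_sec[g]] *= gate;
  }
}

void rhs_core(const Model& mod, const Therapy& th, double t,
              const double* y, double* dy) {
  static std::vector<double> cell, conc, conc_eff;
  cell.assign(mod.nc, 0.0);
  conc.assign(mod.nm, 0.0);
  conc_eff.assign(mod.nm, 0.0);
  for (int i = 0; i < mod.nc; ++i) cell[i] = y[i] > 0 ? y[i] : 0;
  for (int j = 0; j < mod.nm; ++j) conc[j] = y[mod.nc + j] > 0 ? y[mod.nc + j] : 0;

  Exposure ex = exposure_at(mod, th, t, conc[mod.tnfa_idx]);
  for (int j = 0; j < mod.nm; ++j) conc_eff[j] = conc[j];
  conc_eff[mod.tnfa_idx] *= ex.free_tnf_scale;

  static std::vector<double> fac;
  process_factors(mod, cell.data(), conc_eff.data(), fac);

  for (int i = 0; i < mod.nc; ++i) {
    double prolif = mod.kg[i] * fac[i];
    double influx = mod.kin[i] * fac[mod.nc + i];
    if (mod.influx_mtx[i]) influx *= (1 - ex.anti_influx);
    double deg = mod.kdeg[i] * fac[2 * mod.nc + i] * y[i];
    dy[i] = prolif + influx - deg;
  }
  double fdiff = mod.kdiff * fac[3 * mod.nc + mod.ns] * cell[mod.diff_src];
  dy[mod.diff_src] -= fdiff;
  dy[mod.diff_dst] += fdiff;

  static std::vector<double> prod;
  prod.assign(mod.nm, 0.0);
  for (int s = 0; s < mod.ns; ++s) {
    double flux = mod.ksec[s] * cell[mod.sec_cell[s]] * fac[3 * mod.nc + s];
    if (mod.sec_mtx_mode[s] < 0) flux *= (1 - ex.anti_cytsec);
    else if (mod.sec_mtx_mode[s] > 0) flux *= (1 + ex.pro_cytsec);
    prod[mod.sec_med[s]] += flux;
  }
  for (int j = 0; j < mod.nm; ++j) {
    double cl = mod.clr[j];
    if (j == mod.il6_idx) cl *= ex.il6_clr_mult;
    dy[mod.nc + j] = mod.Fm[j] * prod[j] - cl * y[mod.nc + j];
  }
  // CAM relaxes to its endothelial-driven level
  double e = cell[mod.cam_drv];
  double es = e <= 0 ? 0 : std::pow(e, mod.cam_sl);
  double target = mod.Fm[mod.cam_med] * mod.cam_level * es /
                  (es + std::pow(mod.cam_km, mod.cam_sl));
  dy[mod.nc + mod.cam_med] =
      mod.cam_krelax * (target - y[mod.nc + mod.cam_med]);
}

Therapy make_therapy(Nullable<List> therapy) {
  if (therapy.isNotNull()) return Therapy(therapy.get());
  return Therapy();
}

// Integration context for the deSolve compiled-function interface: the
// model/therapy are installed once per integration, then the solver calls
// the plain-C derivative below with no R overhead per step.
Model* g_model = nullptr;
Therapy g_therapy;

} // namespace

// [[Rcpp::export]]
void rasim_set_context_(List model, Nullable<List> therapy) {
  delete g_model;
  g_model = new Model(model);
  g_therapy = make_therapy(therapy);
}

extern "C" void rasim_derivs_c(int* neq, double* t, double* y, double* ydot,
                               double* yout, int* ip) {
  rhs_core(*g_model, g_therapy, *t, y, ydot);
}

// Re-enable lookup of exported C symbols by name (deSolve resolves
// rasim_derivs_c via getNativeSymbolInfo).
// [[Rcpp::init]]
void rasim_dyn_init(DllInfo* dll) {
  R_useDynamicSymbols(dll, TRUE);
}

// [[Rcpp::export]]
NumericVector rasim_rhs_(double t, NumericVector y, List model,
                         Nullable<List> therapy) {
  Model mod(model);
  Therapy th = make_therapy(therapy);
  NumericVector dy(y.size());
  rhs_core(mod, th, t, REAL(y), REAL(dy));
  return dy;
}

// Damped Picard iteration on the algebraic steady-state system: each species
// is moved (in log space) toward production/removal balance at the current
// state. Returns the candidate state plus the scaled residual of the true
// right-hand side so callers can verify convergence.
// [[Rcpp::export]]
List rasim_picard_(List model, NumericVector y0, Nullable<List> therapy,
                   double t, int maxit, double tol, double damp) {
  Model mod(model);
  Therapy th = make_therapy(therapy);
  int n = mod.nc + mod.nm;
  std::vector<double> x(y0.begin(), y0.end());
  const double floor_ = 1e-30;
  for (int i = 0; i < n; ++i) if (x[i] < floor_) x[i] = floor_;

  std::vector<double> fac;
  std::vector<double> cell(mod.nc), conc(mod.nm), conc_eff(mod.nm);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    for (int i = 0; i < mod.nc; ++i) cell[i] = x[i];
    for (int j = 0; j < mod.nm; ++j) conc[j] = x[mod.nc + j];
    Exposure ex = exposure_at(mod, th, t, conc[mod.tnfa_idx]);
    for (int j = 0; j < mod.nm; ++j) conc_eff[j] = conc[j];
    conc_eff[mod.tnfa_idx] *= ex.free_tnf_scale;
    process_factors(mod, cell.data(), conc_eff.data(), fac);

    double maxstep = 0;
    std::vector<double> xn(n);
    double fdiff_rate = mod.kdiff * fac[3 * mod.nc + mod.ns];
    for (int i = 0; i < mod.nc; ++i) {
      double prod = mod.kg[i] * fac[i];
      double influx = mod.kin[i] * fac[mod.nc + i];
      if (mod.influx_mtx[i]) influx *= (1 - ex.anti_influx);
      prod += influx;
      if (i == mod.diff_dst) prod += fdiff_rate * cell[mod.diff_src];
      double rem = mod.kdeg[i] * fac[2 * mod.nc + i];
      if (i == mod.diff_src) rem += fdiff_rate;
      xn[i] = prod > 0 ? prod / rem : floor_;
    }
    std::vector<double> prod_m(mod.nm, 0.0);
    for (int s = 0; s < mod.ns; ++s) {
      double flux = mod.ksec[s] * cell[mod.sec_cell[s]] * fac[3 * mod.nc + s];
      if (mod.sec_mtx_mode[s] < 0) flux *= (1 - ex.anti_cytsec);
      else if (mod.sec_mtx_mode[s] > 0) flux *= (1 + ex.pro_cytsec);
      prod_m[mod.sec_med[s]] += flux;
    }
    for (int j = 0; j < mod.nm; ++j) {
      double cl = mod.clr[j];
      if (j == mod.il6_idx) cl *= ex.il6_clr_mult;
      double v = mod.Fm[j] * prod_m[j] / cl;
      xn[mod.nc + j] = v > 0 ? v : floor_;
    }
    double e = cell[mod.cam_drv];
    double es = e <= 0 ? 0 : std::pow(e, mod.cam_sl);
    double camt = mod.Fm[mod.cam_med] * mod.cam_level * es /
                  (es + std::pow(mod.cam_km, mod.cam_sl));
    xn[mod.nc + mod.cam_med] = camt > 0 ? camt : floor_;

    for (int i = 0; i < n; ++i) {
      double step = std::log(xn[i] / x[i]);
      if (std::fabs(step) > maxstep) maxstep = std::fabs(step);
      x[i] = x[i] * std::exp(damp * step);
    }
    if (maxstep < tol) { converged = true; ++it; break; }
  }

  NumericVector xf(x.begin(), x.end());
  NumericVector dy(n);
  rhs_core(mod, th, t, REAL(xf), REAL(dy));
  double resid = 0;
  for (int i = 0; i < n; ++i) {
    double scale = std::fabs(x[i]);
    if (scale < 1e-12) scale = 1e-12;
    double r = std::fabs(dy[i]) / scale;
    if (r > resid) resid = r;
  }
  return List::create(_["state"] = xf, _["iterations"] = it,
                      _["converged"] = converged, _["residual"] = resid);
}
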