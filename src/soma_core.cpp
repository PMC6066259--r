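// Fixed-step integrator for the assembled soma model: linearized implicit
// voltage update, exact exponential gate updates from voltage-indexed lookup
// tables supplied by the R layer, and the 12-shell Ca2+/IP3 system.
// Units follow the package convention: mV, ms, mM, mA/cm2, S/cm2, cm/s, um.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212;   // C/mol

// gate indices (columns of the inf/tau tables and entries of the gate state)
enum Gate {
  G_TTXS_M, G_TTXS_H, G_NAV18_M, G_NAV18_H, G_KA_N, G_KA_HF, G_KA_HS,
  G_KDR_N, G_BK_N, G_CAL_M, G_CAL_H, G_CAN_M, G_CAN_H, G_NAV19_M,
  G_NAV19_H, G_KCNQ_N, G_HCN_M, G_CAT_M, G_CAT_H, G_CAPQ_M, G_CAR_M,
  G_CAR_H, NGATE
};

// mechanism order for the record matrix (matches the R layer)
enum Mech {
  M_PAS, M_TTXS, M_NAV18, M_NAV19, M_KA, M_KDR, M_KCNQ, M_KNA, M_BK, M_SK,
  M_CAL, M_CAN, M_CAPQ, M_CAR, M_CAT, M_SOCC, M_TRPM8, M_CACC, M_NAK,
  M_NCX, M_PMCA, M_HCN, NMECH
};

struct Params {
  double area_cm2, cm_spec;      // membrane area (cm2), uF/cm2
  double rtf_mV;                 // RT/F in mV at model temperature
  double e_na, e_k, e_cl, e_pas, e_hcn, e_trpm8;
  double g_pas, g_ttxs, g_nav18, g_nav19, g_ka, g_kdr, g_kcnq, g_kna,
      g_bk, g_sk, g_hcn, p_cal, p_can, p_capq, p_car, p_cat, p_socc,
      g_trpm8, g_cacc, i_nak, k_ncx;
  double na_i, na_o, ca_o, k_o;
  double kna_ec50, kna_hill;
  double nak_km_na, nak_km_k;
  double ncx_eta, ncx_ksat, ncx_kmna, ncx_kmca;
  double trpm8_vhalf, trpm8_vslope, trpm8_fca;
  double cacc_ec50, cacc_hill, cacc_vhalf, cacc_vslope, cacc_wip3;
  double socc_k, socc_hill;
  double can_a;
  double cdi_k, cdi_n;
  double sk_ec50, sk_hill;
  int sk_rectify;
  std::vector<double> sk_ca, sk_v12, sk_sf;
  double v_min, v_step;
  int nv;
  std::vector<double> tab_inf, tab_tau;  // column-major nv x NGATE
  int ca_on, ns;
  std::vector<double> v_cyt, v_er, cs_area, cs_dr;  // um3, um2, um
  double d_ca, beta_cyt, d_ip3, k_degr_ip3, ip3_rest;
  double k_ip3, k_act_ip3, k_on_ip3, k_inh_ip3, j_ip3r_bar;
  double v_serca, k_psr, n_serca;
  double v_cicr, k_cicr, k_t_cicr;
  double kb_er, btot_er, kb_mt, btot_mt;
  double v_mcu, k_mcu, n_mcu, v_mncx, k_na_mncx, k_ca_mncx, mcu_scale;
  double l_er;
  double pk1, pk2, pk3, pk4;  // PMCA rates per ms
  int dye_on, dye_cyt;        // dye_cyt: 1 cytosolic dye, 0 mitochondrial
  double dye_kb, dye_btot, dye_d;
  int en_pmca, en_serca, en_ip3r, en_cicr, en_leak, en_mcu, en_mncx,
      en_diff, en_mem;
  double ca_fixed, caer_fixed;  // near-membrane values when ca_on == 0
};

struct Currents {
  double i[NMECH];    // per-mechanism currents, mA/cm2, positive outward
  double total;
  double i_ca_total;  // Ca2+-carried portion fed to the shell system
  double g_sk, sk_o, sk_m;
};

static inline double interp1(const std::vector<double>& x,
                             const std::vector<double>& y, double q) {
  int n = (int)x.size();
  if (n == 1 || q <= x[0]) return y[0];
  if (q >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= q) lo = mid; else hi = mid;
  }
  double f = (q - x[lo]) / (x[lo + 1] - x[lo]);
  return y[lo] + f * (y[lo + 1] - y[lo]);
}

static inline double ghk(double p, double gate, double v, double ci,
                         double co, const Params& P) {
  double u = 2.0 * v / P.rtf_mV;  // z = 2 (Ca2+)
  double scale = p * gate * 2.0 * FARADAY * 1e-3;
  if (std::fabs(u) < 1e-4) {
    return scale * (1.0 + u / 2.0 + u * u / 12.0) * (ci - co * std::exp(-u));
  }
  return scale * u * (ci - co * std::exp(-u)) / (1.0 - std::exp(-u));
}

static inline double beta_ratio(double kb, double btot, double ca) {
  double d = kb + ca;
  return kb * btot / (d * d);
}

// Evaluate all membrane currents at potential v with the given gates and
// near-membrane concentrations. j_ip3r_outer couples the CaCC to ER release;
// i_pmca is the pump current derived from the current pump state.
static void currents(const Params& P, double v, const double* g, double ca0,
                     double caer0, double j_ip3r_outer, double i_pmca,
                     Currents& out) {
  const double ek = P.e_k, ena = P.e_na;
  out.i[M_PAS] = P.g_pas * (v - P.e_pas);
  double m = g[G_TTXS_M];
  out.i[M_TTXS] = P.g_ttxs * m * m * m * g[G_TTXS_H] * (v - ena);
  m = g[G_NAV18_M];
  out.i[M_NAV18] = P.g_nav18 * m * m * m * g[G_NAV18_H] * (v - ena);
  out.i[M_NAV19] = P.g_nav19 * g[G_NAV19_M] * g[G_NAV19_H] * (v - ena);
  out.i[M_KA] = P.g_ka * g[G_KA_N] *
      (0.3 * g[G_KA_HF] + 0.7 * g[G_KA_HS]) * (v - ek);
  double n = g[G_KDR_N];
  out.i[M_KDR] = P.g_kdr * n * n * n * n * (v - ek);
  out.i[M_KCNQ] = P.g_kcnq * g[G_KCNQ_N] * (v - ek);
  double wna = 1.0 / (1.0 + std::pow(P.kna_ec50 / P.na_i, P.kna_hill));
  out.i[M_KNA] = P.g_kna * wna * (v - ek);
  out.i[M_BK] = P.g_bk * g[G_BK_N] * (v - ek);
  double op = std::pow(ca0, P.sk_hill);
  double sk_o = op / (op + std::pow(P.sk_ec50, P.sk_hill));
  double v12 = interp1(P.sk_ca, P.sk_v12, ca0);
  double sf = interp1(P.sk_ca, P.sk_sf, ca0);
  double sk_m = 1.0 / (1.0 + std::exp((v - (ek + v12)) / sf));
  double gsk = P.sk_rectify ? P.g_sk * sk_o * sk_m : P.g_sk * sk_o;
  out.g_sk = gsk; out.sk_o = sk_o; out.sk_m = sk_m;
  out.i[M_SK] = gsk * (v - ek);
  double hca = 1.0 / (1.0 + std::pow(ca0 / P.cdi_k, P.cdi_n));
  out.i[M_CAL] = ghk(P.p_cal, g[G_CAL_M] * g[G_CAL_H] * hca, v, ca0, P.ca_o, P);
  out.i[M_CAN] = ghk(P.p_can,
      g[G_CAN_M] * (P.can_a * g[G_CAN_H] + (1.0 - P.can_a)) * hca,
      v, ca0, P.ca_o, P);
  out.i[M_CAPQ] = ghk(P.p_capq, g[G_CAPQ_M], v, ca0, P.ca_o, P);
  out.i[M_CAR] = ghk(P.p_car, g[G_CAR_M] * g[G_CAR_H], v, ca0, P.ca_o, P);
  out.i[M_CAT] = ghk(P.p_cat, g[G_CAT_M] * g[G_CAT_H], v, ca0, P.ca_o, P);
  double sg = 1.0 / (1.0 + std::pow(caer0 / P.socc_k, P.socc_hill));
  out.i[M_SOCC] = ghk(P.p_socc, sg, v, ca0, P.ca_o, P);
  double mtrp = 1.0 / (1.0 + std::exp((P.trpm8_vhalf - v) / P.trpm8_vslope));
  out.i[M_TRPM8] = P.g_trpm8 * mtrp * (v - P.e_trpm8);
  double ca_eff = ca0 + P.cacc_wip3 * j_ip3r_outer;
  double cc = std::pow(ca_eff, P.cacc_hill);
  double occ = cc / (cc + std::pow(P.cacc_ec50, P.cacc_hill));
  double ovv = 1.0 / (1.0 + std::exp((P.cacc_vhalf - v) / P.cacc_vslope));
  out.i[M_CACC] = P.g_cacc * occ * ovv * (v - P.e_cl);
  double fna = P.na_i / (P.na_i + P.nak_km_na);
  double fk = P.k_o / (P.k_o + P.nak_km_k);
  out.i[M_NAK] = P.i_nak * fna * fna * fna * fk * fk;
  double u = v / P.rtf_mV;
  double na_i3 = P.na_i * P.na_i * P.na_i;
  double na_o3 = P.na_o * P.na_o * P.na_o;
  double xf = na_i3 * P.ca_o * std::exp(P.ncx_eta * u);
  double xr = na_o3 * ca0 * std::exp((P.ncx_eta - 1.0) * u);
  double den = (P.ncx_kmna * P.ncx_kmna * P.ncx_kmna + na_o3) *
      (P.ncx_kmca + P.ca_o) *
      (1.0 + P.ncx_ksat * std::exp((P.ncx_eta - 1.0) * u));
  double incx = P.k_ncx * (xf - xr) / den;
  out.i[M_NCX] = incx;
  out.i[M_PMCA] = i_pmca;
  out.i[M_HCN] = P.g_hcn * g[G_HCN_M] * (v - P.e_hcn);
  out.i_ca_total = out.i[M_CAL] + out.i[M_CAN] + out.i[M_CAPQ] +
      out.i[M_CAR] + out.i[M_CAT] + out.i[M_SOCC] +
      P.trpm8_fca * out.i[M_TRPM8] - 2.0 * incx;
  out.total = 0.0;
  for (int k = 0; k < NMECH; ++k) out.total += out.i[k];
}

struct CaState {
  std::vector<double> ca, ca_er, ca_mt, ip3, h;
  double pump_free, pump_bound;
};

// One forward-Euler substep of the shell system; returns false if any
// concentration would go non-positive. j_ip3r_out receives the outermost
// IP3R flux (for the CaCC coupling).
static bool ca_substep(const Params& P, CaState& S, double i_ca_dens,
                       double dt, double* j_ip3r_out) {
  int ns = P.ns;
  std::vector<double> dca(ns), dcaer(ns), dcamt(ns);
  double jip3r0 = 0.0;
  for (int s = 0; s < ns; ++s) {
    double ca = S.ca[s], caer = S.ca_er[s], camt = S.ca_mt[s];
    double jserca = 0, jip3r = 0, jcicr = 0, jleak = 0;
    if (P.en_serca) {
      double cn = std::pow(ca, P.n_serca);
      jserca = P.v_serca * cn / (cn + std::pow(P.k_psr, P.n_serca));
    }
    if (P.en_ip3r) {
      double po = (S.ip3[s] / (S.ip3[s] + P.k_ip3)) *
          (ca / (ca + P.k_act_ip3)) * S.h[s];
      jip3r = P.j_ip3r_bar * po * po * po * (1.0 - ca / caer);
    }
    if (P.en_cicr && ca > P.k_t_cicr) {
      jcicr = P.v_cicr * ca / (ca + P.k_cicr) * (caer - ca);
    }
    if (P.en_leak) jleak = P.l_er * (1.0 - ca / caer);
    if (s == 0) jip3r0 = jip3r;
    double jmcu = 0, jmncx = 0;
    if (P.en_mcu) {
      double cn = std::pow(ca, P.n_mcu);
      jmcu = P.mcu_scale * P.v_mcu * cn / (cn + std::pow(P.k_mcu, P.n_mcu));
    }
    if (P.en_mncx) {
      double na3 = P.na_i * P.na_i * P.na_i;
      jmncx = P.v_mncx * na3 /
          (na3 + P.k_na_mncx * P.k_na_mncx * P.k_na_mncx) *
          camt / (camt + P.k_ca_mncx);
    }
    double jmem = 0, jpmca = 0;
    if (s == 0) {
      if (P.en_mem) {
        // mA/cm2 * cm2 -> mA; 1e-3 -> A; / (zF * L) -> M/s == mM/ms
        double i_amp = i_ca_dens * P.area_cm2 * 1e-3;
        jmem = -i_amp / (2.0 * FARADAY * (P.v_cyt[0] * 1e-15));
      }
      if (P.en_pmca) {
        // cytosol-facing net flux of the binding reaction (mol/cm2/ms)
        double r1 = P.pk1 * ca * S.pump_free - P.pk2 * S.pump_bound;
        jpmca = r1 * P.area_cm2 / (P.v_cyt[0] * 1e-15) * 1e3;  // mM/ms
      }
    }
    double beta_dye = 0.0;
    if (P.dye_on && P.dye_cyt) beta_dye = beta_ratio(P.dye_kb, P.dye_btot, ca);
    double divisor = 1.0 + P.beta_cyt + beta_dye;
    dca[s] = (jmem - jpmca + (jip3r + jcicr + jleak - jserca) +
              (jmncx - jmcu)) / divisor;
    double ber = beta_ratio(P.kb_er, P.btot_er, caer);
    dcaer[s] = (jserca - jip3r - jcicr - jleak) / (1.0 + ber);
    double bmt = beta_ratio(P.kb_mt, P.btot_mt, camt);
    if (P.dye_on && !P.dye_cyt) bmt += beta_ratio(P.dye_kb, P.dye_btot, camt);
    dcamt[s] = (jmcu - jmncx) / (1.0 + bmt);
  }
  if (P.en_diff && ns > 1) {
    for (int s = 0; s < ns - 1; ++s) {
      double dfac;
      if (P.dye_on && P.dye_cyt) {
        double bd = beta_ratio(P.dye_kb, P.dye_btot, S.ca[s]);
        dfac = (P.d_ca + bd * P.dye_d) / (1.0 + P.beta_cyt + bd);
      } else {
        dfac = P.d_ca / (1.0 + P.beta_cyt);
      }
      double amt = dfac * P.cs_area[s] * (S.ca[s + 1] - S.ca[s]) / P.cs_dr[s];
      dca[s] += amt / P.v_cyt[s];
      dca[s + 1] -= amt / P.v_cyt[s + 1];
    }
  }
  // trial update of concentrations
  for (int s = 0; s < ns; ++s) {
    if (S.ca[s] + dt * dca[s] <= 0.0) return false;
    if (S.ca_er[s] + dt * dcaer[s] <= 0.0) return false;
    if (S.ca_mt[s] + dt * dcamt[s] <= 0.0) return false;
  }
  // IP3: diffusion + degradation (explicit; rates are slow)
  std::vector<double> dip3(ns, 0.0);
  for (int s = 0; s < ns - 1; ++s) {
    double amt = P.d_ip3 * P.cs_area[s] * (S.ip3[s + 1] - S.ip3[s]) / P.cs_dr[s];
    dip3[s] += amt / P.v_cyt[s];
    dip3[s + 1] -= amt / P.v_cyt[s + 1];
  }
  for (int s = 0; s < ns; ++s) {
    dip3[s] -= P.k_degr_ip3 * (S.ip3[s] - P.ip3_rest);
  }
  // commit
  for (int s = 0; s < ns; ++s) {
    double ca_old = S.ca[s];
    S.ca[s] += dt * dca[s];
    S.ca_er[s] += dt * dcaer[s];
    S.ca_mt[s] += dt * dcamt[s];
    S.ip3[s] += dt * dip3[s];
    // IP3R inhibition gate: exact exponential update at the old [Ca]
    double hinf = P.k_inh_ip3 / (ca_old + P.k_inh_ip3);
    double tau = 1.0 / (P.k_on_ip3 * (ca_old + P.k_inh_ip3));
    S.h[s] = hinf + (S.h[s] - hinf) * std::exp(-dt / tau);
  }
  if (P.en_pmca) {
    // backward Euler on the linear 2x2 (free, bound) system
    double a = P.pk1 * S.ca[0] + P.pk4 * P.ca_o;
    double b = P.pk2 + P.pk3;
    double tot = S.pump_free + S.pump_bound;
    double den = 1.0 + dt * (a + b);
    double fnew = (S.pump_free * (1.0 + dt * b) + dt * b * S.pump_bound) / den;
    S.pump_free = fnew;
    S.pump_bound = tot - fnew;
  }
  *j_ip3r_out = jip3r0;
  return true;
}

static Params unpack(List pk) {
  Params P;
  P.area_cm2 = as<double>(pk["area_cm2"]);
  P.cm_spec = as<double>(pk["cm_spec"]);
  P.rtf_mV = as<double>(pk["rtf_mV"]);
  P.e_na = as<double>(pk["e_na"]); P.e_k = as<double>(pk["e_k"]);
  P.e_cl = as<double>(pk["e_cl"]); P.e_pas = as<double>(pk["e_pas"]);
  P.e_hcn = as<double>(pk["e_hcn"]); P.e_trpm8 = as<double>(pk["e_trpm8"]);
  P.g_pas = as<double>(pk["g_pas"]); P.g_ttxs = as<double>(pk["g_ttxs"]);
  P.g_nav18 = as<double>(pk["g_nav18"]); P.g_nav19 = as<double>(pk["g_nav19"]);
  P.g_ka = as<double>(pk["g_ka"]); P.g_kdr = as<double>(pk["g_kdr"]);
  P.g_kcnq = as<double>(pk["g_kcnq"]); P.g_kna = as<double>(pk["g_kna"]);
  P.g_bk = as<double>(pk["g_bk"]); P.g_sk = as<double>(pk["g_sk"]);
  P.g_hcn = as<double>(pk["g_hcn"]);
  P.p_cal = as<double>(pk["p_cal"]); P.p_can = as<double>(pk["p_can"]);
  P.p_capq = as<double>(pk["p_capq"]); P.p_car = as<double>(pk["p_car"]);
  P.p_cat = as<double>(pk["p_cat"]); P.p_socc = as<double>(pk["p_socc"]);
  P.g_trpm8 = as<double>(pk["g_trpm8"]); P.g_cacc = as<double>(pk["g_cacc"]);
  P.i_nak = as<double>(pk["i_nak"]); P.k_ncx = as<double>(pk["k_ncx"]);
  P.na_i = as<double>(pk["na_i"]); P.na_o = as<double>(pk["na_o"]);
  P.ca_o = as<double>(pk["ca_o"]); P.k_o = as<double>(pk["k_o"]);
  P.kna_ec50 = as<double>(pk["kna_ec50"]); P.kna_hill = as<double>(pk["kna_hill"]);
  P.nak_km_na = as<double>(pk["nak_km_na"]); P.nak_km_k = as<double>(pk["nak_km_k"]);
  P.ncx_eta = as<double>(pk["ncx_eta"]); P.ncx_ksat = as<double>(pk["ncx_ksat"]);
  P.ncx_kmna = as<double>(pk["ncx_kmna"]); P.ncx_kmca = as<double>(pk["ncx_kmca"]);
  P.trpm8_vhalf = as<double>(pk["trpm8_vhalf"]);
  P.trpm8_vslope = as<double>(pk["trpm8_vslope"]);
  P.trpm8_fca = as<double>(pk["trpm8_fca"]);
  P.cacc_ec50 = as<double>(pk["cacc_ec50"]); P.cacc_hill = as<double>(pk["cacc_hill"]);
  P.cacc_vhalf = as<double>(pk["cacc_vhalf"]);
  P.cacc_vslope = as<double>(pk["cacc_vslope"]);
  P.cacc_wip3 = as<double>(pk["cacc_wip3"]);
  P.socc_k = as<double>(pk["socc_k"]); P.socc_hill = as<double>(pk["socc_hill"]);
  P.can_a = as<double>(pk["can_a"]);
  P.cdi_k = as<double>(pk["cdi_k"]); P.cdi_n = as<double>(pk["cdi_n"]);
  P.sk_ec50 = as<double>(pk["sk_ec50"]); P.sk_hill = as<double>(pk["sk_hill"]);
  P.sk_rectify = as<int>(pk["sk_rectify"]);
  P.sk_ca = as<std::vector<double> >(pk["sk_ca"]);
  P.sk_v12 = as<std::vector<double> >(pk["sk_v12"]);
  P.sk_sf = as<std::vector<double> >(pk["sk_sf"]);
  P.v_min = as<double>(pk["v_min"]); P.v_step = as<double>(pk["v_step"]);
  NumericMatrix ti = pk["tab_inf"], tt = pk["tab_tau"];
  P.nv = ti.nrow();
  P.tab_inf.assign(ti.begin(), ti.end());
  P.tab_tau.assign(tt.begin(), tt.end());
  P.ca_on = as<int>(pk["ca_on"]);
  P.ns = as<int>(pk["ns"]);
  P.v_cyt = as<std::vector<double> >(pk["v_cyt"]);
  P.v_er = as<std::vector<double> >(pk["v_er"]);
  P.cs_area = as<std::vector<double> >(pk["cs_area"]);
  P.cs_dr = as<std::vector<double> >(pk["cs_dr"]);
  P.d_ca = as<double>(pk["d_ca"]); P.beta_cyt = as<double>(pk["beta_cyt"]);
  P.d_ip3 = as<double>(pk["d_ip3"]); P.k_degr_ip3 = as<double>(pk["k_degr_ip3"]);
  P.ip3_rest = as<double>(pk["ip3_rest"]);
  P.k_ip3 = as<double>(pk["k_ip3"]); P.k_act_ip3 = as<double>(pk["k_act_ip3"]);
  P.k_on_ip3 = as<double>(pk["k_on_ip3"]); P.k_inh_ip3 = as<double>(pk["k_inh_ip3"]);
  P.j_ip3r_bar = as<double>(pk["j_ip3r_bar"]);
  P.v_serca = as<double>(pk["v_serca"]); P.k_psr = as<double>(pk["k_psr"]);
  P.n_serca = as<double>(pk["n_serca"]);
  P.v_cicr = as<double>(pk["v_cicr"]); P.k_cicr = as<double>(pk["k_cicr"]);
  P.k_t_cicr = as<double>(pk["k_t_cicr"]);
  P.kb_er = as<double>(pk["kb_er"]); P.btot_er = as<double>(pk["btot_er"]);
  P.kb_mt = as<double>(pk["kb_mt"]); P.btot_mt = as<double>(pk["btot_mt"]);
  P.v_mcu = as<double>(pk["v_mcu"]); P.k_mcu = as<double>(pk["k_mcu"]);
  P.n_mcu = as<double>(pk["n_mcu"]);
  P.v_mncx = as<double>(pk["v_mncx"]); P.k_na_mncx = as<double>(pk["k_na_mncx"]);
  P.k_ca_mncx = as<double>(pk["k_ca_mncx"]);
  P.mcu_scale = as<double>(pk["mcu_scale"]);
  P.l_er = as<double>(pk["l_er"]);
  P.pk1 = as<double>(pk["pk1"]); P.pk2 = as<double>(pk["pk2"]);
  P.pk3 = as<double>(pk["pk3"]); P.pk4 = as<double>(pk["pk4"]);
  P.dye_on = as<int>(pk["dye_on"]); P.dye_cyt = as<int>(pk["dye_cyt"]);
  P.dye_kb = as<double>(pk["dye_kb"]); P.dye_btot = as<double>(pk["dye_btot"]);
  P.dye_d = as<double>(pk["dye_d"]);
  P.en_pmca = as<int>(pk["en_pmca"]); P.en_serca = as<int>(pk["en_serca"]);
  P.en_ip3r = as<int>(pk["en_ip3r"]); P.en_cicr = as<int>(pk["en_cicr"]);
  P.en_leak = as<int>(pk["en_leak"]); P.en_mcu = as<int>(pk["en_mcu"]);
  P.en_mncx = as<int>(pk["en_mncx"]); P.en_diff = as<int>(pk["en_diff"]);
  P.en_mem = as<int>(pk["en_mem"]);
  P.ca_fixed = as<double>(pk["ca_fixed"]);
  P.caer_fixed = as<double>(pk["caer_fixed"]);
  return P;
}

// state vector layout: vm, gates[NGATE], then (if ca_on)
// ca[ns], ca_er[ns], ca_mt[ns], ip3[ns], h[ns], pump_free, pump_bound
// [[Rcpp::export]]
List soma_run_cpp(List pack, NumericMatrix segments, double dt,
                  int record_every, NumericVector init_state) {
  Params P = unpack(pack);
  int ns = P.ns;
  int idx = 0;
  double vm = init_state[idx++];
  double gates[NGATE];
  for (int k = 0; k < NGATE; ++k) gates[k] = init_state[idx++];
  CaState S;
  if (P.ca_on) {
    S.ca.assign(init_state.begin() + idx, init_state.begin() + idx + ns); idx += ns;
    S.ca_er.assign(init_state.begin() + idx, init_state.begin() + idx + ns); idx += ns;
    S.ca_mt.assign(init_state.begin() + idx, init_state.begin() + idx + ns); idx += ns;
    S.ip3.assign(init_state.begin() + idx, init_state.begin() + idx + ns); idx += ns;
    S.h.assign(init_state.begin() + idx, init_state.begin() + idx + ns); idx += ns;
    S.pump_free = init_state[idx++];
    S.pump_bound = init_state[idx++];
  }

  // total steps across segments
  long nstep_total = 0;
  int nseg = segments.nrow();
  std::vector<long> seg_steps(nseg);
  for (int s = 0; s < nseg; ++s) {
    seg_steps[s] = (long)std::floor(segments(s, 1) / dt + 0.5);
    nstep_total += seg_steps[s];
  }
  long nrec = nstep_total / record_every + 1;
  const int NCOL = 2 + NMECH + 8;
  NumericMatrix rec(nrec, NCOL);
  long irec = 0;

  Currents C, C2;
  double j_ip3r_outer = 0.0;
  double t = 0.0;
  long step_count = 0;

  // record initial sample after computing currents at the initial state
  {
    double ca0 = P.ca_on ? S.ca[0] : P.ca_fixed;
    double caer0 = P.ca_on ? S.ca_er[0] : P.caer_fixed;
    double ipm = 0.0;
    if (P.ca_on && P.en_pmca) {
      double r2 = P.pk3 * S.pump_bound - P.pk4 * P.ca_o * S.pump_free;
      ipm = r2 * 2.0 * FARADAY * 1e6;
    }
    currents(P, vm, gates, ca0, caer0, j_ip3r_outer, ipm, C);
    rec(0, 0) = 0.0; rec(0, 1) = vm;
    for (int k = 0; k < NMECH; ++k) rec(0, 2 + k) = C.i[k];
    rec(0, 2 + NMECH + 0) = ca0;
    rec(0, 2 + NMECH + 1) = caer0;
    rec(0, 2 + NMECH + 2) = P.ca_on ? S.ca_mt[0] : 0.0;
    rec(0, 2 + NMECH + 3) = P.ca_on ? S.ip3[0] : 0.0;
    rec(0, 2 + NMECH + 4) = C.g_sk;
    rec(0, 2 + NMECH + 5) = C.sk_o;
    rec(0, 2 + NMECH + 6) = C.sk_m;
    rec(0, 2 + NMECH + 7) = 0.0;
    irec = 1;
  }

  for (int s = 0; s < nseg; ++s) {
    int mode = (int)segments(s, 0);  // 0 = current clamp, 1 = voltage clamp
    double a0 = segments(s, 2), a1 = segments(s, 3);
    long nst = seg_steps[s];
    for (long k = 0; k < nst; ++k) {
      double frac = (nst > 1) ? ((double)k / (double)(nst - 1)) : 0.0;
      double level = a0 + (a1 - a0) * frac;
      double istim_nA = (mode == 0) ? level : 0.0;
      double ca0 = P.ca_on ? S.ca[0] : P.ca_fixed;
      double caer0 = P.ca_on ? S.ca_er[0] : P.caer_fixed;
      double ipm = 0.0;
      if (P.ca_on && P.en_pmca) {
        double r2 = P.pk3 * S.pump_bound - P.pk4 * P.ca_o * S.pump_free;
        ipm = r2 * 2.0 * FARADAY * 1e6;  // mol/cm2/ms -> mA/cm2
      }

      // --- gate update (exact exponential, tables at current vm) ---
      double q = (vm - P.v_min) / P.v_step;
      if (q < 0) q = 0;
      if (q > P.nv - 1.000001) q = P.nv - 1.000001;
      int i0 = (int)q;
      double f = q - i0;
      for (int gidx = 0; gidx < NGATE; ++gidx) {
        const double* colI = &P.tab_inf[(size_t)gidx * P.nv];
        const double* colT = &P.tab_tau[(size_t)gidx * P.nv];
        double inf = colI[i0] + f * (colI[i0 + 1] - colI[i0]);
        double tau = colT[i0] + f * (colT[i0 + 1] - colT[i0]);
        if (gidx == G_BK_N) {
          double pca = std::log10(ca0 * 1e-3);
          double v12 = -43.4 * pca - 203.0;
          double sf = 33.88 * std::exp(-std::pow((pca + 5.42) / 1.85, 2.0));
          inf = 1.0 / (1.0 + std::exp((v12 - vm) / sf));
        }
        gates[gidx] = inf + (gates[gidx] - inf) * std::exp(-dt / tau);
      }

      // --- voltage update ---
      if (mode == 1) {
        vm = level;  // ideal clamp
        currents(P, vm, gates, ca0, caer0, j_ip3r_outer, ipm, C);
      } else {
        currents(P, vm, gates, ca0, caer0, j_ip3r_outer, ipm, C);
        const double dv = 0.001;
        currents(P, vm + dv, gates, ca0, caer0, j_ip3r_outer, ipm, C2);
        double G = (C2.total - C.total) / dv;  // S/cm2 (chord slope)
        if (G < 0) G = 0;
        double istim_dens = istim_nA * 1e-6 / P.area_cm2;  // mA/cm2
        // (mA/cm2) / (uF/cm2) = 1e3 mV/ms
        double dvm = dt * 1e3 * (istim_dens - C.total) / P.cm_spec;
        vm = vm + dvm / (1.0 + dt * 1e3 * G / P.cm_spec);
      }

      // --- calcium system ---
      if (P.ca_on) {
        int nsub = 1;
        for (;;) {
          CaState trial = S;
          bool ok = true;
          double jout = j_ip3r_outer;
          double h = dt / nsub;
          for (int ss = 0; ss < nsub; ++ss) {
            if (!ca_substep(P, trial, C.i_ca_total, h, &jout)) { ok = false; break; }
          }
          if (ok) { S = trial; j_ip3r_outer = jout; break; }
          nsub *= 2;
          if (nsub > 4096) stop("calcium step failed to stay positive");
        }
      }

      t += dt;
      ++step_count;
      if (step_count % record_every == 0 && irec < nrec) {
        double rca0 = P.ca_on ? S.ca[0] : P.ca_fixed;
        rec(irec, 0) = t; rec(irec, 1) = vm;
        for (int kk = 0; kk < NMECH; ++kk) rec(irec, 2 + kk) = C.i[kk];
        rec(irec, 2 + NMECH + 0) = rca0;
        rec(irec, 2 + NMECH + 1) = P.ca_on ? S.ca_er[0] : P.caer_fixed;
        rec(irec, 2 + NMECH + 2) = P.ca_on ? S.ca_mt[0] : 0.0;
        rec(irec, 2 + NMECH + 3) = P.ca_on ? S.ip3[0] : 0.0;
        rec(irec, 2 + NMECH + 4) = C.g_sk;
        rec(irec, 2 + NMECH + 5) = C.sk_o;
        rec(irec, 2 + NMECH + 6) = C.sk_m;
        rec(irec, 2 + NMECH + 7) = istim_nA;
        ++irec;
      }
      if (!std::isfinite(vm)) stop("membrane potential became non-finite");
    }
  }

  // final state
  int state_len = 1 + NGATE + (P.ca_on ? (5 * ns + 2) : 0);
  NumericVector fin(state_len);
  idx = 0;
  fin[idx++] = vm;
  for (int k = 0; k < NGATE; ++k) fin[idx++] = gates[k];
  if (P.ca_on) {
    for (int s2 = 0; s2 < ns; ++s2) fin[idx++] = S.ca[s2];
    for (int s2 = 0; s2 < ns; ++s2) fin[idx++] = S.ca_er[s2];
    for (int s2 = 0; s2 < ns; ++s2) fin[idx++] = S.ca_mt[s2];
    for (int s2 = 0; s2 < ns; ++s2) fin[idx++] = S.ip3[s2];
    for (int s2 = 0; s2 < ns; ++s2) fin[idx++] = S.h[s2];
    fin[idx++] = S.pump_free;
    fin[idx++] = S.pump_bound;
  }
  return List::create(_["trace"] = rec(Range(0, irec - 1), _),
                      _["state"] = fin);
}
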