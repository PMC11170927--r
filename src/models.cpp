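#include <Rcpp.h>
using namespace Rcpp;

// Pool order used throughout the MEND-type model:
// 0 P_O  particulate organic C, oxidatively decomposed
// 1 P_H  particulate organic C, hydrolytically decomposed
// 2 M    mineral-associated organic C
// 3 Q    adsorbed (protected) dissolved organic C
// 4 D    dissolved organic C
// 5 B_A  active microbial biomass
// 6 B_D  dormant microbial biomass
// 7 EP_O oxidative exo-enzymes (EnzCo)
// 8 EP_H hydrolytic exo-enzymes (EnzCh)
// 9 EM   mineral-associated-pool enzymes
//
// Calibrated parameter vector order (matches R mend_params()):
// 0 f_INP, 1 r_E, 2 p_EP, 3 fp_EM, 4 f_D, 5 g_D, 6 V_g, 7 alpha,
// 8 K_D, 9 beta, 10 psi_A2D, 11 Yg_ref, 12 k_Yg, 13 T_ref
//
// Frozen kinetic constants vector order (matches R mend_constants()):
// 0 V_P, 1 V_M, 2 K_P, 3 K_M, 4 k_ads, 5 k_des, 6 Q_max, 7 Ea_dec,
// 8 Ea_up, 9 Ea_m, 10 k_mortA, 11 k_mortD, 12 dorm_maint_frac,
// 13 W_ref, 14 w_exp, 15 c_gpp

static const double RGAS = 8.314;

static inline double arrh(double Ea, double T, double Tref) {
  return std::exp((Ea / RGAS) * (1.0 / (Tref + 273.15) - 1.0 / (T + 273.15)));
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Derivatives and the respiration/input rates at a given state.
// dx, out must have length 10 and 2 (rh, input) respectively.
static void mend_deriv(const double* x, double T, double W, double gpp,
                       const double* p, const double* cs,
                       double* dx, double* rates) {
  const double fT_dec = arrh(cs[7], T, p[13]);
  const double fT_up  = arrh(cs[8], T, p[13]);
  const double fT_m   = arrh(cs[9], T, p[13]);
  double fW = W <= 0.0 ? 0.0 : std::pow(std::min(1.0, W / cs[13]), cs[14]);

  const double Yg = clampd(p[11] + p[12] * (T - p[13]), 0.01, 0.99);

  // enzyme-mediated decomposition (Michaelis-Menten in substrate)
  const double decPO = cs[0] * fT_dec * fW * x[7] * x[0] / (cs[2] + x[0]);
  const double decPH = cs[0] * fT_dec * fW * x[8] * x[1] / (cs[2] + x[1]);
  const double decM  = cs[1] * fT_dec * fW * x[9] * x[2] / (cs[3] + x[2]);

  // sorption exchange between D and Q
  const double ads = cs[4] * x[4] * (1.0 - x[3] / cs[6]);
  const double des = cs[5] * x[3];

  // uptake of D by active biomass, split growth vs growth respiration
  const double U  = p[6] * fT_up * fW * x[5] * x[4] / (p[8] + x[4]);
  const double growth = Yg * U;
  const double rg     = (1.0 - Yg) * U;

  const double maintA = p[7] * fT_m * x[5];
  const double maintD = cs[12] * p[7] * fT_m * x[6];

  // enzyme production (from active biomass) and turnover
  const double prodEPO = 0.5 * p[2] * x[5];
  const double prodEPH = 0.5 * p[2] * x[5];
  const double prodEM  = p[3] * p[2] * x[5];
  const double tEPO = p[1] * x[7];
  const double tEPH = p[1] * x[8];
  const double tEM  = p[1] * x[9];
  const double enzTurn = tEPO + tEPH + tEM;

  // mortality
  const double mortA = cs[10] * x[5];
  const double mortD = cs[11] * x[6];
  const double mort  = mortA + mortD;

  // dormancy switching on the moisture scalar
  double a2d = 0.0, d2a = 0.0;
  if (fW < p[10]) a2d = p[9] * (p[10] - fW) * x[5];
  else            d2a = p[9] * (fW - p[10]) * x[6];

  // external C input from GPP
  const double I = cs[15] * (gpp > 0.0 ? gpp : 0.0);

  dx[0] = 0.5 * p[0] * I - decPO;
  dx[1] = 0.5 * p[0] * I - decPH + (1.0 - p[5]) * mort;
  dx[2] = (1.0 - p[4]) * (decPO + decPH) - decM + (1.0 - p[5]) * enzTurn;
  dx[3] = ads - des;
  dx[4] = (1.0 - p[0]) * I + p[4] * (decPO + decPH) + decM
          + p[5] * (mort + enzTurn) - ads + des - U;
  dx[5] = growth - maintA - (prodEPO + prodEPH + prodEM) - mortA - a2d + d2a;
  dx[6] = a2d - d2a - maintD - mortD;
  dx[7] = prodEPO - tEPO;
  dx[8] = prodEPH - tEPH;
  dx[9] = prodEM - tEM;

  rates[0] = rg + maintA + maintD; // heterotrophic respiration
  rates[1] = I;                    // external input
}

// [[Rcpp::export]]
List mend_simulate_cpp(NumericVector par, NumericVector consts,
                       NumericVector init,
                       NumericVector temperature, NumericVector moisture,
                       NumericVector gpp, int substeps) {
  const int n = temperature.size();
  if (moisture.size() != n || gpp.size() != n)
    stop("forcing series lengths differ");
  if (init.size() != 10) stop("initial state must have 10 pools");

  NumericMatrix pools(n, 10);
  NumericVector rh(n), cue(n), input(n);
  double x[10], dx[10], rates[2];
  for (int j = 0; j < 10; ++j) x[j] = init[j];
  const double* p = REAL(par);
  const double* cs = REAL(consts);

  for (int t = 0; t < n; ++t) {
    const double T = temperature[t], W = moisture[t], G = gpp[t];
    double remaining = 1.0;
    const double h0 = 1.0 / substeps;
    double rh_day = 0.0, in_day = 0.0;
    int guard = 0;
    while (remaining > 1e-12) {
      if (++guard > 1000000) stop("integration failed to advance (day %d)", t + 1);
      mend_deriv(x, T, W, G, p, cs, dx, rates);
      double hh = std::min(h0, remaining);
      // shrink the step until no pool is driven negative
      int k = 0;
      bool ok = false;
      while (k < 40) {
        ok = true;
        for (int j = 0; j < 10; ++j)
          if (x[j] + hh * dx[j] < 0.0) { ok = false; break; }
        if (ok) break;
        hh *= 0.5;
        ++k;
      }
      if (!ok) stop("unstable configuration: pool driven negative at maximum refinement (day %d)", t + 1);
      for (int j = 0; j < 10; ++j) x[j] += hh * dx[j];
      rh_day += hh * rates[0];
      in_day += hh * rates[1];
      remaining -= hh;
    }
    for (int j = 0; j < 10; ++j) pools(t, j) = x[j];
    rh[t] = rh_day;
    input[t] = in_day;
    cue[t] = clampd(p[11] + p[12] * (T - p[13]), 0.01, 0.99);
  }

  return List::create(_["pools"] = pools, _["rh"] = rh,
                      _["input"] = input, _["cue"] = cue);
}

// First-order (CENTURY/TECO-type) model:
// dX = b*u(t) + xi(T,W) * (A - I) diag(k) X, respired fraction per pool
// r_j = 1 - colsum(A)_j; Rh = xi * sum_j r_j k_j X_j.
// [[Rcpp::export]]
List teco_simulate_cpp(NumericVector k, NumericMatrix A, NumericVector b,
                       NumericVector init, double q10, double tref,
                       double wref, double cgpp,
                       NumericVector temperature, NumericVector moisture,
                       NumericVector gpp, int substeps) {
  const int np = k.size();
  const int n = temperature.size();
  if (A.nrow() != np || A.ncol() != np) stop("transfer matrix dimension mismatch");
  if (b.size() != np || init.size() != np) stop("parameter length mismatch");

  std::vector<double> r(np);
  for (int j = 0; j < np; ++j) {
    double cj = 0.0;
    for (int i = 0; i < np; ++i) cj += A(i, j);
    if (cj > 1.0 + 1e-12) stop("transfer fractions out of pool %d exceed 1", j + 1);
    r[j] = 1.0 - cj;
  }

  NumericMatrix pools(n, np);
  NumericVector rh(n);
  std::vector<double> x(init.begin(), init.end());
  const double h = 1.0 / substeps;

  for (int t = 0; t < n; ++t) {
    const double xi_T = std::pow(q10, (temperature[t] - tref) / 10.0);
    const double W = moisture[t];
    const double xi_W = W <= 0.0 ? 0.0 : std::min(1.0, W / wref);
    const double xi = xi_T * xi_W;
    const double u = cgpp * (gpp[t] > 0.0 ? gpp[t] : 0.0);
    double rh_day = 0.0;
    for (int s = 0; s < substeps; ++s) {
      double rh_inst = 0.0;
      std::vector<double> dx(np, 0.0);
      for (int j = 0; j < np; ++j) {
        const double out = xi * k[j] * x[j];
        dx[j] -= out;
        rh_inst += r[j] * out;
        for (int i = 0; i < np; ++i) dx[i] += A(i, j) * out;
      }
      for (int i = 0; i < np; ++i) {
        dx[i] += b[i] * u;
        x[i] += h * dx[i];
        if (x[i] < 0.0) x[i] = 0.0;
      }
      rh_day += h * rh_inst;
    }
    for (int j = 0; j < np; ++j) pools(t, j) = x[j];
    rh[t] = rh_day;
  }
  return List::create(_["pools"] = pools, _["rh"] = rh);
}
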