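/* Compiled copy of the reduced tumor-immune ODE right-hand side.
 *
 * Mirrors R/rhs.R::assemble_rhs exactly; parameter and state orderings are
 * those of R/parameters.R (.qsp_par_table) and R/state.R (.qsp_state_names).
 * The test suite asserts elementwise agreement of the two implementations.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 100
#define NSTATE 34

static double p[NPAR];

/* parameter indices: table order of R/parameters.R */
enum {
  iV_C, iV_P, iV_LN, irho_cell, if_int, iC_seed, id_0, iC_max,
  ik_growth, ik_apop, ik_kill, iK_ratio, in_ratio,
  ia_neo, ia_self, ik_P_deg, ik_up,
  iAPC_base, ik_APC0, ik_mat, iK_P, ik_mAPC_mig, ik_APC_death,
  ik_nT_source, ik_nT_death, ik_CP, ik_PC, ik_CLN, ik_LNC,
  ik_act, iK_act, in_act, iTCC, iTCC_ref, ik_aT_prolif, iaT_max,
  ik_aT_exit, if_Treg,
  ik_Teff_death_C, ik_Teff_death_T, ik_infil, iK_C_inf, ik_exh_PD1,
  ik_exh_Treg, iK_Treg_exh, ik_Texh_death, ik_ThTreg, iK_TGFb, iK_ArgI_td,
  iK_ArgI, iK_NO, iK_Treg_supp, iK_PD1, in_PD1,
  ik_MDSC_rec, iK_CCL2, iMDSC_max, ik_MDSC_death, ik_CCL2_sec, ik_CCL2_deg,
  ik_ArgI_sec, ik_ArgI_deg, ik_NO_sec, ik_NO_deg, ik_TGFb_sec, ik_TGFb_deg,
  iCL_A, ik_CP_A, ik_PC_A, ik_CT_A, ik_TC_A, ik_TLN_A, ik_LNC_A, iMW_A,
  iCL_E, ik_CP_E, ik_PC_E, ik_CT_E, ik_TC_E, ik_TLN_E, ik_LNC_E, iMW_E,
  iKd_CD3, iKd_CEA, ichi, iCD3_per_T, iCEA_per_C, iKd_PD1_PDL1, iKd_A_PDL1,
  iPD1_per_T, iPDL1_per_C, iPDL1_per_Treg, if_syn, iK_syn, in_syn,
  ibeta_max, ibeta_prolif, iuse_kill_boost, iuse_prolif_boost, idecoy
};

/* state indices */
enum {
  sC, sP_neo, sP_self, sAPC, smAPC, smAPC_LN,
  snCD8_C, snCD8_P, snCD8_LN, snCD4_C, snCD4_P, snCD4_LN,
  saCD8_LN, saCD4_LN, sTeff_C, sTeff_T, sTh_C, sTh_T, sTreg_C, sTreg_T,
  sTexh_T, sMDSC_T, sCCL2, sArgI, sNO, sTGFb,
  sA_C, sA_P, sA_T, sA_LN, sE_C, sE_P, sE_T, sE_LN
};

static const double N_AV = 6.02214076e23;

static double hillf(double x, double K, double n)
{
  double r;
  if (x <= 0.0) return 0.0;
  r = pow(x / K, n);
  if (!R_FINITE(r)) return 1.0;
  return r / (1.0 + r);
}

/* stable positive root of a*x^2 + b*x + c = 0 with a >= 0, c <= 0 */
static double pos_quad_root(double a, double b, double c)
{
  double disc, s;
  if (a == 0.0) return (b == 0.0) ? 0.0 : -c / b;
  disc = b * b - 4.0 * a * c;
  s = sqrt(disc > 0.0 ? disc : 0.0);
  return (b <= 0.0) ? (-b + s) / (2.0 * a) : -2.0 * c / (b + s);
}

/* ternary complex at fixed free engager e (see R/binding.R) */
static double tern_at_e(double e, double CD3t, double CEAt,
                        double K3, double KC, double chi,
                        double *c3o, double *ceao)
{
  double u = e / K3, v = e / KC, w = e * chi / (K3 * KC);
  double a = w * (1.0 + v);
  double b = (1.0 + v) * (1.0 + u) + w * (CD3t - CEAt);
  double c = -CEAt * (1.0 + u);
  double cea = pos_quad_root(a, b, c);
  double c3 = CD3t / (1.0 + u + w * cea);
  *c3o = c3; *ceao = cea;
  return w * c3 * cea;
}

/* quasi-steady-state ternary complex concentration; bisection on free e */
static double ternary_qss(double Etot, double CD3t, double CEAt,
                          double K3, double KC, double chi)
{
  double lo = 0.0, hi = Etot, e, c3, cea, tern = 0.0, g;
  int i;
  if (Etot <= 0.0 || (CD3t <= 0.0 && CEAt <= 0.0)) return 0.0;
  for (i = 0; i < 100; i++) {
    e = 0.5 * (lo + hi);
    tern = tern_at_e(e, CD3t, CEAt, K3, KC, chi, &c3, &cea);
    g = e * (1.0 + c3 / K3 + cea / KC) + tern - Etot;
    if (g > 0.0) hi = e; else lo = e;
  }
  e = 0.5 * (lo + hi);
  tern = tern_at_e(e, CD3t, CEAt, K3, KC, chi, &c3, &cea);
  return tern;
}

/* PD-1 occupancy under anti-PD-L1 competition; drug buffered at its free
 * concentration, receptors conserved (quadratic in free PD-L1) */
static double pd1_occ(double At, double PD1t, double PDL1t,
                      double Kd1, double KdA)
{
  double a, L;
  if (PDL1t <= 0.0 || PD1t <= 0.0) return 0.0;
  a = 1.0 + At / KdA;
  L = pos_quad_root(a, a * Kd1 + PD1t - PDL1t, -PDL1t * Kd1);
  return (L / Kd1) / (1.0 + L / Kd1);
}

void qsp_init(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

/* variant taking one extra trailing parameter: the cancer-cell count at
 * which the root function fires (used by grow_to_baseline) */
static double root_target = -1.0;

void qsp_init_root(void (*odeparms)(int *, double *))
{
  double tmp[NPAR + 1];
  int n = NPAR + 1, i;
  odeparms(&n, tmp);
  for (i = 0; i < NPAR; i++) p[i] = tmp[i];
  root_target = tmp[NPAR];
}

void qsp_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
  gout[0] = y[sC] - root_target;
}

void qsp_deriv(int *neq, double *t, double *yin, double *ydot,
               double *yout, int *ip)
{
  double y[NSTATE];
  int i;
  for (i = 0; i < NSTATE; i++) y[i] = yin[i] > 0.0 ? yin[i] : 0.0;

  double C = y[sC];
  double V_T = fmax(C / p[irho_cell], 1e-4) / 1000.0;  /* L */
  double V_int = V_T * p[if_int];
  double V_T_cm3 = V_T * 1000.0;

  /* pharmacodynamic signals */
  double molar = 1.0 / (N_AV * V_int);
  double E_Tc = y[sE_T] / V_int;
  double A_Tc = y[sA_T] / V_int;
  double CD3t = p[iCD3_per_T] * y[sTeff_T] * molar;
  double CEAt = p[iCEA_per_C] * C * molar;
  double PD1t = p[iPD1_per_T] * y[sTeff_T] * molar;
  double PDL1t = (p[iPDL1_per_C] * C + p[iPDL1_per_Treg] * y[sTreg_T]) * molar;

  double syn = 0.0;
  if (E_Tc > 0.0 && CD3t > 0.0 && CEAt > 0.0) {
    double tern = ternary_qss(E_Tc, CD3t, CEAt, p[iKd_CD3], p[iKd_CEA], p[ichi]);
    syn = p[if_syn] * p[iCD3_per_T] * tern / CD3t;
  }
  double act = hillf(syn, p[iK_syn], p[in_syn]);
  double kill_boost = p[iuse_kill_boost] * p[ibeta_max] * act;
  double prolif_boost = p[iuse_prolif_boost] * p[ibeta_prolif] * act;
  double H_PD1 = pd1_occ(A_Tc, PD1t, PDL1t, p[iKd_PD1_PDL1], p[iKd_A_PDL1]);
  double inh = hillf(H_PD1, p[iK_PD1], p[in_PD1]);

  double supp = 1.0 -
    (1.0 - hillf(y[sArgI], p[iK_ArgI], 1.0)) *
    (1.0 - hillf(y[sNO], p[iK_NO], 1.0)) *
    (1.0 - hillf(y[sTreg_T], p[iK_Treg_supp], 1.0));

  double R_kill = 0.0;
  if (C > 0.0 && y[sTeff_T] > 0.0) {
    R_kill = p[ik_kill] * C * hillf(y[sTeff_T] / C, p[iK_ratio], p[in_ratio]) *
      (1.0 + kill_boost) * (1.0 - inh) * (1.0 - supp);
  }

  /* tumor */
  ydot[sC] = p[ik_growth] * C * (1.0 - C / p[iC_max]) - p[ik_apop] * C - R_kill;

  /* antigen and APCs */
  double release = p[ik_apop] * C + R_kill;
  ydot[sP_neo] = p[ia_neo] * release - p[ik_P_deg] * y[sP_neo] -
    p[ik_up] * y[sAPC] * y[sP_neo];
  ydot[sP_self] = p[ia_self] * release - p[ik_P_deg] * y[sP_self] -
    p[ik_up] * y[sAPC] * y[sP_self];
  double mat = p[ik_mat] * y[sAPC] * hillf(y[sP_neo] + y[sP_self], p[iK_P], 1.0);
  ydot[sAPC] = p[ik_APC0] * (p[iAPC_base] - y[sAPC]) - mat;
  ydot[smAPC] = mat - (p[ik_mAPC_mig] + p[ik_APC_death]) * y[smAPC];
  ydot[smAPC_LN] = p[ik_mAPC_mig] * y[smAPC] - p[ik_APC_death] * y[smAPC_LN];

  /* naive T cells: trafficking + activation */
  double drive = hillf(y[smAPC_LN], p[iK_act], p[in_act]);
  double act8 = p[ik_act] * y[snCD8_LN] * drive * (p[iTCC] / p[iTCC_ref]);
  double act4 = p[ik_act] * y[snCD4_LN] * drive;
  ydot[snCD8_C] = p[ik_nT_source] - p[ik_nT_death] * y[snCD8_C] -
    p[ik_CP] * y[snCD8_C] + p[ik_PC] * y[snCD8_P] -
    p[ik_CLN] * y[snCD8_C] + p[ik_LNC] * y[snCD8_LN];
  ydot[snCD8_P] = p[ik_CP] * y[snCD8_C] - (p[ik_PC] + p[ik_nT_death]) * y[snCD8_P];
  ydot[snCD8_LN] = p[ik_CLN] * y[snCD8_C] -
    (p[ik_LNC] + p[ik_nT_death]) * y[snCD8_LN] - act8;
  ydot[snCD4_C] = p[ik_nT_source] - p[ik_nT_death] * y[snCD4_C] -
    p[ik_CP] * y[snCD4_C] + p[ik_PC] * y[snCD4_P] -
    p[ik_CLN] * y[snCD4_C] + p[ik_LNC] * y[snCD4_LN];
  ydot[snCD4_P] = p[ik_CP] * y[snCD4_C] - (p[ik_PC] + p[ik_nT_death]) * y[snCD4_P];
  ydot[snCD4_LN] = p[ik_CLN] * y[snCD4_C] -
    (p[ik_LNC] + p[ik_nT_death]) * y[snCD4_LN] - act4;

  /* activated T cells in LN */
  double a8 = y[saCD8_LN], a4 = y[saCD4_LN];
  double room = 1.0 - (a8 + a4) / p[iaT_max];
  if (room < 0.0) room = 0.0;
  double prolif = p[ik_aT_prolif] * (1.0 + prolif_boost) * room;
  ydot[saCD8_LN] = act8 + prolif * a8 - p[ik_aT_exit] * a8;
  ydot[saCD4_LN] = act4 + prolif * a4 - p[ik_aT_exit] * a4;

  /* central effectors and infiltration */
  double f_inf = hillf(C, p[iK_C_inf], 1.0);
  double in_Teff = p[ik_aT_exit] * a8;
  double in_Th = (1.0 - p[if_Treg]) * p[ik_aT_exit] * a4;
  double in_Treg = p[if_Treg] * p[ik_aT_exit] * a4;
  double inf_E = p[ik_infil] * y[sTeff_C] * f_inf;
  double inf_H = p[ik_infil] * y[sTh_C] * f_inf;
  double inf_R = p[ik_infil] * y[sTreg_C] * f_inf;
  ydot[sTeff_C] = in_Teff - p[ik_Teff_death_C] * y[sTeff_C] - inf_E;
  ydot[sTh_C] = in_Th - p[ik_Teff_death_C] * y[sTh_C] - inf_H;
  ydot[sTreg_C] = in_Treg - p[ik_Teff_death_C] * y[sTreg_C] - inf_R;

  /* tumor-infiltrating T cells */
  double exh = p[ik_exh_PD1] * y[sTeff_T] * inh +
    p[ik_exh_Treg] * y[sTeff_T] * hillf(y[sTreg_T], p[iK_Treg_exh], 1.0);
  double trans = p[ik_ThTreg] * y[sTh_T] * hillf(y[sTGFb], p[iK_TGFb], 1.0) *
    hillf(y[sArgI], p[iK_ArgI_td], 1.0);
  ydot[sTeff_T] = inf_E - p[ik_Teff_death_T] * y[sTeff_T] - exh;
  ydot[sTh_T] = inf_H - p[ik_Teff_death_T] * y[sTh_T] - trans;
  ydot[sTreg_T] = inf_R + trans - p[ik_Teff_death_T] * y[sTreg_T];
  ydot[sTexh_T] = exh - p[ik_Texh_death] * y[sTexh_T];

  /* MDSC and cytokines */
  double mroom = 1.0 - y[sMDSC_T] / p[iMDSC_max];
  if (mroom < 0.0) mroom = 0.0;
  ydot[sMDSC_T] = p[ik_MDSC_rec] * hillf(y[sCCL2], p[iK_CCL2], 1.0) * mroom -
    p[ik_MDSC_death] * y[sMDSC_T];
  ydot[sCCL2] = p[ik_CCL2_sec] * C / V_T - p[ik_CCL2_deg] * y[sCCL2];
  ydot[sArgI] = p[ik_ArgI_sec] * y[sMDSC_T] / V_T - p[ik_ArgI_deg] * y[sArgI];
  ydot[sNO] = p[ik_NO_sec] * y[sMDSC_T] / V_T - p[ik_NO_deg] * y[sNO];
  ydot[sTGFb] = p[ik_TGFb_sec] * y[sTreg_T] / V_T - p[ik_TGFb_deg] * y[sTGFb];

  /* antibody PK (amounts, mol) */
  double inT;
  inT = p[ik_CT_A] * V_T_cm3 * y[sA_C];
  ydot[sA_C] = -p[iCL_A] * y[sA_C] - p[ik_CP_A] * y[sA_C] +
    p[ik_PC_A] * y[sA_P] - inT + p[ik_TC_A] * y[sA_T] + p[ik_LNC_A] * y[sA_LN];
  ydot[sA_P] = p[ik_CP_A] * y[sA_C] - p[ik_PC_A] * y[sA_P];
  ydot[sA_T] = inT - (p[ik_TC_A] + p[ik_TLN_A]) * y[sA_T];
  ydot[sA_LN] = p[ik_TLN_A] * y[sA_T] - p[ik_LNC_A] * y[sA_LN];

  inT = p[ik_CT_E] * V_T_cm3 * y[sE_C];
  ydot[sE_C] = -p[iCL_E] * y[sE_C] - p[ik_CP_E] * y[sE_C] +
    p[ik_PC_E] * y[sE_P] - inT + p[ik_TC_E] * y[sE_T] + p[ik_LNC_E] * y[sE_LN];
  ydot[sE_P] = p[ik_CP_E] * y[sE_C] - p[ik_PC_E] * y[sE_P];
  ydot[sE_T] = inT - (p[ik_TC_E] + p[ik_TLN_E]) * y[sE_T];
  ydot[sE_LN] = p[ik_TLN_E] * y[sE_T] - p[ik_LNC_E] * y[sE_LN];
}

static const R_CMethodDef cMethods[] = {
  {"qsp_deriv", (DL_FUNC) &qsp_deriv, 6},
  {"qsp_init",  (DL_FUNC) &qsp_init,  1},
  {"qsp_init_root", (DL_FUNC) &qsp_init_root, 1},
  {"qsp_root",  (DL_FUNC) &qsp_root,  7},
  {NULL, NULL, 0}
};

void R_init_qspio(DllInfo *dll)
{
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
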