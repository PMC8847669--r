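/* Compiled right-hand side of the 25-state DC-vaccination model.
 *
 * State order (0-based):
 *   0 dc_blood  1 dc_lung  2 dc_liver  3 dc_spleen
 *   4 traf2  5 traf2p  6 irak1  7 irak1p  8 ikk  9 ikkb
 *   10 m_ikba  11 ikba  12 nfkb_ikba  13 nfkb
 *   14 m_il12  15 il12  16 m_il6  17 il6  18 m_il8  19 il8  20 cd70
 *   21 naive  22 early_effector  23 short_lived_effector  24 memory
 *
 * Parameter block (doubles, fixed length NPAR_TOTAL):
 *   [0..45]   the 46 kinetic parameters in canonical order
 *   [46..49]  delta_IkBa, tau, A, f_SLE2M
 *   [50]      n_u (number of stimulus breakpoints, <= MAXU)
 *   [51..66]  stimulus breakpoint times (padded)
 *   [67..82]  stimulus values (padded)
 *   [83..103] reset state for restimulation events (organ + signaling)
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAXU 16
#define NPAR_TOTAL (46 + 4 + 1 + 2 * MAXU + 21)

static double parms[NPAR_TOTAL];

/* canonical parameter indices */
#define mu_BS        parms[0]
#define mu_BLu       parms[1]
#define mu_BLi       parms[2]
#define mu_P         parms[3]
#define mu_S0        parms[4]
#define mu_Lu0       parms[5]
#define Q_Blood      parms[6]
#define Q_Spleen     parms[7]
#define Q_Lung       parms[8]
#define Q_Liver      parms[9]
#define k_ph1_TRAF2  parms[10]
#define k_ph1_IRAK1  parms[11]
#define k_ph2        parms[12]
#define k_deg_TRAF2p parms[13]
#define k_deg_IRAK1p parms[14]
#define k_syn_IKK    parms[15]
#define k_act_IKK    parms[16]
#define k_deg_IKK    parms[17]
#define k_deg_IKKb   parms[18]
#define N_tot        parms[19]
#define k_ass        parms[20]
#define k_transc_mIkBa parms[21]
#define k_deg_mIkBa  parms[22]
#define k_tranl_IkBa parms[23]
#define k_loss_IkBa  parms[24]
#define k_transc1_mIL8 parms[25]
#define k_transc2_mIL8 parms[26]
#define k_deg_mIL8   parms[27]
#define k_transl_IL8 parms[28]
#define k_deg_IL8    parms[29]
#define k_sec_IL8    parms[30]
#define k_transc2_mIL6 parms[31]
#define k_deg_mIL6   parms[32]
#define k_transl_IL6 parms[33]
#define k_deg_IL6    parms[34]
#define k_transc2_mIL12 parms[35]
#define k_deg_mIL12  parms[36]
#define k_transl_IL12 parms[37]
#define k_deg_IL12   parms[38]
#define k_transc2_CD70 parms[39]
#define k_deg_CD70   parms[40]
#define k_act_N      parms[41]
#define K_4          parms[42]
#define k_diff1_EE   parms[43]
#define k_diff2_EE   parms[44]
#define k_deg_SLE    parms[45]
#define delta_IkBa   parms[46]
#define tau_delay    parms[47]
#define A_amp        parms[48]
#define f_SLE2M      parms[49]
#define n_u          parms[50]
#define U_TIMES      51
#define U_VALUES     (51 + MAXU)
#define Y_RESET      (51 + 2 * MAXU)

/* deSolve lagged-value interface */
static void lagvalue(double T, int *nr, int N, double *ytau) {
  static void (*fun)(double, int *, int, double *) = NULL;
  if (fun == NULL)
    fun = (void (*)(double, int *, int, double *))
      R_GetCCallable("deSolve", "lagvalue");
  fun(T, nr, N, ytau);
}

void dcvax_init(void (*odeparms)(int *, double *)) {
  int n = NPAR_TOTAL;
  odeparms(&n, parms);
}

/* piecewise-constant stimulus; 0 before the first breakpoint */
static double stimulus_at(double t) {
  int n = (int) n_u;
  double u = 0.0;
  for (int i = 0; i < n; i++) {
    if (t >= parms[U_TIMES + i]) u = parms[U_VALUES + i];
    else break;
  }
  return u;
}

void dcvax_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  if (ip[0] < 3) error("nout must be at least 3");

  double u = stimulus_at(*t);

  /* --- organ bio-distribution -------------------------------------- */
  double b = y[0];
  ydot[0] = -(mu_BS + mu_BLu + mu_BLi + mu_P) * b;
  ydot[1] = mu_BLu * (Q_Blood / Q_Lung) * b - mu_Lu0 * y[1];
  ydot[2] = mu_BLi * (Q_Blood / Q_Liver) * b;
  ydot[3] = mu_BS * (Q_Blood / Q_Spleen) * b - mu_S0 * y[3];

  /* --- upstream signaling + IKK ------------------------------------ */
  double d_tp = k_ph1_TRAF2 * u * y[4] / (k_ph2 + y[4]) - k_deg_TRAF2p * y[5];
  double d_ip = k_ph1_IRAK1 * u * y[6] / (k_ph2 + y[6]) - k_deg_IRAK1p * y[7];
  ydot[4] = -d_tp;
  ydot[5] = d_tp;
  ydot[6] = -d_ip;
  ydot[7] = d_ip;
  double act = y[5] + y[7];
  ydot[8] = k_syn_IKK - k_deg_IKK * y[8] - k_act_IKK * act * y[8];
  ydot[9] = k_act_IKK * act * y[8] - k_deg_IKKb * y[9];

  /* --- NF-kB / IkB-alpha core -------------------------------------- */
  double loss = k_loss_IkBa * y[9] + delta_IkBa;
  ydot[10] = k_transc_mIkBa * y[13] - k_deg_mIkBa * y[10];
  double assoc = k_ass * y[13] * y[11];
  ydot[11] = k_tranl_IkBa * y[10] - assoc - loss * y[11];
  double d_complex = assoc - loss * y[12];
  ydot[12] = d_complex;
  ydot[13] = -d_complex;

  /* --- cytokines and CD70 ------------------------------------------ */
  ydot[14] = k_transc2_mIL12 * y[13] - k_deg_mIL12 * y[14];
  ydot[15] = k_transl_IL12 * y[14] - k_deg_IL12 * y[15];
  ydot[16] = k_transc2_mIL6 * y[13] - k_deg_mIL6 * y[16];
  ydot[17] = k_transl_IL6 * y[16] - k_deg_IL6 * y[17];
  ydot[18] = k_transc1_mIL8 + k_transc2_mIL8 * y[13] - k_deg_mIL8 * y[18];
  ydot[19] = k_transl_IL8 * y[18] - (k_deg_IL8 + k_sec_IL8) * y[19];
  ydot[20] = k_transc2_CD70 * y[13] - k_deg_CD70 * y[20];

  /* --- delayed stimulation signal ---------------------------------- */
  double S_now = Q_Spleen * y[3] * (y[17] + y[19] + y[15] + y[20]);
  double S_lag = 0.0;
  if (*t > tau_delay) {
    int nr[5] = {3, 17, 19, 15, 20};
    double ylag[5];
    lagvalue(*t - tau_delay, nr, 5, ylag);
    double dcs = ylag[0] > 0 ? ylag[0] : 0;
    double cyt = 0.0;
    for (int i = 1; i < 5; i++) cyt += ylag[i] > 0 ? ylag[i] : 0;
    S_lag = Q_Spleen * dcs * cyt;
    /* smooth onset of the delayed drive over 0.25 h: keeps the vector
       field continuous at t = tau when S(0) > 0 (in-vitro protocols) */
    double w = (*t - tau_delay) / 0.25;
    if (w < 1.0) S_lag *= w;
  }

  /* --- T-cell pools -------------------------------------------------- */
  double H = S_lag / (K_4 + S_lag);
  double actN = k_act_N * y[21] * H;
  ydot[21] = -actN;
  ydot[22] = A_amp * actN - (k_diff1_EE + k_diff2_EE) * y[22];
  ydot[23] = k_diff1_EE * y[22] - k_deg_SLE * y[23];
  ydot[24] = k_diff2_EE * y[22] + f_SLE2M * k_deg_SLE * y[23];

  yout[0] = S_now;
  yout[1] = S_lag;
  yout[2] = u;
}

/* restimulation event: reset organ + signaling compartments */
void dcvax_event(int *n, double *t, double *y) {
  for (int i = 0; i < 21; i++) y[i] = parms[Y_RESET + i];
}
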