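/* Right-hand side of the 14-compartment platelet reconstitution model,
 * compiled for use with deSolve (dllname = "pltrecon").
 *
 * State order:
 *  0 HSC_PAT  1 TR1_PAT  2 TR2_PAT  3 TR3_PAT  4 PLT_PAT
 *  5 ATG      6 HCT      7 Graft1   8 Graft2
 *  9 HSC_GT  10 TR1_GT  11 TR2_GT  12 TR3_GT  13 PLT_GT
 *
 * The ATG amount is a closed-form dose superposition (first-order decline
 * from each bolus), evaluated analytically from the dose history in the
 * parameter vector when N_ATG > 0; otherwise the ATG state compartment is
 * used. Both are solutions of dATG/dt = -K_INT * ATG with bolus inputs.
 *
 * Parameter vector (see plt_parms_vector() on the R side):
 *  0 K_PAT  1 K_GT  2 K_GR  3 rho  4 alpha  5 K_INT  6 K_EL  7 gamma
 *  8 graft10  9 t_start  10 t_stop  11 feedback floor (clamp)
 *  12 n_tp, then PLT_MAX_TP breakpoint times and PLT_MAX_TP total-protein
 *     multipliers (step function, last observation carried forward; 1
 *     before the first breakpoint)
 *  then n_atg, PLT_MAX_ATG dose times, PLT_MAX_ATG dose amounts (mg).
 */
#include <R.h>
#include <math.h>

#define PLT_MAX_TP 512
#define PLT_MAX_ATG 32
#define PLT_NPAR (13 + 2 * PLT_MAX_TP + 1 + 2 * PLT_MAX_ATG + 1)

static double parms[PLT_NPAR];

#define K_PAT   parms[0]
#define K_GT    parms[1]
#define K_GR    parms[2]
#define RHO     parms[3]
#define ALPHA   parms[4]
#define K_INT   parms[5]
#define K_EL    parms[6]
#define GAMMA   parms[7]
#define GRAFT10 parms[8]
#define T_START parms[9]
#define T_STOP  parms[10]
#define CLAMP   parms[11]
#define N_TP    parms[12]
#define TP_T(i) parms[13 + (i)]
#define TP_M(i) parms[13 + PLT_MAX_TP + (i)]
#define N_ATG   parms[13 + 2 * PLT_MAX_TP]
#define ATG_T(i) parms[14 + 2 * PLT_MAX_TP + (i)]
#define ATG_D(i) parms[14 + 2 * PLT_MAX_TP + PLT_MAX_ATG + (i)]
#define FB_CAP  parms[PLT_NPAR - 1]

void plt_initmod(void (*odeparms)(int *, double *))
{
    int n = PLT_NPAR;
    odeparms(&n, parms);
}

static double tp_multiplier(double t)
{
    int n = (int) N_TP, i;
    double m = 1.0;
    for (i = 0; i < n && i < PLT_MAX_TP; i++) {
        if (TP_T(i) <= t) m = TP_M(i); else break;
    }
    return m;
}

static double atg_amount(double t, double y_atg)
{
    int n = (int) N_ATG, i;
    double a;
    if (n <= 0) return y_atg;
    a = 0.0;
    for (i = 0; i < n && i < PLT_MAX_ATG; i++) {
        if (ATG_T(i) <= t) a += ATG_D(i) * exp(-K_INT * (t - ATG_T(i)));
    }
    return a;
}

void plt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double drug = (*t >= T_START && *t <= T_STOP) ? RHO : 0.0;
    double plt_gt = y[13] > CLAMP ? y[13] : CLAMP;
    double fb = pow(GRAFT10 / plt_gt, GAMMA);
    if (fb > FB_CAP) fb = FB_CAP;
    double tpm = tp_multiplier(*t);
    double atg = atg_amount(*t, y[5]);

    /* patient submodel */
    ydot[0] = K_PAT * (1.0 - drug) * y[0] - K_PAT * y[0];
    ydot[1] = K_PAT * y[0] - K_PAT * y[1];
    ydot[2] = K_PAT * y[1] - K_PAT * y[2];
    ydot[3] = K_PAT * y[2] - K_PAT * y[3];
    ydot[4] = K_PAT * y[3] - K_PAT * y[4] * (1.0 + ALPHA * atg);
    ydot[5] = -K_INT * y[5];

    /* graft submodel */
    ydot[6] = -K_EL * y[6];
    ydot[7] = -K_GR * y[7];
    ydot[8] = K_GR * y[7] - K_GR * y[8];
    ydot[9] = K_GT * fb * (1.0 - y[6]) * tpm * y[9] - K_GT * y[9]
              + K_GR * y[8];
    ydot[10] = K_GT * y[9] - K_GT * y[10];
    ydot[11] = K_GT * y[10] - K_GT * y[11];
    ydot[12] = K_GT * y[11] - K_GT * y[12];
    ydot[13] = K_GT * y[12] - K_GT * y[13];
}
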