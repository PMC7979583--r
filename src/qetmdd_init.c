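/* Compiled right-hand side of the quasi-equilibrium multiple-target TMDD
 * system, in deSolve's compiled-model calling convention.
 *
 * States (amounts, nmol): y[0] depot, y[1] transit, y[2] central (total
 * drug, free + target-bound), y[3] first peripheral, y[4] second peripheral.
 *
 * Parameters (see tmdd_solve_params() on the R side):
 *   0 ka, 1 k20, 2 k23, 3 k32, 4 k24, 5 k42,
 *   6 V2, 7 V3, 8 V4, 9 KD, 10 tVAP1c, 11 mVAP1p1, 12 mVAP1p2
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 13
static double parms[N_PARMS];

#define KA   parms[0]
#define K20  parms[1]
#define K23  parms[2]
#define K32  parms[3]
#define K24  parms[4]
#define K42  parms[5]
#define V2   parms[6]
#define V3   parms[7]
#define V4   parms[8]
#define KD   parms[9]
#define TC   parms[10]
#define TP1  parms[11]
#define TP2  parms[12]

/* Free fraction of drug at total drug concentration C (nM) against total
 * target T (nM) with dissociation constant kd (nM).  Quadratic mass-balance
 * root; the conjugate form is used when C - T - kd <= 0 to avoid
 * cancellation, and the C -> 0 limit kd/(kd + T) is taken explicitly. */
static double phi_free(double C, double T, double kd)
{
    double b, s;
    if (T <= 0.0) return 1.0;
    if (C <= 0.0) return kd / (kd + T);
    b = C - T - kd;
    s = sqrt(b * b + 4.0 * kd * C);
    if (b > 0.0) return (b + s) / (2.0 * C);
    return 2.0 * kd / (s - b);
}

void qetmdd_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void qetmdd_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double phic  = phi_free(y[2] / V2, TC,  KD);
    double phip1 = phi_free(y[3] / V3, TP1, KD);
    double phip2 = phi_free(y[4] / V4, TP2, KD);

    ydot[0] = -KA * y[0];
    ydot[1] =  KA * y[0] - KA * y[1];
    ydot[2] =  KA * y[1] - phic * (K20 + K23 + K24) * y[2]
               + phip1 * K32 * y[3] + phip2 * K42 * y[4];
    ydot[3] =  phic * K23 * y[2] - phip1 * K32 * y[3];
    ydot[4] =  phic * K24 * y[2] - phip2 * K42 * y[4];
}

static const R_CMethodDef CEntries[] = {
    {"qetmdd_initmod", (DL_FUNC) &qetmdd_initmod, 1},
    {"qetmdd_derivs",  (DL_FUNC) &qetmdd_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_qetmdd(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
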