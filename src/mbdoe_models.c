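/* Compiled right-hand sides for the built-in kinetic models, in the
 * standard deSolve compiled-model convention (initfunc + derivs).
 * These mirror the exported R-level rate functions; the R versions are
 * the reference, the C versions exist because Monte-Carlo re-estimation
 * integrates the ODEs hundreds of thousands of times.
 */
#include <R.h>
#include <math.h>

/* ---- irreversible Michaelis-Menten: parms = (r_max, K_S) ---- */

static double mm_p[2];

void mm_init(void (*odeparms)(int *, double *))
{
    int N = 2;
    odeparms(&N, mm_p);
}

void mm_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double denom = y[0] + mm_p[1];
    /* defined limit: rate -> 0 when S and K_S are both zero */
    double rate = (denom > 0.0) ? mm_p[0] * y[0] / denom : 0.0;
    ydot[0] = -rate;
    ydot[1] = rate;
}

/* ---- reversible phosphorolysis under QSSA:
 * states (Thd, Pi, Thy, R1P),
 * parms = (K_M_S, K_M_P, k_catf, k_catr, T_max, T_width, Enz0, Temp) ---- */

static double ph_p[8];

void phos_init(void (*odeparms)(int *, double *))
{
    int N = 8;
    odeparms(&N, ph_p);
}

void phos_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double KMS = ph_p[0], KMP = ph_p[1];
    double kcatf = ph_p[2], kcatr = ph_p[3];
    double Tmax = ph_p[4], Twidth = ph_p[5];
    double Enz0 = ph_p[6], Temp = ph_p[7];

    double dT = Temp - Tmax;
    double tw = 2.0 * Twidth;
    double tf = exp(-(dT * dT) / (tw * tw));

    /* elementary rates from the Michaelis form, each temperature-scaled */
    double k2  = kcatf * tf;
    double km1 = kcatr * tf;
    double k1  = (kcatr + kcatf) / KMS * tf;
    double km2 = (kcatr + kcatf) / KMP * tf;

    double Thd = y[0], Pi = y[1], Thy = y[2], R1P = y[3];
    double denom = k1 * Thd * Pi + km2 * Thy * R1P + km1 + k2;
    double v = Enz0 * (k1 * k2 * Thd * Pi - km1 * km2 * Thy * R1P) / denom;

    ydot[0] = -v;
    ydot[1] = -v;
    ydot[2] = v;
    ydot[3] = v;
}
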