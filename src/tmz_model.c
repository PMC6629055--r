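/* Two-compartment tumor response model with exponential drug clearance.
 *
 * States: y[0] = P (proliferative volume, cm^3)
 *         y[1] = D (lethally damaged volume, cm^3)
 *         y[2] = C (tissue drug concentration, ug/cm^3)
 *
 * Parameters (in order, passed from R via deSolve's initfunc protocol):
 *   rho, K, alpha1, alpha2, kappa, lam, threshold
 *
 * The root function reports total volume P + D crossing `threshold`,
 * used for survival-time detection with lsodar.
 */
#include <R.h>

static double parms[7];
#define rho       parms[0]
#define K         parms[1]
#define alpha1    parms[2]
#define alpha2    parms[3]
#define kappa     parms[4]
#define lam       parms[5]
#define threshold parms[6]

void tmz_init(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void tmz_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double P = y[0], D = y[1], C = y[2];
    double crowd = 1.0 - (P + D) / K;

    ydot[0] = rho * P * crowd - (alpha1 + alpha2) * P * C;
    ydot[1] = -(rho / kappa) * D * crowd + alpha1 * P * C;
    ydot[2] = -lam * C;
}

void tmz_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    gout[0] = y[0] + y[1] - threshold;
}
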