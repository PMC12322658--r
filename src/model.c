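/* Compiled right-hand side of the batch production model for deSolve.
 *
 * States: y[0] = c_b (OD), y[1] = c_p (a.u.), y[2] = c_g (g/L).
 * Parameters (in order): mu_max, k_g, alpha, beta, d_p, Y_gb.
 */
#include <R.h>
#include <Rinternals.h>

static double parms[6];
#define MU_MAX parms[0]
#define K_G    parms[1]
#define ALPHA  parms[2]
#define BETA   parms[3]
#define D_P    parms[4]
#define Y_GB   parms[5]

void odx_initparms(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void odx_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double cg = y[2] > 0 ? y[2] : 0;
    double mu = MU_MAX * cg / (cg + K_G);
    double qp = ALPHA * mu / (BETA + mu);
    ydot[0] = mu * y[0];
    ydot[1] = qp - (D_P + mu) * y[1];
    ydot[2] = -Y_GB * mu * y[0];
}
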