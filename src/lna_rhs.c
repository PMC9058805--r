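/* Compiled right-hand side of the LNA moment ODEs for deSolve.
 *
 * State layout: eta (3), unique covariance entries in the order
 * V11 V12 V13 V22 V23 V33 (6), and optionally the fundamental matrix G
 * column-major (9), selected by neq = 9 or 18.
 *
 * Parameters: par[0] = gamma (removal rate), par[1] = sigma^2 (log-rate
 * diffusion variance).
 */
#include <R.h>
#include <math.h>

static double par[2];

void lna_initmod(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, par);
}

void lna_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double g = par[0], sigma2 = par[1];
    const double s = y[0], i = y[1], b = exp(y[2]);
    const double bsi = b * s * i;

    /* drift */
    ydot[0] = -bsi;
    ydot[1] = bsi - g * i;
    ydot[2] = 0.0;

    /* Jacobian H (row-major) */
    const double h11 = -b * i, h12 = -b * s, h13 = -bsi;
    const double h21 = b * i, h22 = b * s - g, h23 = bsi;

    const double v11 = y[3], v12 = y[4], v13 = y[5];
    const double v22 = y[6], v23 = y[7], v33 = y[8];

    /* rows of H V (third row of H is zero) */
    const double hv11 = h11 * v11 + h12 * v12 + h13 * v13;
    const double hv12 = h11 * v12 + h12 * v22 + h13 * v23;
    const double hv13 = h11 * v13 + h12 * v23 + h13 * v33;
    const double hv21 = h21 * v11 + h22 * v12 + h23 * v13;
    const double hv22 = h21 * v12 + h22 * v22 + h23 * v23;
    const double hv23 = h21 * v13 + h22 * v23 + h23 * v33;

    /* dV = H V + (H V)' + b(eta) on unique entries */
    ydot[3] = 2.0 * hv11 + bsi;
    ydot[4] = hv12 + hv21 - bsi;
    ydot[5] = hv13;
    ydot[6] = 2.0 * hv22 + bsi + g * i;
    ydot[7] = hv23;
    ydot[8] = sigma2;

    if (*neq == 18) {
        /* dG = H G, G column-major in y[9..17] */
        for (int c = 0; c < 3; c++) {
            const double g1 = y[9 + 3 * c], g2 = y[10 + 3 * c],
                         g3 = y[11 + 3 * c];
            ydot[9 + 3 * c] = h11 * g1 + h12 * g2 + h13 * g3;
            ydot[10 + 3 * c] = h21 * g1 + h22 * g2 + h23 * g3;
            ydot[11 + 3 * c] = 0.0;
        }
    }
}
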