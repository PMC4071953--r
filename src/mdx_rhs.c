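/* Compiled right-hand side of the six-variable immune-muscle model for
 * deSolve.  Parameter vector (18 doubles, set through mdx_initmod):
 *   0..5   k1 k2 k3 k4 k5 k6
 *   6..9   dH dC dM dD
 *   10..12 h m sigma          (lognormal damage input)
 *   13..15 H0 C0 M0           (baseline immune counts)
 *   16     mask_var:  0 none, 1 H, 2 C, 3 M
 *   17     mask_mech: 0 none, 1 clamp_zero, 2 block_influx
 */
#include <math.h>

static double parms[18];

void mdx_initmod(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, parms);
}

void mdx_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double k1 = parms[0], k2 = parms[1], k3 = parms[2];
    const double k4 = parms[3], k5 = parms[4], k6 = parms[5];
    const double dH = parms[6], dC = parms[7], dM = parms[8];
    const double dD = parms[9];
    const double h = parms[10], m = parms[11], sigma = parms[12];
    const double H0 = parms[13], C0 = parms[14], M0 = parms[15];
    const int mvar = (int) parms[16], mmech = (int) parms[17];

    double H = y[0], C = y[1], M = y[2];
    double N = y[3], D = y[4], R = y[5];

    if (mmech == 1) {           /* clamp_zero: population held at zero */
        if (mvar == 1) H = 0.0;
        else if (mvar == 2) C = 0.0;
        else if (mvar == 3) M = 0.0;
    }

    double a = 0.0;
    if (*t > 0.0) {
        double z = log(*t) - m;
        a = h / (*t * sigma * sqrt(2.0 * M_PI)) *
            exp(-z * z / (2.0 * sigma * sigma));
    }

    double bH = dH * H0, bC = dC * C0, bM = dM * M0;
    double actH = k1 * D * M, actC = k2 * D * H, actM = k3 * M * D;
    if (mmech == 2) {           /* block_influx: source + activation off */
        if (mvar == 1) { bH = 0.0; actH = 0.0; }
        else if (mvar == 2) { bC = 0.0; actC = 0.0; }
        else if (mvar == 3) { bM = 0.0; actM = 0.0; }
    }

    double dHdt = bH + actH - dH * H;
    double dCdt = bC + actC - dC * C;
    double dMdt = bM + actM - dM * M;
    if (mmech == 1) {
        if (mvar == 1) dHdt = 0.0;
        else if (mvar == 2) dCdt = 0.0;
        else if (mvar == 3) dMdt = 0.0;
    }

    double dNdt = k4 * R - k5 * C * N - a * N;
    double dDdt = k5 * C * N + a * N - k6 * D * M - dD * D;
    double dRdt = -(dNdt + dDdt);   /* fiber conservation, exact */

    ydot[0] = dHdt; ydot[1] = dCdt; ydot[2] = dMdt;
    ydot[3] = dNdt; ydot[4] = dDdt; ydot[5] = dRdt;
}
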