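/* Compiled right-hand side of the FdeR biosensor reporter model.
 *
 * States: y[0] mRNA, y[1] FdeR, y[2] GFP/OD.
 * Parameters (in order):
 *  0 L1, 1 a1, 2 t1, 3 k1, 4 k2, 5 mu_max, 6 frozen,
 *  7 vmax_PROM, 8 K_Pk, 9 K_mRNAp, 10 k_deg, 11 K_mRNAdeg, 12 K_P,
 * 13 K_lysis, 14 RBS_strength, 15 k_FDER, 16 K_NFDER, 17 k_deg_FDER,
 * 18 vmax_NAR, 19 k_deg_GFP, 20 R_basal, 21 hill_half, 22 hill_exp
 */
#include <R.h>
#include <math.h>

#define NPARMS 23
static double parms[NPARMS];

void biosensor_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double logistic(double x)
{
    return 1.0 / (1.0 + exp(-x));
}

void biosensor_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double L1 = parms[0], a1 = parms[1], t1 = parms[2], k1 = parms[3],
           k2 = parms[4], mu_max = parms[5], frozen = parms[6];
    double mu = 0.0;

    if (frozen < 0.5) {
        double s1 = logistic(a1 * (*t - t1));
        double s2 = logistic(k1 * a1 * (*t - k2 * t1));
        double n = L1 * s1 + k1 * s2;
        double dn = L1 * a1 * s1 * (1.0 - s1) +
                    k1 * (k1 * a1) * s2 * (1.0 - s2);
        mu = dn / n;
    }

    double A = (mu_max > 0.0) ? mu / mu_max : 0.0;
    if (A < 0.0) A = 0.0;
    if (A > 1.0) A = 1.0;
    double R = A + parms[20] * (1.0 - A);

    double mrna = y[0] > 0.0 ? y[0] : 0.0;
    double fder = y[1] > 0.0 ? y[1] : 0.0;
    double gfp  = y[2] > 0.0 ? y[2] : 0.0;

    double hh = pow(parms[21], parms[22]);
    double fh = pow(fder, parms[22]);

    ydot[0] = parms[7] * parms[8] * parms[9] - mu * mrna -
              parms[10] * parms[11] * mrna;
    ydot[1] = parms[15] * R * parms[14] * mrna / (mrna + parms[16]) -
              parms[17] * fder * parms[13] - mu * fder;
    ydot[2] = parms[18] * parms[12] * R * fh / (fh + hh) -
              parms[19] * gfp * parms[13] - mu * gfp;
}
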