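/* Right-hand sides of the conjugation / M13-infection kinetic model,
 * in deSolve's compiled-model calling convention.
 *
 * Parameter vector (13, order shared with R/params.R):
 *   psi_max, gamma_max, beta_max, psiP_max, Q, e, K, K_P,
 *   lambda_T, lambda_X, lambda_N, P_psi, P_gamma
 *
 * State orderings:
 *   full:             r, n_D, n_R, n_T, n_X, n_N, n_I, n_XI, n_P   (9)
 *   conjugation-only: r, n_D, n_R, n_T, n_X                        (5)
 *   infection-only:   r, n_D, n_N, n_I, n_P                        (5)
 */

#include <R.h>

static double p[13];

#define PSI_MAX   p[0]
#define GAMMA_MAX p[1]
#define BETA_MAX  p[2]
#define PSIP_MAX  p[3]
#define QHALF     p[4]
#define ECONS     p[5]
#define KCAP      p[6]
#define KPCAP     p[7]
#define LAMBDA_T  p[8]
#define LAMBDA_X  p[9]
#define LAMBDA_N  p[10]
#define P_PSI     p[11]
#define P_GAMMA   p[12]

void conjphage_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, p);
}

/* hyperbolic (Monod) saturation factor r/(Q+r) */
static double sat(double r)
{
    return r / (QHALF + r);
}

void conjphage_derivs_full(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double r = y[0], nD = y[1], nR = y[2], nT = y[3], nX = y[4];
    double nN = y[5], nI = y[6], nXI = y[7], nP = y[8];

    double s     = sat(r);
    double psi   = PSI_MAX * s;
    double gam   = GAMMA_MAX * s;
    double bet   = BETA_MAX * s;
    double psiP  = PSIP_MAX * s;
    double sumn  = nD + nR + nT + nX + nN + nI + nXI;
    double L     = 1.0 - sumn / KCAP;
    double conj  = gam * nD * nR;          /* donor-recipient transfer  */
    double conjI = P_GAMMA * gam * nI * nR; /* infected-donor transfer  */
    double inf   = bet * nD * nP;           /* phage adsorption          */

    ydot[0] = -ECONS * psi * (nD + nR + nT + nX) * L
              - ECONS * P_PSI * psi * (nN + nI + nXI) * L;
    ydot[1] = psi * nD * L - conj + LAMBDA_X * nX + LAMBDA_T * nT - inf;
    ydot[2] = psi * nR * L - conj - conjI;
    ydot[3] = psi * nT * L + conj - LAMBDA_T * nT + conjI;
    ydot[4] = psi * nX * L + conj - LAMBDA_X * nX;
    ydot[5] = P_PSI * psi * nN * L + inf - LAMBDA_N * nN;
    ydot[6] = P_PSI * psi * nI * L + LAMBDA_N * nN - conjI + LAMBDA_X * nXI;
    ydot[7] = P_PSI * psi * nXI * L + conjI - LAMBDA_X * nXI;
    ydot[8] = psiP * (nI + nXI) * (1.0 - nP / KPCAP);
}

void conjphage_derivs_conj(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double r = y[0], nD = y[1], nR = y[2], nT = y[3], nX = y[4];

    double s    = sat(r);
    double psi  = PSI_MAX * s;
    double gam  = GAMMA_MAX * s;
    double sumn = nD + nR + nT + nX;
    double L    = 1.0 - sumn / KCAP;
    double conj = gam * nD * nR;

    ydot[0] = -ECONS * psi * sumn * L;
    ydot[1] = psi * nD * L - conj + LAMBDA_X * nX + LAMBDA_T * nT;
    ydot[2] = psi * nR * L - conj;
    ydot[3] = psi * nT * L + conj - LAMBDA_T * nT;
    ydot[4] = psi * nX * L + conj - LAMBDA_X * nX;
}

void conjphage_derivs_inf(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double r = y[0], nD = y[1], nN = y[2], nI = y[3], nP = y[4];

    double s    = sat(r);
    double psi  = PSI_MAX * s;
    double bet  = BETA_MAX * s;
    double psiP = PSIP_MAX * s;
    double sumn = nD + nN + nI;
    double L    = 1.0 - sumn / KCAP;
    double inf  = bet * nD * nP;

    ydot[0] = -ECONS * psi * nD * L - ECONS * P_PSI * psi * (nN + nI) * L;
    ydot[1] = psi * nD * L - inf;
    ydot[2] = P_PSI * psi * nN * L + inf - LAMBDA_N * nN;
    ydot[3] = P_PSI * psi * nI * L + LAMBDA_N * nN;
    ydot[4] = psiP * nI * (1.0 - nP / KPCAP);
}
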