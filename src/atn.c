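/* Bioenergetic (allometric trophic network) derivatives.
 *
 * The parameter block is a single packed double vector (see pack_atn_parms()
 * on the R side):
 *   P[0]  total length of the vector (lets the initializer size its copy)
 *   P[1]  N                (number of nodes)
 *   P[2]  K                (shared autotroph carrying capacity)
 *   P[3]  ymax             (maximum consumption rate)
 *   P[4]  h                (Hill exponent)
 *   P[5]  fa               (assimilated-carbon growth fraction)
 *   P[6]  fm               (maintenance fraction)
 *   P[7]  has_interference (0/1; skips the O(N^3) interference sum when 0)
 *   then, in order: guild (N; 0 autotroph, 1 invertebrate, 2 fish),
 *   r (N), x (N), eloss (N; per-prey loss-to-predation factor),
 *   w (N*N, column-major; omega_ij = a_ij / P_i),
 *   B0h (N*N; B0_ij^h), cB0h (N*N; a_kj * c_kj * B0_kj^h),
 *   p (N*N; diet-overlap fractions p_ik).
 *
 * State entries below zero are treated as zero biomass (the integrator may
 * undershoot); the caller clamps reported output.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <string.h>

static double *P_g = NULL;
static int P_len = 0;
static double *work_g = NULL;
static int work_len = 0;

/* install the packed parameter block before an integration; deSolve is
 * then called without initfunc/parms (the block length is model-dependent,
 * which the odeparms interface does not accommodate) */
SEXP C_atn_set_parms(SEXP parms)
{
    const int n = LENGTH(parms);
    if (n < 8) error("parameter block too short");
    if (P_len < n) {
        if (P_g) R_Free(P_g);
        P_g = R_Calloc(n, double);
        P_len = n;
    }
    memcpy(P_g, REAL(parms), n * sizeof(double));
    return R_NilValue;
}

static void atn_core(const double *P, const double *y, double *ydot,
                     double *work)
{
    const int N = (int) (P[1] + 0.5);
    const double K = P[2], ymax = P[3], h = P[4], fa = P[5], fm = P[6];
    const int interf = P[7] != 0.0;
    const double *guild = P + 8;
    const double *r = guild + N;
    const double *x = r + N;
    const double *eloss = x + N;
    const double *w = eloss + N;
    const double *B0h = w + (size_t) N * N;
    const double *cB0h = B0h + (size_t) N * N;
    const double *pov = cB0h + (size_t) N * N;

    double *Bc = work;
    double *powh = work + N;
    double *di = work + 2 * N;
    double *loss = work + 3 * N;
    double S_auto = 0.0;
    int i, j, k;

    for (j = 0; j < N; j++) {
        Bc[j] = y[j] > 0.0 ? y[j] : 0.0;
        powh[j] = Bc[j] > 0.0 ? pow(Bc[j], h) : 0.0;
        loss[j] = 0.0;
        di[j] = 0.0;
        if (guild[j] == 0.0) S_auto += Bc[j];
    }

    /* prey sum of the functional-response denominator, per consumer */
    for (j = 0; j < N; j++) {
        const double *wcol = w + (size_t) j * N;
        const double ph = powh[j];
        if (ph == 0.0) continue;
        for (i = 0; i < N; i++)
            if (wcol[i] > 0.0) di[i] += wcol[i] * ph;
    }

    for (i = 0; i < N; i++) {
        double gain = 0.0;
        if (guild[i] != 0.0 && Bc[i] > 0.0) {
            const double xyB = x[i] * ymax * Bc[i];
            for (j = 0; j < N; j++) {
                const double wij = w[i + (size_t) j * N];
                if (wij <= 0.0) continue;
                double denom = B0h[i + (size_t) j * N] + di[i];
                if (interf) {
                    const double *ccol = cB0h + (size_t) j * N;
                    double I = 0.0;
                    for (k = 0; k < N; k++)
                        if (ccol[k] > 0.0)
                            I += pov[i + (size_t) k * N] * ccol[k] * Bc[k];
                    denom += I;
                }
                const double F = wij * powh[j] / denom;
                const double flux = xyB * F;
                gain += flux;
                loss[j] += flux * eloss[j];
            }
        }
        ydot[i] = gain; /* stash; finished below once all losses are known */
    }

    for (i = 0; i < N; i++) {
        if (guild[i] == 0.0)
            ydot[i] = r[i] * (1.0 - S_auto / K) * Bc[i] - loss[i];
        else
            ydot[i] = -fm * x[i] * Bc[i] + fa * ydot[i] - loss[i];
    }
}

void atn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int N = *neq;
    if (work_len < 4 * N) {
        if (work_g) R_Free(work_g);
        work_g = R_Calloc(4 * N, double);
        work_len = 4 * N;
    }
    atn_core(P_g, y, ydot, work_g);
}

/* one-shot evaluation for tests and diagnostics */
SEXP C_atn_deriv(SEXP y, SEXP parms)
{
    const int N = LENGTH(y);
    SEXP ydot = PROTECT(allocVector(REALSXP, N));
    double *work = (double *) R_alloc(4 * N, sizeof(double));
    atn_core(REAL(parms), REAL(y), REAL(ydot), work);
    UNPROTECT(1);
    return ydot;
}

static const R_CallMethodDef callMethods[] = {
    {"C_atn_deriv",     (DL_FUNC) &C_atn_deriv,     2},
    {"C_atn_set_parms", (DL_FUNC) &C_atn_set_parms, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"atn_derivs", (DL_FUNC) &atn_derivs, 0},
    {NULL, NULL, 0}
};

void R_init_atnfish(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
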