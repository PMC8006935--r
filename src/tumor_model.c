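/* Compiled right-hand side of the heterogeneous glioma model for deSolve.
 *
 * State:  y[0] = N    non-cancerous precursor cells
 *         y[1] = C    undifferentiated cancer cells
 *         y[2] = C_R  drug-resistant cancer cells
 *         y[3] = C_S  drug-sensitive cancer cells
 *
 * The parameter vector (length 29) is the full drug-treated parameterisation;
 * with both doses zero the Hill terms vanish exactly and the system reduces
 * to the drug-free model.  The pure-R rhs functions in R/model.R are the
 * reference implementation; tests assert element-wise agreement.
 */
#include <R.h>
#include <math.h>

static double parms[29];

#define ALPHA_N   parms[0]
#define DELTA_N   parms[1]
#define RHO       parms[2]
#define CAP_K     parms[3]
#define MU        parms[4]
#define ALPHA_C   parms[5]
#define DELTA_C   parms[6]
#define GAMMA_R   parms[7]
#define OMEGA_S   parms[8]
#define GAMMA_RT  parms[9]   /* C_S -> C_R transition probability */
#define OMEGA_ST  parms[10]  /* C_R -> C_S transition probability */
#define ALPHA_CR  parms[11]
#define DELTA_R   parms[12]
#define ALPHA_CS  parms[13]
#define DELTA_S   parms[14]
#define EMAX_D1R  parms[15]
#define ETA_D1R   parms[16]
#define IC50_D1R  parms[17]
#define EMAX_D2R  parms[18]
#define ETA_D2R   parms[19]
#define IC50_D2R  parms[20]
#define EMAX_D1S  parms[21]
#define ETA_D1S   parms[22]
#define IC50_D1S  parms[23]
#define EMAX_D2S  parms[24]
#define ETA_D2S   parms[25]
#define IC50_D2S  parms[26]
#define DOSE_D1   parms[27]
#define DOSE_D2   parms[28]

void tumor_init(void (*odeparms)(int *, double *))
{
    int n = 29;
    odeparms(&n, parms);
}

static double gompertz(double alpha, double x, double k, double mu)
{
    return alpha * x * log(k / (x + mu));
}

static double hill_kill(double emax, double dose, double ic50, double eta)
{
    double dn;
    if (dose <= 0.0 || emax <= 0.0)
        return 0.0;
    dn = pow(dose, eta);
    return emax * dn / (pow(ic50, eta) + dn);
}

void tumor_deriv(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double N = y[0], C = y[1], CR = y[2], CS = y[3];

    ydot[0] = ALPHA_N * N * (1.0 - RHO) * (1.0 - N / CAP_K)
              - DELTA_N * N - ALPHA_N * N * RHO;

    ydot[1] = ALPHA_N * RHO * N + gompertz(ALPHA_C, C, CAP_K, MU)
              - GAMMA_R * ALPHA_C * C - OMEGA_S * ALPHA_C * C - DELTA_C * C;

    ydot[2] = GAMMA_R * ALPHA_C * C + GAMMA_RT * ALPHA_CS * CS
              + gompertz(ALPHA_CR, CR, CAP_K, MU)
              - DELTA_R * CR - OMEGA_ST * ALPHA_CR * CR
              - hill_kill(EMAX_D1R, DOSE_D1, IC50_D1R, ETA_D1R) * CR
              - hill_kill(EMAX_D2R, DOSE_D2, IC50_D2R, ETA_D2R) * CR;

    ydot[3] = OMEGA_ST * ALPHA_CR * CR + OMEGA_S * ALPHA_C * C
              + gompertz(ALPHA_CS, CS, CAP_K, MU)
              - DELTA_S * CS - GAMMA_RT * ALPHA_CS * CS
              - hill_kill(EMAX_D1S, DOSE_D1, IC50_D1S, ETA_D1S) * CS
              - hill_kill(EMAX_D2S, DOSE_D2, IC50_D2S, ETA_D2S) * CS;
}
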