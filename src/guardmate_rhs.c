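/* Right-hand side of the 17-compartment mating-strategy model, in the
 * deSolve compiled-model interface. Mirrors rhs_core() in R/model.R;
 * the two are cross-checked in the test suite.
 *
 * Parameter vector (see integrate_model): rho, beta, chi, delta_g,
 * delta_m, omega_F, omega_M, L, mort_factor, q_star.
 */
#include <R.h>

static double parms[10];
#define rho_p      parms[0]
#define beta_p     parms[1]
#define chi_p      parms[2]
#define dg_p       parms[3]
#define dm_p       parms[4]
#define wF_p       parms[5]
#define wM_p       parms[6]
#define L_p        parms[7]
#define mfac_p     parms[8]
#define qstar_p    parms[9]

void guardmate_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

void guardmate_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double s[17];
    for (int i = 0; i < 17; i++) s[i] = (y[i] > 0.0) ? y[i] : 0.0;

    double FM = s[0], FG = s[1], M = s[2], G = s[3];
    double FMm = s[4], FGg = s[5], FGm = s[6], FMg = s[7];
    double PGg = s[8], PG = s[9], PMm = s[10], PMg = s[11], PM = s[12];
    double X = s[13], Xm = s[14], Xg = s[15], Y = s[16];

    double carers = FMm + FGg + FGm + FMg + PGg + PMm + PMg + Xg + Xm;
    double muF = 1.0 / L_p;
    double dens = 0.5 * beta_p * carers;
    if (dens > muF) muF = dens;
    double muM = mfac_p * muF;

    double tot = M + G, fM = 0.0, fG = 0.0;
    if (tot > 0.0) { fM = M / tot; fG = G / tot; }
    double q = fM * qstar_p;

    double m_dep = FMm + FGm + PMm + Xm;
    double g_dep = FGg + FMg + PGg + PMg + Xg;

    ydot[0] = -rho_p * FM + 0.5 * beta_p * m_dep
        + (beta_p + dm_p) * FMm + (beta_p + dg_p) * FMg
        + (chi_p + muM) * PM - (wF_p + muF) * FM;
    ydot[1] = -rho_p * FG + 0.5 * beta_p * g_dep
        + (beta_p + dg_p) * FGg + (beta_p + dm_p) * FGm
        + (chi_p + muM) * PG - (wF_p + muF) * FG;
    ydot[2] = 0.5 * beta_p * m_dep + 0.5 * q * beta_p * g_dep
        - (wM_p + muM) * M;
    ydot[3] = -rho_p * fG * (FM + FG) + 0.5 * (1.0 - q) * beta_p * g_dep
        + (chi_p + wF_p + muF) * (PM + PG + PMg + PGg + PMm)
        - (wM_p + muM) * G;
    ydot[4] = rho_p * fM * FM + (chi_p + muM) * PMm
        - (beta_p + dm_p + wF_p + muF) * FMm;
    ydot[5] = 0.5 * rho_p * fM * FG + (chi_p + muM) * PGg
        - (beta_p + dg_p + wF_p + muF) * FGg;
    ydot[6] = 0.5 * rho_p * fM * FG - (beta_p + dm_p + wF_p + muF) * FGm;
    ydot[7] = (chi_p + muM) * PMg - (beta_p + dg_p + wF_p + muF) * FMg;
    ydot[8] = rho_p * fG * FG + rho_p * PG
        - (beta_p + dg_p + chi_p + wF_p + muM + muF) * PGg;
    ydot[9] = -rho_p * PG + (beta_p + dg_p) * PGg
        - (chi_p + wF_p + muM + muF) * PG;
    ydot[10] = 0.5 * rho_p * fG * FM + 0.5 * rho_p * PM
        - (beta_p + dm_p + chi_p + wF_p + muM + muF) * PMm;
    ydot[11] = 0.5 * rho_p * fG * FM + 0.5 * rho_p * PM
        - (beta_p + dg_p + chi_p + wF_p + muM + muF) * PMg;
    ydot[12] = -rho_p * PM + (beta_p + dm_p) * PMm + (beta_p + dg_p) * PMg
        - (chi_p + wF_p + muM + muF) * PM;
    ydot[13] = wF_p * (FM + FG + PM + PG) + (beta_p + dm_p) * Xm
        + (beta_p + dg_p) * Xg - muF * X;
    ydot[14] = wF_p * (FMm + FGm + PMm) - (beta_p + dm_p + muF) * Xm;
    ydot[15] = wF_p * (FMg + FGg + PGg + PMg) - (beta_p + dg_p + muF) * Xg;
    ydot[16] = wM_p * (M + G) - muM * Y;
}
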