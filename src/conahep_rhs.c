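/* Compiled right-hand side of the 24-state PK/PD/disease-progression ODE
 * system, in the deSolve compiled-model convention. Parameter order must
 * match .c_parms() in R/model.R.
 *
 * States: 0 A_depot, 1 X_central, 2 T1, 3 T1a, 4..10 T1b..T7b, 11 T1c,
 * 12..17 T1d..T6d, 18 C_TNF, 19 C_IFN, 20 C_IL6, 21 C_IL10, 22 A_ALT,
 * 23 A_AST.
 *
 * The ConA event (T1 jump to 1) is applied by the R driver between two
 * solver phases; `cona_active` switches the disease-state IL-10 production
 * term so the right-hand side itself is autonomous.
 */
#include <R.h>
#include <math.h>

#define NP 36
static double p[NP];

void conahep_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

void conahep_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double Vd_F = p[0], ka = p[1], ke = p[2], tau = p[3];
    const double Imax_TNF = p[4], IC50_TNF = p[5], S_TNF = p[6],
        kout_TNF = p[7], R0_TNF = p[8];
    const double Imax_IFN = p[9], IC50_IFN = p[10], S_IFN = p[11],
        kout_IFN = p[12], R0_IFN = p[13];
    const double Imax_IL6 = p[14], IC50_IL6 = p[15], S_IL6 = p[16],
        kout_IL6 = p[17], R0_IL6 = p[18];
    const double S_IL10 = p[19], kout_IL10 = p[20], kin_IL10_dis = p[21],
        I_IL10_IFN = p[22], R0_IL10 = p[23];
    const double S_ALT_TNF = p[24], S_ALT_IFN = p[25], kout_ALT = p[26],
        R0_ALT = p[27], alpha = p[28];
    const double S_AST_TNF = p[29], S_AST_IFN = p[30], kout_AST = p[31],
        R0_AST = p[32], beta = p[33];
    const int drug_present = p[34] > 0.5, cona_active = p[35] > 0.5;

    const double A = y[0], X = y[1], T1 = y[2], T1a = y[3];
    const double *Tb = y + 4;   /* T1b..T7b */
    const double T1c = y[11];
    const double *Td = y + 12;  /* T1d..T6d */
    const double C_TNF = y[18], C_IFN = y[19], C_IL6 = y[20],
        C_IL10 = y[21], A_ALT = y[22], A_AST = y[23];
    int n;

    const double C = X / Vd_F;
    double inh_tnf = 0.0, inh_ifn = 0.0, inh_il6 = 0.0;
    if (drug_present) {
        inh_tnf = Imax_TNF * C / (IC50_TNF + C);
        inh_ifn = Imax_IFN * C / (IC50_IFN + C);
        inh_il6 = Imax_IL6 * C / (IC50_IL6 + C);
    }

    ydot[0] = -ka * A;
    ydot[1] = ka * A - ke * X;
    ydot[2] = -T1 / tau;
    ydot[3] = T1 * (1.0 - inh_tnf) - T1a / tau;
    ydot[4] = T1 * (1.0 - inh_ifn) - Tb[0] / tau;
    for (n = 1; n < 7; n++)
        ydot[4 + n] = (Tb[n - 1] - Tb[n]) / tau;
    ydot[11] = (T1 - T1c) / tau;
    ydot[12] = T1 * (1.0 - inh_il6) - Td[0] / tau;
    for (n = 1; n < 6; n++)
        ydot[12 + n] = (Td[n - 1] - Td[n]) / tau;

    ydot[18] = (1.0 + T1a * S_TNF) * R0_TNF * kout_TNF - kout_TNF * C_TNF;
    ydot[19] = (1.0 + Tb[6] * S_IFN) * R0_IFN * kout_IFN - kout_IFN * C_IFN;
    ydot[20] = (1.0 + Td[5] * S_IL6) * R0_IL6 * kout_IL6 - kout_IL6 * C_IL6;

    {
        double prod10 = R0_IL10 * kout_IL10;
        if (cona_active) {
            double F_IL10 = 1.0 + T1c * S_IL10 - C_IFN * I_IL10_IFN;
            prod10 += F_IL10 * kin_IL10_dis;
            if (prod10 < 0.0) prod10 = 0.0;
        }
        ydot[21] = prod10 - kout_IL10 * C_IL10;
    }

    {
        double exc_tnf = C_TNF - R0_TNF, exc_ifn = C_IFN - R0_IFN;
        double F_ALT, F_AST;
        if (exc_tnf < 0.0) exc_tnf = 0.0;
        if (exc_ifn < 0.0) exc_ifn = 0.0;
        F_ALT = (1.0 + pow(exc_tnf, alpha) * S_ALT_TNF)
              * (1.0 + pow(exc_ifn, beta) * S_ALT_IFN);
        F_AST = (1.0 + exc_tnf * S_AST_TNF) * (1.0 + exc_ifn * S_AST_IFN);
        ydot[22] = F_ALT * R0_ALT * kout_ALT - kout_ALT * A_ALT;
        ydot[23] = F_AST * R0_AST * kout_AST - kout_AST * A_AST;
    }
}
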