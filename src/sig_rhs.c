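/* Compiled right-hand sides of the E2 signaling models for deSolve.
   Parameter vector layout (doubles):
   [0] model code (1, 2, 3)
   [1] clamp flag (E2 derivative zeroed)
   [2..4] knockdown flags for GREB1, PR, TFF1
   [5] b_E2_ER [6] d_ER [7] d_E2_ER
   [8] s_ER [9] s_GREB1 [10] s_PR [11] s_TFF1
   [12] d_GREB1 [13] d_PR [14] d_TFF1
   [15] stim_GREB1 [16] stim_PR [17] stim_TFF1
   Models I/II: [18] b_E2_ER_GREB1 [19] d_E2_ER_GREB1 [20] consumption flag
   Model III:   [18] b_E2_ER_PR [19] b_E2_ER_PR_GREB1
                [20] d_E2_ER_PR [21] d_E2_ER_PR_GREB1                    */

#include <R.h>

static double parms[22];

void init_sig(void (*odeparms)(int *, double *))
{
    int n = 22;
    odeparms(&n, parms);
}

static double pos(double x) { return x > 0 ? x : 0; }

void derivs_sig(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int model = (int) parms[0];
    int clamp = parms[1] != 0;
    int kdG = parms[2] != 0, kdP = parms[3] != 0, kdT = parms[4] != 0;
    double b1 = parms[5], dER = parms[6], dC = parms[7];
    double sER = parms[8], sG = parms[9], sP = parms[10], sT = parms[11];
    double dG = parms[12], dP = parms[13], dT = parms[14];
    double stG = parms[15], stP = parms[16], stT = parms[17];

    if (model == 3) {
        double E2 = pos(y[0]), ER = pos(y[1]), C = pos(y[2]);
        double CP = pos(y[3]), CPG = pos(y[4]);
        double G = pos(y[5]), PR = pos(y[6]), TF = pos(y[7]);
        double bP = parms[18], bPG = parms[19];
        double dCP = parms[20], dCPG = parms[21];
        double fER = b1 * E2 * ER / (1 + E2 + ER);
        double fP = bP * C * PR / (1 + C + PR);
        double fPG = bPG * CP * G / (1 + CP + G);
        double satPG = CPG / (1 + CPG);
        double stimT = stT * C * PR / (1 + C + PR);
        ydot[0] = clamp ? 0 : -fER;
        ydot[1] = sER - fER - dER * ER;
        ydot[2] = fER - fP - dC * C;
        ydot[3] = fP - fPG - dCP * CP;
        ydot[4] = fPG - dCPG * CPG;
        ydot[5] = (kdG ? 0 : sG + stG * satPG) - fPG - dG * G;
        ydot[6] = (kdP ? 0 : sP + stP * satPG) - fP - dP * PR;
        ydot[7] = (kdT ? 0 : sT + stimT) - dT * TF;
    } else {
        double E2 = pos(y[0]), ER = pos(y[1]), C = pos(y[2]);
        double CG = pos(y[3]);
        double G = pos(y[4]), PR = pos(y[5]), TF = pos(y[6]);
        double bG = parms[18], dCG = parms[19];
        int cons = parms[20] != 0;
        double fER = b1 * E2 * ER / (1 + E2 + ER);
        double fG = bG * C * G / (1 + C + G);
        double satCG = CG / (1 + CG);
        double stimG, stimT;
        if (model == 1) {
            stimG = stG * satCG;
            stimT = stT * satCG;
        } else {
            stimG = stG * CG * PR / (1 + CG + PR);
            stimT = stT * C * PR / (1 + C + PR);
        }
        ydot[0] = clamp ? 0 : -fER;
        ydot[1] = sER - fER - dER * ER;
        ydot[2] = fER - fG - dC * C;
        ydot[3] = fG - dCG * CG;
        ydot[4] = (kdG ? 0 : sG + stimG) - (cons ? fG : 0) - dG * G;
        ydot[5] = (kdP ? 0 : sP + stP * satCG) - dP * PR;
        ydot[6] = (kdT ? 0 : sT + stimT) - dT * TF;
    }
}
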