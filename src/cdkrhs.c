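/* minimal Cdk network RHS, deSolve compiled-model convention */
#include <R.h>

static double p[33];

void cdk_initmod(void (*odeparms)(int *, double *))
{
    int n = 33;
    odeparms(&n, p);
}

#define K_SMPF     p[0]
#define ALPHA      p[1]
#define K_IRUM1    p[2]
#define K_ARUM1    p[3]
#define K_DRUM1P   p[4]
#define K_I2RUM1   p[5]
#define K_ASS      p[6]
#define K_DISS     p[7]
#define K_DX       p[8]
#define CCP        p[9]
#define MU         p[10]
#define WEE1_TOT   p[11]
#define AF         p[12]
#define NMPP1      p[13]
#define V_SRUM1    p[14]
#define K_DMPF     p[15]
#define K_DMPF_APC p[16]
#define K_DC       p[17]
#define K_DBR      p[18]
#define K_WEE      p[19]
#define K_25       p[20]
#define K_25B      p[21]
#define VA_WEE     p[22]
#define VI_WEE     p[23]
#define VA_25      p[24]
#define VI_25      p[25]
#define VA_IE      p[26]
#define VI_IE      p[27]
#define VA_APC     p[28]
#define VI_APC     p[29]
#define J_GK       p[30]
#define THETA_S    p[31]
#define THETA_M    p[32]

static double gk(double a, double va, double vi, double ja, double ji)
{
    return va * (1.0 - a) / (ja + 1.0 - a) - vi * a / (ji + a);
}

void cdk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double mpf = y[0], mpf_p = y[1], c = y[2], r = y[3], rp = y[4];
    double w = y[5], d25 = y[6], ie = y[7], apc = y[8], mass = y[9];

    double inh = 1.0 + NMPP1;
    double A = (mpf + ALPHA * mpf_p) / inh;
    double mpfp_eff = mpf_p / inh;
    double vwee = (AF > 0.0) ? 0.0 : K_WEE * WEE1_TOT * w;
    double v25 = K_25B + K_25 * d25;
    double deg = K_DMPF + K_DMPF_APC * apc;
    double ccpd = K_DX * CCP;

    ydot[0] = K_SMPF * mass - vwee * mpf + v25 * mpf_p - deg * mpf
        - K_ASS * mpf * r + (K_DISS + K_IRUM1 + ccpd) * c;
    ydot[1] = vwee * mpf - v25 * mpf_p - deg * mpf_p;
    ydot[2] = K_ASS * mpf * r - (K_DISS + K_IRUM1 + deg + K_DC + ccpd) * c;
    ydot[3] = V_SRUM1 - K_ASS * mpf * r + K_DISS * c + K_ARUM1 * rp
        - K_I2RUM1 * mpfp_eff * r - (ccpd + K_DBR) * r + (deg + K_DC) * c;
    ydot[4] = K_IRUM1 * c + K_I2RUM1 * mpfp_eff * r - K_ARUM1 * rp
        - K_DRUM1P * A * rp - (ccpd + K_DBR) * rp;
    ydot[5] = gk(w, VA_WEE, VI_WEE * A, J_GK, J_GK);
    ydot[6] = gk(d25, VA_25 * A, VI_25, J_GK, J_GK);
    ydot[7] = gk(ie, VA_IE * A, VI_IE, J_GK, J_GK);
    ydot[8] = gk(apc, VA_APC * ie, VI_APC, J_GK, J_GK);
    ydot[9] = MU * mass;

    if (*ip > 0)
        yout[0] = A;
}

/* root at effective MPF activity = theta_m (division / M-entry surface) */
void cdk_root_m(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    gout[0] = (y[0] + ALPHA * y[1]) / (1.0 + NMPP1) - THETA_M;
}
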