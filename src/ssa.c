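/* Gillespie direct-method simulation of the minimal Cdk network with
 * deterministic exponential growth and partition noise at division.
 *
 * The system size omega converts concentrations to molecule numbers
 * (count n = concentration * omega); growth enters the dynamics only
 * through the mass-scaled synthesis flux, exactly as in the ODE model.
 * At division, mass is halved while counts represent intensive
 * concentrations: a daughter inherits Binomial(n, 1/2) molecules in half
 * the volume, so on the fixed omega scale its count is twice that draw -
 * mean-preserving with variance n.  Propensities are refreshed at every
 * firing (and at least every max_step minutes).
 */
#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>

#define N_SPEC 9
#define N_RXN 26

/* parameter vector indices (canonical order, see R/model.R) */
enum {
    P_K_SMPF, P_ALPHA, P_K_IRUM1, P_K_ARUM1, P_K_DRUM1P, P_K_I2RUM1,
    P_K_ASS, P_K_DISS, P_K_DX, P_CCP, P_MU, P_WEE1_TOT, P_AF, P_NMPP1,
    P_V_SRUM1, P_K_DMPF, P_K_DMPF_APC, P_K_DC, P_K_DBR, P_K_WEE, P_K_25,
    P_K_25B, P_VA_WEE, P_VI_WEE, P_VA_25, P_VI_25, P_VA_IE, P_VI_IE,
    P_VA_APC, P_VI_APC, P_J_GK, P_THETA_S, P_THETA_M, N_PAR
};

/* species: 0 MPF, 1 MPF_P, 2 MPF:Rum1, 3 Rum1, 4 Rum1_P,
 *          5 Wee1, 6 Cdc25, 7 IE, 8 APC  (5-8 active counts, total = V) */
static const int STOICH[N_RXN][N_SPEC] = {
    /* mpf mfp  c   r  rp   w  d25 ie apc */
    {  1,  0,  0,  0,  0,  0,  0,  0,  0}, /* 1 FP synthesis            */
    { -1,  1,  0,  0,  0,  0,  0,  0,  0}, /* 2 Wee1 phosphorylation    */
    {  1, -1,  0,  0,  0,  0,  0,  0,  0}, /* 3 Cdc25 dephosphorylation */
    { -1,  0,  0,  0,  0,  0,  0,  0,  0}, /* 4 MPF degradation         */
    {  0, -1,  0,  0,  0,  0,  0,  0,  0}, /* 5 MPF_P degradation       */
    { -1,  0,  1, -1,  0,  0,  0,  0,  0}, /* 6 association             */
    {  1,  0, -1,  1,  0,  0,  0,  0,  0}, /* 7 dissociation            */
    {  1,  0, -1,  0,  1,  0,  0,  0,  0}, /* 8 in-complex Rum1 phosph. */
    {  0,  0, -1,  1,  0,  0,  0,  0,  0}, /* 9 fusion deg. in complex  */
    {  1,  0, -1,  0,  0,  0,  0,  0,  0}, /* 10 CCP deg. of cplx Rum1  */
    {  0,  0,  0,  1,  0,  0,  0,  0,  0}, /* 11 Rum1 synthesis         */
    {  0,  0,  0, -1,  1,  0,  0,  0,  0}, /* 12 MPF_P phosph. of Rum1  */
    {  0,  0,  0, -1,  0,  0,  0,  0,  0}, /* 13 Rum1 basal turnover    */
    {  0,  0,  0, -1,  0,  0,  0,  0,  0}, /* 14 CCP deg. of Rum1       */
    {  0,  0,  0,  1, -1,  0,  0,  0,  0}, /* 15 Rum1_P dephosph.       */
    {  0,  0,  0,  0, -1,  0,  0,  0,  0}, /* 16 2nd phosph. + deg.     */
    {  0,  0,  0,  0, -1,  0,  0,  0,  0}, /* 17 Rum1_P basal turnover  */
    {  0,  0,  0,  0, -1,  0,  0,  0,  0}, /* 18 CCP deg. of Rum1_P     */
    {  0,  0,  0,  0,  0,  1,  0,  0,  0}, /* 19 Wee1 activation        */
    {  0,  0,  0,  0,  0, -1,  0,  0,  0}, /* 20 Wee1 inactivation      */
    {  0,  0,  0,  0,  0,  0,  1,  0,  0}, /* 21 Cdc25 activation       */
    {  0,  0,  0,  0,  0,  0, -1,  0,  0}, /* 22 Cdc25 inactivation     */
    {  0,  0,  0,  0,  0,  0,  0,  1,  0}, /* 23 IE activation          */
    {  0,  0,  0,  0,  0,  0,  0, -1,  0}, /* 24 IE inactivation        */
    {  0,  0,  0,  0,  0,  0,  0,  0,  1}, /* 25 APC activation         */
    {  0,  0,  0,  0,  0,  0,  0,  0, -1}  /* 26 APC inactivation       */
};

static double gk_leg(double num, double frac, double j)
{
    double x = frac < 0 ? 0 : (frac > 1 ? 1 : frac);
    (void) num;
    return x / (j + x);
}

static double gk_act(double frac, double j)
{
    double x = frac < 0 ? 0 : (frac > 1 ? 1 : frac);
    return (1 - x) / (j + 1 - x);
}

/* fill a[N_RXN]; n = counts, V = omega*mass, p = params (with per-cell
 * k_smpf/v_srum1 already substituted) */
static void propensities(const double *n, double V, double mass,
                         const double *p, double *a)
{
    double inh = 1 + p[P_NMPP1];
    double iV = 1.0 / V;
    double x0 = n[0] * iV, x1 = n[1] * iV;
    double A = (x0 + p[P_ALPHA] * x1) / inh;
    double w = n[5] * iV, d25 = n[6] * iV, ie = n[7] * iV, apc = n[8] * iV;
    double vwee = p[P_AF] > 0 ? 0 : p[P_K_WEE] * p[P_WEE1_TOT] *
        (w < 0 ? 0 : (w > 1 ? 1 : w));
    double v25 = p[P_K_25B] + p[P_K_25] * (d25 < 0 ? 0 : (d25 > 1 ? 1 : d25));
    double deg = p[P_K_DMPF] + p[P_K_DMPF_APC] *
        (apc < 0 ? 0 : (apc > 1 ? 1 : apc));
    double ccpd = p[P_K_DX] * p[P_CCP];
    double j = p[P_J_GK];

    a[0] = V * p[P_K_SMPF] * mass;
    a[1] = vwee * n[0];
    a[2] = v25 * n[1];
    a[3] = deg * n[0];
    a[4] = deg * n[1];
    a[5] = p[P_K_ASS] * n[0] * n[3] * iV;
    a[6] = p[P_K_DISS] * n[2];
    a[7] = p[P_K_IRUM1] * n[2];
    a[8] = (deg + p[P_K_DC]) * n[2];
    a[9] = ccpd * n[2];
    a[10] = V * p[P_V_SRUM1];
    a[11] = p[P_K_I2RUM1] * (x1 / inh) * n[3];
    a[12] = p[P_K_DBR] * n[3];
    a[13] = ccpd * n[3];
    a[14] = p[P_K_ARUM1] * n[4];
    a[15] = p[P_K_DRUM1P] * A * n[4];
    a[16] = p[P_K_DBR] * n[4];
    a[17] = ccpd * n[4];
    a[18] = V * p[P_VA_WEE] * gk_act(w, j);
    a[19] = V * p[P_VI_WEE] * A * gk_leg(0, w, j);
    a[20] = V * p[P_VA_25] * A * gk_act(d25, j);
    a[21] = V * p[P_VI_25] * gk_leg(0, d25, j);
    a[22] = V * p[P_VA_IE] * A * gk_act(ie, j);
    a[23] = V * p[P_VI_IE] * gk_leg(0, ie, j);
    a[24] = V * p[P_VA_APC] * (ie < 0 ? 0 : (ie > 1 ? 1 : ie)) *
        gk_act(apc, j);
    a[25] = V * p[P_VI_APC] * gk_leg(0, apc, j);
}

/* R interface: propensity vector at one state (for the drift oracle) */
SEXP C_ssa_propensities(SEXP s_counts, SEXP s_mass, SEXP s_params,
                        SEXP s_omega)
{
    double n[N_SPEC], a[N_RXN];
    double mass = asReal(s_mass), omega = asReal(s_omega);
    double V = omega;
    SEXP out;
    int i;

    if (LENGTH(s_counts) != N_SPEC) error("counts must have length %d", N_SPEC);
    if (LENGTH(s_params) != N_PAR) error("params must have length %d", N_PAR);
    for (i = 0; i < N_SPEC; i++) n[i] = REAL(s_counts)[i];
    propensities(n, V, mass, REAL(s_params), a);
    out = PROTECT(allocVector(REALSXP, N_RXN));
    for (i = 0; i < N_RXN; i++) REAL(out)[i] = a[i];
    UNPROTECT(1);
    return out;
}

SEXP C_ssa_stoich(void)
{
    SEXP out = PROTECT(allocMatrix(INTSXP, N_SPEC, N_RXN));
    int i, r;
    for (r = 0; r < N_RXN; r++)
        for (i = 0; i < N_SPEC; i++)
            INTEGER(out)[i + N_SPEC * r] = STOICH[r][i];
    UNPROTECT(1);
    return out;
}

/* one lineage: SSA with growth, division and per-birth parameter noise.
 *
 * s_counts0: integer(9) initial counts; s_mass0: birth mass;
 * s_params: double(33); s_omega, s_tend, s_record_dt, s_max_step: scalars;
 * s_sigma: double(2) = (sigma_smpf, sigma_srum1);
 * s_binom: logical, binomial (TRUE) or deterministic halving at division;
 * s_max_div: stop after this many divisions (<=0: no limit).
 *
 * Uses R's RNG stream (set.seed on the R side).
 */
SEXP C_ssa_lineage(SEXP s_counts0, SEXP s_mass0, SEXP s_params, SEXP s_omega,
                   SEXP s_tend, SEXP s_record_dt, SEXP s_sigma, SEXP s_binom,
                   SEXP s_max_step, SEXP s_max_div)
{
    double p[N_PAR], n[N_SPEC], a[N_RXN];
    double omega = asReal(s_omega), tend = asReal(s_tend);
    double rec_dt = asReal(s_record_dt), max_step = asReal(s_max_step);
    double sig_smpf = REAL(s_sigma)[0], sig_srum1 = REAL(s_sigma)[1];
    int binom = asLogical(s_binom);
    int max_div = asInteger(s_max_div);
    double base_ksmpf, base_vsrum1;
    double t = 0, mass = asReal(s_mass0);
    double theta_s, theta_m, alpha, inh;
    int i, r;
    long nsteps = 0;

    int n_rec = (int) floor(tend / rec_dt) + 1;
    int cap_div = max_div > 0 ? max_div + 1 : (int) (tend / 10) + 16;

    SEXP s_time = PROTECT(allocVector(REALSXP, n_rec));
    SEXP s_cnt = PROTECT(allocMatrix(INTSXP, n_rec, N_SPEC));
    SEXP s_massv = PROTECT(allocVector(REALSXP, n_rec));
    /* division records: time, mass_before, k_smpf, v_srum1, birth_time,
     * relic, s_entry, m_entry (entry times relative to birth; NA if none) */
    SEXP s_div = PROTECT(allocMatrix(REALSXP, cap_div, 8));
    double *dv = REAL(s_div);
    int n_div = 0, rec_i = 0;

    if (LENGTH(s_params) != N_PAR) error("params must have length %d", N_PAR);
    for (i = 0; i < N_PAR; i++) p[i] = REAL(s_params)[i];
    for (i = 0; i < N_SPEC; i++) n[i] = (double) INTEGER(s_counts0)[i];
    base_ksmpf = p[P_K_SMPF];
    base_vsrum1 = p[P_V_SRUM1];
    theta_s = p[P_THETA_S];
    theta_m = p[P_THETA_M];
    alpha = p[P_ALPHA];
    inh = 1 + p[P_NMPP1];

    GetRNGstate();

    /* per-cycle bookkeeping; threshold crossings are debounced: an entry
     * counts only after the activity stays on the far side for >= 1 min */
    double birth_t = 0, relic = 0, s_entry = NA_REAL, m_entry = NA_REAL;
    double cand_s = NA_REAL, cand_m = NA_REAL;
    int m_conf = 0;
    p[P_K_SMPF] = base_ksmpf * (1 + sig_smpf * (2 * unif_rand() - 1));
    p[P_V_SRUM1] = base_vsrum1 * (1 + sig_srum1 * (2 * unif_rand() - 1));

    const double V = omega;
    double A = (n[0] + alpha * n[1]) / V / inh;

    while (t < tend) {
        if (max_div > 0 && n_div >= max_div) break;
        propensities(n, V, mass, p, a);
        double a0 = 0;
        for (r = 0; r < N_RXN; r++) a0 += a[r];
        double tau;
        int fire;
        if (a0 > 0) {
            tau = exp_rand() / a0;
            fire = 1;
            if (tau > max_step) { tau = max_step; fire = 0; }
        } else {
            tau = max_step;
            fire = 0;
        }
        if (t + tau > tend) { tau = tend - t; fire = 0; }

        /* record on the fixed grid (state during [t, t+tau)) */
        while (rec_i < n_rec && rec_i * rec_dt < t + tau) {
            double tg = rec_i * rec_dt;
            REAL(s_time)[rec_i] = tg;
            REAL(s_massv)[rec_i] = mass * exp(p[P_MU] * (tg - t));
            for (i = 0; i < N_SPEC; i++)
                INTEGER(s_cnt)[rec_i + n_rec * i] = (int) n[i];
            rec_i++;
        }
        if (A < theta_s) relic += tau;

        t += tau;
        mass *= exp(p[P_MU] * tau);

        if (fire) {
            double u = unif_rand() * a0, c = 0;
            for (r = 0; r < N_RXN - 1; r++) { c += a[r]; if (u <= c) break; }
            for (i = 0; i < N_SPEC; i++) n[i] += STOICH[r][i];
            nsteps++;
        }

        double A_new = (n[0] + alpha * n[1]) / V / inh;
        if (ISNA(s_entry)) {
            if (A < theta_s && A_new >= theta_s && ISNA(cand_s))
                cand_s = t;
            else if (A_new < theta_s)
                cand_s = NA_REAL;
            if (!ISNA(cand_s) && t - cand_s >= 1.0)
                s_entry = cand_s - birth_t;
        }
        if (!m_conf) {
            if (A < theta_m && A_new >= theta_m && ISNA(cand_m))
                cand_m = t;
            else if (A_new < theta_m)
                cand_m = NA_REAL;
            if (!ISNA(cand_m) && t - cand_m >= 1.0) {
                m_entry = cand_m - birth_t;
                m_conf = 1;
            }
        }

        if (m_conf && A >= theta_m && A_new < theta_m) {
            /* division */
            if (n_div < cap_div) {
                dv[n_div + cap_div * 0] = t;
                dv[n_div + cap_div * 1] = mass;
                dv[n_div + cap_div * 2] = p[P_K_SMPF];
                dv[n_div + cap_div * 3] = p[P_V_SRUM1];
                dv[n_div + cap_div * 4] = birth_t;
                dv[n_div + cap_div * 5] = relic;
                dv[n_div + cap_div * 6] = s_entry;
                dv[n_div + cap_div * 7] = m_entry;
            }
            n_div++;
            mass /= 2;
            if (binom)
                for (i = 0; i < N_SPEC; i++)
                    n[i] = 2 * rbinom(n[i], 0.5);
            birth_t = t; relic = 0; s_entry = NA_REAL; m_entry = NA_REAL;
            cand_s = NA_REAL; cand_m = NA_REAL; m_conf = 0;
            p[P_K_SMPF] = base_ksmpf *
                (1 + sig_smpf * (2 * unif_rand() - 1));
            p[P_V_SRUM1] = base_vsrum1 *
                (1 + sig_srum1 * (2 * unif_rand() - 1));
            A_new = (n[0] + alpha * n[1]) / V / inh;
        }
        A = A_new;
        if (nsteps % 4096 == 0) R_CheckUserInterrupt();
    }

    PutRNGstate();

    /* fill any remaining record slots with the final state */
    while (rec_i < n_rec) {
        REAL(s_time)[rec_i] = rec_i * rec_dt;
        REAL(s_massv)[rec_i] = mass;
        for (i = 0; i < N_SPEC; i++)
            INTEGER(s_cnt)[rec_i + n_rec * i] = (int) n[i];
        rec_i++;
    }

    {
        int keep = n_div < cap_div ? n_div : cap_div;
        SEXP s_divout = PROTECT(allocMatrix(REALSXP, keep, 8));
        for (r = 0; r < keep; r++)
            for (i = 0; i < 8; i++)
                REAL(s_divout)[r + keep * i] = dv[r + cap_div * i];
        SEXP out = PROTECT(allocVector(VECSXP, 5));
        SET_VECTOR_ELT(out, 0, s_time);
        SET_VECTOR_ELT(out, 1, s_cnt);
        SET_VECTOR_ELT(out, 2, s_massv);
        SET_VECTOR_ELT(out, 3, s_divout);
        SET_VECTOR_ELT(out, 4, ScalarReal((double) nsteps));
        SEXP nms = PROTECT(allocVector(STRSXP, 5));
        SET_STRING_ELT(nms, 0, mkChar("time"));
        SET_STRING_ELT(nms, 1, mkChar("counts"));
        SET_STRING_ELT(nms, 2, mkChar("mass"));
        SET_STRING_ELT(nms, 3, mkChar("divisions"));
        SET_STRING_ELT(nms, 4, mkChar("nsteps"));
        setAttrib(out, R_NamesSymbol, nms);
        UNPROTECT(7);
        return out;
    }
}
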