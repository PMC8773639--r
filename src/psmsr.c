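/* PSMSR right-hand side and a Dormand-Prince 5(4) panel integrator.
 *
 * State layout per culture block (6 doubles):
 *   y[0] Rs  red-labelled cells, sensitive phenotype
 *   y[1] Rt  red-labelled cells, tolerant phenotype
 *   y[2] Gs  green-labelled cells, sensitive phenotype
 *   y[3] Gt  green-labelled cells, tolerant phenotype
 *   y[4] C   hidden stress level
 *   y[5] AUC accumulated drug exposure (uM * h)
 *
 * Parameter vector layout (25 doubles), shared with the R side
 * (see .parvec() in R/model-core.R):
 *   0 K0   1 Kb   2 KGs0  3 KGt0  4 Kstr  5 Kstrd  6 a  7 b  8 g
 *   9 Sdrug 10 AUC5s 11 AUC95s 12 SCALEs 13 AUC5t 14 AUC95t 15 SCALEt
 *   16 conc (uM)  17 drugOn (0/1)  18 hasDrug (0/1)
 *   19 coupling (0 linear, 1 sigmoidal)  20 aucDecay (1/day)
 *   21 sdrugCouple (0/1)  22 ampGS  23 ampGT  24 ampK
 *
 * Time unit is days; AUC accumulates at 24*conc per day while drug is on.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 25
#define NSTATE 6

static double ln19; /* set in R_init */

static double clamp_exp(double x)
{
    if (x > 700.0) x = 700.0;
    if (x < -700.0) x = -700.0;
    return exp(x);
}

/* logistic kill fraction anchored at 5% (AUC5) and 95% (AUC95) */
static double sig01(double auc, double a5, double a95)
{
    double z = ln19 * (1.0 - 2.0 * (auc - a5) / (a95 - a5));
    return 1.0 / (1.0 + clamp_exp(z));
}

/* monotone saturating map: value f0 and slope -s at C = 0, amplitude amp >= 0 */
static double sat_down(double f0, double s, double amp, double C)
{
    if (amp <= 0.0 || s <= 0.0) return f0 - s * C; /* degenerate: keep linear */
    return f0 - amp * tanh(s * C / amp);
}

static double sat_up(double f0, double s, double amp, double C)
{
    if (amp <= 0.0 || s <= 0.0) return f0 + s * C;
    return f0 + amp * tanh(s * C / amp);
}

static void rhs_core(const double *y, double *dy, const double *p, int nblk)
{
    const double K0 = p[0], Kb = p[1], KGs0 = p[2], KGt0 = p[3];
    const double Kstr = p[4], Kstrd = p[5], a = p[6], b = p[7], g = p[8];
    const double Sdrug = p[9];
    const double A5s = p[10], A95s = p[11], SCs = p[12];
    const double A5t = p[13], A95t = p[14], SCt = p[15];
    const double conc = p[16];
    const int drugOn = p[17] != 0.0;
    const int hasDrug = p[18] != 0.0;
    const int sigm = p[19] != 0.0;
    const double aucDecay = p[20];
    const int sdrugCouple = p[21] != 0.0;
    const double ampGS = p[22], ampGT = p[23], ampK = p[24];

    for (int blk = 0; blk < nblk; blk++) {
        const double *yb = y + NSTATE * blk;
        double *db = dy + NSTATE * blk;
        double Rs = yb[0], Rt = yb[1], Gs = yb[2], Gt = yb[3];
        double C = yb[4], AUC = yb[5];
        double KGS, KGT, K;

        if (sigm) {
            KGS = sat_down(KGs0, a, ampGS, C);
            KGT = sat_down(KGt0, b, ampGT, C);
            K = sat_up(K0, g, ampK, C);
        } else {
            KGS = KGs0 - a * C;
            KGT = KGt0 - b * C;
            K = K0 + g * C;
        }
        double Ka = K * Kb;

        double dS = 0.0, dT = 0.0;
        if (hasDrug) {
            dS = SCs * sig01(AUC, A5s, A95s);
            dT = SCt * sig01(AUC, A5t, A95t);
        }

        double S = Rs + Gs, T = Rt + Gt;

        db[0] = -Ka * Rs + Kb * Rt + KGS * Rs - dS * Rs;
        db[1] = Ka * Rs - Kb * Rt + KGT * Rt - dT * Rt;
        db[2] = -Ka * Gs + Kb * Gt + KGS * Gs - dS * Gs;
        db[3] = Ka * Gs - Kb * Gt + KGT * Gt - dT * Gt;
        db[4] = Kstr * S - Kstrd * T;
        if (sdrugCouple && drugOn) db[4] += Sdrug;
        /* stress is a non-negative quantity: tolerant cells cannot remove
         * what is not there (reflecting boundary at zero) */
        if (C <= 0.0 && db[4] < 0.0) db[4] = 0.0;
        db[5] = drugOn ? 24.0 * conc : -aucDecay * AUC;
    }
}

/* ---------------- deSolve compiled interface ---------------- */

static double desolve_parms[NPAR];

void psmsr_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, desolve_parms);
}

void psmsr_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    rhs_core(y, ydot, desolve_parms, *neq / NSTATE);
}

/* ---------------- .Call helpers ---------------- */

/* single RHS evaluation, for cross-checking the R reference implementation */
SEXP C_psmsr_rhs(SEXP y_, SEXP par_)
{
    int n = LENGTH(y_);
    if (n % NSTATE != 0) error("state length must be a multiple of %d", NSTATE);
    if (LENGTH(par_) != NPAR) error("parameter vector must have length %d", NPAR);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    rhs_core(REAL(y_), REAL(out), REAL(par_), n / NSTATE);
    UNPROTECT(1);
    return out;
}

/* Dormand-Prince 5(4) coefficients */
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

/* Integrate nblk independent PSMSR blocks with shared parameters from
 * times[0] to times[nt-1], writing the state at every requested time.
 * Returns an nt x (6*nblk) matrix; rows past an integrator failure are NaN. */
SEXP C_psmsr_panel(SEXP y0_, SEXP times_, SEXP par_, SEXP rtol_, SEXP atol_)
{
    if (LENGTH(par_) != NPAR) error("parameter vector must have length %d", NPAR);
    int n = LENGTH(y0_);
    if (n == 0 || n % NSTATE != 0)
        error("initial state length must be a positive multiple of %d", NSTATE);
    int nblk = n / NSTATE;
    int nt = LENGTH(times_);
    const double *times = REAL(times_);
    const double *p = REAL(par_);
    double rtol = asReal(rtol_), atol = asReal(atol_);

    SEXP out_ = PROTECT(allocMatrix(REALSXP, nt, n));
    double *out = REAL(out_);

    double y[n], yn[n], k1[n], k2[n], k3[n], k4[n], k5[n], k6[n], k7[n], ytmp[n];
    memcpy(y, REAL(y0_), n * sizeof(double));

    double t = times[0];
    for (int j = 0; j < n; j++) out[0 + nt * j] = y[j];

    double h = (times[nt - 1] - times[0]) / 100.0;
    if (h <= 0) h = 1e-3;
    const double hmin = 1e-12, hmax = times[nt - 1] - times[0];
    long maxsteps = 2000000;
    int failed = 0;

    rhs_core(y, k1, p, nblk); /* FSAL */

    for (int it = 1; it < nt; it++) {
        double tout = times[it];
        while (!failed && t < tout) {
            if (--maxsteps < 0 || h < hmin) { failed = 1; break; }
            int hit = 0;
            if (t + h >= tout) { h = tout - t; hit = 1; }

            for (int j = 0; j < n; j++) ytmp[j] = y[j] + h * a21 * k1[j];
            rhs_core(ytmp, k2, p, nblk);
            for (int j = 0; j < n; j++)
                ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
            rhs_core(ytmp, k3, p, nblk);
            for (int j = 0; j < n; j++)
                ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
            rhs_core(ytmp, k4, p, nblk);
            for (int j = 0; j < n; j++)
                ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                                      a54 * k4[j]);
            rhs_core(ytmp, k5, p, nblk);
            for (int j = 0; j < n; j++)
                ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                                      a64 * k4[j] + a65 * k5[j]);
            rhs_core(ytmp, k6, p, nblk);
            for (int j = 0; j < n; j++)
                yn[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                                    b5 * k5[j] + b6 * k6[j]);
            rhs_core(yn, k7, p, nblk);

            double err = 0.0;
            for (int j = 0; j < n; j++) {
                double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                 e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
                double sc = atol + rtol * fmax(fabs(y[j]), fabs(yn[j]));
                double r = ej / sc;
                err += r * r;
            }
            err = sqrt(err / n);
            if (!R_FINITE(err)) { failed = 1; break; }

            if (err <= 1.0) {
                t = hit ? tout : t + h;
                memcpy(y, yn, n * sizeof(double));
                memcpy(k1, k7, n * sizeof(double));
            }
            double fac = 0.9 * pow(err > 1e-12 ? err : 1e-12, -0.2);
            if (fac < 0.2) fac = 0.2;
            if (fac > 5.0) fac = 5.0;
            h *= fac;
            if (h > hmax) h = hmax;
        }
        for (int j = 0; j < n; j++)
            out[it + nt * j] = failed ? R_NaN : y[j];
    }

    UNPROTECT(1);
    return out_;
}

/* ---------------- registration ---------------- */

static const R_CallMethodDef callMethods[] = {
    {"C_psmsr_panel", (DL_FUNC) &C_psmsr_panel, 5},
    {"C_psmsr_rhs", (DL_FUNC) &C_psmsr_rhs, 2},
    {NULL, NULL, 0}
};

/* registered so deSolve can resolve them by name with dynamic lookup off */
static const R_CMethodDef cMethods[] = {
    {"psmsr_derivs", (DL_FUNC) &psmsr_derivs, -1},
    {"psmsr_initmod", (DL_FUNC) &psmsr_initmod, -1},
    {NULL, NULL, 0}
};

void R_init_psmsr(DllInfo *info)
{
    ln19 = log(19.0);
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
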