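/* SIR model with logistic recruitment of susceptibles.
 *
 * Two entry points:
 *   - sir_initmod / sir_derivs: deSolve-compatible right-hand side used by
 *     simulate_sir() through deSolve's compiled-model interface.
 *   - C_sir_objective_batch: evaluates the least-squares objective for a whole
 *     population of candidate parameter vectors with an embedded adaptive
 *     Dormand-Prince 5(4) integrator.  The genetic algorithm calls this once
 *     per generation, so per-candidate overhead must stay in microseconds.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- deSolve compiled-model interface ---------------------------------- */

static double parms[4]; /* alpha, beta, mu, K */

void sir_initmod(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, parms);
}

void sir_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double alpha = parms[0], beta = parms[1], mu = parms[2], K = parms[3];
    const double S = y[0], I = y[1], R = y[2];
    const double N = S + I + R;
    ydot[0] = mu * ((K - N) / K) * N - alpha * S * I;
    ydot[1] = alpha * S * I - beta * I;
    ydot[2] = beta * I;
}

/* ---- embedded Dormand-Prince 5(4) -------------------------------------- */

static void rhs(const double *y, double *dy,
                double alpha, double beta, double mu, double K)
{
    const double N = y[0] + y[1] + y[2];
    dy[0] = mu * ((K - N) / K) * N - alpha * y[0] * y[1];
    dy[1] = alpha * y[0] * y[1] - beta * y[1];
    dy[2] = beta * y[1];
}

/* Dormand-Prince coefficients */
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0,
                    B4 = 125.0 / 192.0, B5 = -2187.0 / 6784.0,
                    B6 = 11.0 / 84.0;
/* difference between 5th- and 4th-order weights (error estimator) */
static const double E1 = 35.0 / 384.0 - 5179.0 / 57600.0;
static const double E3 = 500.0 / 1113.0 - 7571.0 / 16695.0;
static const double E4 = 125.0 / 192.0 - 393.0 / 640.0;
static const double E5 = -2187.0 / 6784.0 + 92097.0 / 339200.0;
static const double E6 = 11.0 / 84.0 - 187.0 / 2100.0;
static const double E7 = -1.0 / 40.0;

#define MAX_STEPS 200000

/* Integrate from t=0 to t=(nout-1), storing I at integer times into iout.
 * Returns 0 on success, 1 on failure (step collapse, non-finite state, or a
 * negative excursion beyond tolerance). */
static int integrate_I(double alpha, double beta, double mu, double K,
                       double S0, double I0, double R0,
                       double rtol, double atol,
                       int nout, double *iout)
{
    double y[3] = { S0, I0, R0 };
    double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], ynew[3];
    double t = 0.0, h = 0.1;
    const double tend = (double)(nout - 1);
    const double neg_tol = -1e-6 * fmax(1.0, S0 + I0 + R0);
    int iobs = 0;
    long steps = 0;

    iout[iobs++] = I0;
    if (nout == 1) return 0;

    rhs(y, k1, alpha, beta, mu, K); /* FSAL: k1 reused across steps */

    while (t < tend) {
        if (++steps > MAX_STEPS) return 1;
        if (h < 1e-12) return 1;
        double tnext = (double)iobs; /* next integer output time */
        if (t + h > tnext) h = tnext - t;

        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * A21 * k1[i];
        rhs(yt, k2, alpha, beta, mu, K);
        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
        rhs(yt, k3, alpha, beta, mu, K);
        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
        rhs(yt, k4, alpha, beta, mu, K);
        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
        rhs(yt, k5, alpha, beta, mu, K);
        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] + A64 * k4[i] + A65 * k5[i]);
        rhs(yt, k6, alpha, beta, mu, K);
        for (int i = 0; i < 3; i++)
            ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] + B5 * k5[i] + B6 * k6[i]);
        rhs(ynew, k7, alpha, beta, mu, K);

        /* scaled error norm */
        double err = 0.0;
        for (int i = 0; i < 3; i++) {
            double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
            double sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            double r = e / sc;
            err += r * r;
        }
        err = sqrt(err / 3.0);
        if (!R_FINITE(err)) return 1;

        if (err <= 1.0) { /* accept */
            t += h;
            for (int i = 0; i < 3; i++) {
                if (ynew[i] < neg_tol) return 1;
                y[i] = ynew[i];
                k1[i] = k7[i];
            }
            if (t >= (double)iobs - 1e-12) {
                iout[iobs] = y[1] > 0.0 ? y[1] : 0.0;
                if (++iobs >= nout) return 0;
            }
        }
        double fac = err > 0.0 ? 0.9 * pow(err, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        h *= fac;
    }
    return iobs >= nout ? 0 : 1;
}

/* theta: 5 x m matrix (alpha, beta, mu, S0, K by column per candidate).
 * obs: observed counts at integer months 0..n-1; I0, R0 initial conditions.
 * Returns per-candidate sum of squared residuals; NA_real_ signals failure
 * (including K < S0 + I0 + R0 infeasibility), mapped to a penalty in R. */
SEXP C_sir_objective_batch(SEXP theta, SEXP obs, SEXP i0, SEXP r0,
                           SEXP rtol_, SEXP atol_)
{
    if (!isMatrix(theta) || nrows(theta) != 5)
        error("theta must be a 5-row matrix");
    const int m = ncols(theta);
    const int n = length(obs);
    const double *th = REAL(theta);
    const double *y = REAL(obs);
    const double I0 = asReal(i0), R0 = asReal(r0);
    const double rtol = asReal(rtol_), atol = asReal(atol_);

    SEXP out = PROTECT(allocVector(REALSXP, m));
    double *res = REAL(out);
    double *ihat = (double *) R_alloc(n, sizeof(double));

    for (int j = 0; j < m; j++) {
        const double alpha = th[5 * j], beta = th[5 * j + 1], mu = th[5 * j + 2],
                     S0 = th[5 * j + 3], K = th[5 * j + 4];
        if (!R_FINITE(alpha) || !R_FINITE(beta) || !R_FINITE(mu) ||
            !R_FINITE(S0) || !R_FINITE(K) || K <= 0.0 ||
            S0 + I0 + R0 > K) {
            res[j] = NA_REAL;
            continue;
        }
        if (integrate_I(alpha, beta, mu, K, S0, I0, R0, rtol, atol, n, ihat)) {
            res[j] = NA_REAL;
            continue;
        }
        double ss = 0.0;
        for (int i = 0; i < n; i++) {
            double d = y[i] - ihat[i];
            ss += d * d;
        }
        res[j] = R_FINITE(ss) ? ss : NA_REAL;
    }
    UNPROTECT(1);
    return out;
}

/* Single-candidate I(t) on the integer grid; errors on failure.  Used to
 * cross-check the embedded integrator against deSolve. */
SEXP C_sir_integrate_I(SEXP theta, SEXP i0, SEXP r0, SEXP nout_,
                       SEXP rtol_, SEXP atol_)
{
    const double *th = REAL(theta);
    const int nout = asInteger(nout_);
    SEXP out = PROTECT(allocVector(REALSXP, nout));
    if (integrate_I(th[0], th[1], th[2], th[4], th[3], asReal(i0), asReal(r0),
                    asReal(rtol_), asReal(atol_), nout, REAL(out)))
        error("integration failed");
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_sir_objective_batch", (DL_FUNC) &C_sir_objective_batch, 6},
    {"C_sir_integrate_I",     (DL_FUNC) &C_sir_integrate_I,     6},
    {NULL, NULL, 0}
};

void R_init_sirtopics(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up sir_derivs by name */
}
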