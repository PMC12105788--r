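/* Lotka-Volterra predator-prey dynamics with optional time-varying rate
 * modulators, in the deSolve compiled-model idiom.
 *
 * d prey/dt = g1(t) x1 prey - g2(t) x2 prey pred
 * d pred/dt = g2(t) x2 prey pred - g3(t) x3 pred
 *
 * parms layout (length 16):
 *   [0..2]   x1, x2, x3
 *   [3..6]   modulator 1: type, a, b, c
 *   [7..10]  modulator 2: type, a, b, c
 *   [11..14] modulator 3: type, a, b, c
 *   [15]     T (period constant for sinusoidal modulators)
 * modulator types: 0 identity; 1 sinusoidal 1 + c sin(2 pi (t-a) b / T);
 * 2 quadratic 1 - ((t-5)^2/25 - 0.5)/10.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>

static double parms[16];

void lvpp_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

static double modulate(double t, const double *m, double period)
{
    int type = (int) m[0];
    if (type == 1)
        return 1.0 + m[3] * sin(2.0 * M_PI * (t - m[1]) * m[2] / period);
    if (type == 2)
        return 1.0 - ((t - 5.0) * (t - 5.0) / 25.0 - 0.5) / 10.0;
    return 1.0;
}

void lvpp_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double g1 = modulate(*t, parms + 3, parms[15]);
    double g2 = modulate(*t, parms + 7, parms[15]);
    double g3 = modulate(*t, parms + 11, parms[15]);
    double inter = g2 * parms[1] * y[0] * y[1];
    ydot[0] = g1 * parms[0] * y[0] - inter;
    ydot[1] = inter - g3 * parms[2] * y[1];
}

/* Stochastic Lotka-Volterra via the Gillespie algorithm with
 * piecewise-constant time-varying hazards.  Three reactions:
 *   prey birth       hazard g(t) x1 prey          prey +1
 *   conversion       hazard g(t) x2 prey pred     prey -1, pred +1
 *   predator death   hazard g(t) x3 pred          pred -1
 * The modulator g is supplied pre-evaluated on a refresh grid; hazards are
 * constant within each refresh interval, so drawing an exponential waiting
 * time and discarding it at interval boundaries is exact for the
 * piecewise-constant process.
 *
 * Records the state at each grid time (the state just before/at that time).
 * Returns list(prey, pred, n_events, capped).
 */
SEXP gillespie_lv_c(SEXP sx, SEXP sinit, SEXP sgrid, SEXP sgvals, SEXP scap)
{
    double x1 = REAL(sx)[0], x2 = REAL(sx)[1], x3 = REAL(sx)[2];
    double prey = REAL(sinit)[0], pred = REAL(sinit)[1];
    double *grid = REAL(sgrid);
    double *gv = REAL(sgvals);        /* g on each interval, length ngrid-1 */
    double cap = REAL(scap)[0];
    int ngrid = LENGTH(sgrid);

    SEXP sprey = PROTECT(allocVector(REALSXP, ngrid));
    SEXP spred = PROTECT(allocVector(REALSXP, ngrid));
    double *outprey = REAL(sprey), *outpred = REAL(spred);
    double nev = 0.0;
    int capped = 0;

    GetRNGstate();
    outprey[0] = prey; outpred[0] = pred;
    double t = grid[0];
    int filled = 0;
    for (int i = 0; i < ngrid - 1 && !capped; i++) {
        double tend = grid[i + 1];
        double g = gv[i];
        for (;;) {
            double h1 = g * x1 * prey;
            double h2 = g * x2 * prey * pred;
            double h3 = g * x3 * pred;
            double htot = h1 + h2 + h3;
            if (htot <= 0.0) { t = tend; break; }
            double dt = exp_rand() / htot;
            if (t + dt >= tend) { t = tend; break; }
            t += dt;
            double u = unif_rand() * htot;
            if (u < h1)            prey += 1.0;
            else if (u < h1 + h2)  { prey -= 1.0; pred += 1.0; }
            else                   pred -= 1.0;
            nev += 1.0;
            if (prey > cap || pred > cap) { capped = 1; break; }
        }
        outprey[i + 1] = prey; outpred[i + 1] = pred;
        filled = i + 1;
    }
    PutRNGstate();

    /* on a population-cap abort, pad the remaining records with the last
     * state so vector lengths stay consistent (caller raises the error) */
    for (int j = filled + 1; j < ngrid; j++) {
        outprey[j] = prey; outpred[j] = pred;
    }

    SEXP ans = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(ans, 0, sprey);
    SET_VECTOR_ELT(ans, 1, spred);
    SET_VECTOR_ELT(ans, 2, ScalarReal(nev));
    SET_VECTOR_ELT(ans, 3, ScalarLogical(capped));
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("prey"));
    SET_STRING_ELT(nm, 1, mkChar("pred"));
    SET_STRING_ELT(nm, 2, mkChar("n_events"));
    SET_STRING_ELT(nm, 3, mkChar("capped"));
    setAttrib(ans, R_NamesSymbol, nm);
    UNPROTECT(4);
    return ans;
}
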