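/* Compiled right-hand side of the ABE balance equations, dC/dt = N r X.
 * Mirrors the R reference implementation (abe_rhs / compute_rates); their
 * agreement is asserted in the test suite.
 *
 * Parameter layout (set once per integration via abe_init):
 *   p[(i-1)*4 + 0..3] = V, kA, kB, kC of reaction i (NaN where absent),
 *   p[76]             = clamp-NADH flag.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double p[77];

void abe_init(void (*odeparms)(int *, double *))
{
    int n = 77;
    odeparms(&n, p);
}

#define V(i)  p[((i) - 1) * 4 + 0]
#define KA(i) p[((i) - 1) * 4 + 1]
#define KB(i) p[((i) - 1) * 4 + 2]
#define KC(i) p[((i) - 1) * 4 + 3]

static double mm(double v, double km, double s)
{
    return v * s / (km + s);
}

void abe_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double s[16];
    double r[20];   /* 1-based */
    double den, X;
    int i;

    for (i = 0; i < 16; i++)
        s[i] = y[i] > 0 ? y[i] : 0;

    {
        double G = s[0], F6P = s[1], G3P = s[2], Pyr = s[3], Lac = s[4],
               ACoA = s[5], Ac = s[7], AACoA = s[9], AcAc = s[10],
               BCoA = s[11], Buty = s[12], BuOH = s[14], NADH = s[15];

        /* glucose uptake: substrate inhibition (kC) + butanol inhibition (kB) */
        r[1] = V(1) * G / (KA(1) * (1 + G / KC(1)) + G * (1 + BuOH / KB(1)));
        r[2] = mm(V(2), KA(2), F6P);
        r[3] = mm(V(3), KA(3), G3P);
        r[4] = mm(V(4), KA(4), Lac);
        r[5] = mm(V(5), KA(5), Pyr);
        r[6] = mm(V(6), KA(6), Pyr);
        r[7] = mm(V(7), KA(7), Ac);
        r[8] = V(8) * (Ac / (KA(8) + Ac)) * (AACoA / (KB(8) + AACoA));
        r[9] = mm(V(9), KA(9), ACoA);
        r[10] = mm(V(10), KA(10), ACoA);
        den = ACoA * NADH + KA(11) * NADH + KB(11) * ACoA;
        r[11] = den == 0 ? 0 : V(11) * ACoA * NADH / den;
        r[12] = V(12) * ACoA / ((KA(12) + ACoA) * (1 + BuOH / KB(12)));
        r[13] = KA(13);
        den = AACoA * NADH + KA(14) * NADH + KB(14) * AACoA;
        r[14] = den == 0 ? 0 : V(14) * AACoA * NADH / den;
        r[15] = V(15) * (Buty / (KA(15) + Buty)) * (AACoA / (KB(15) + AACoA));
        r[16] = mm(V(16), KA(16), AcAc);
        den = KA(17) * Buty + KA(17) * KB(17) + Buty * Buty;
        r[17] = den == 0 ? 0 : V(17) * Buty * Buty / den;
        r[18] = mm(V(18), KA(18), BCoA);
        den = KA(19) * BCoA + KB(19) * NADH + BCoA * NADH * (1 + BuOH / KC(19));
        r[19] = den == 0 ? 0 : V(19) * BCoA * NADH / den;
    }

    X = s[6];

    ydot[0]  = -r[1];                                        /* G     */
    ydot[1]  = r[1] - r[2];                                  /* F6P   */
    ydot[2]  = 2 * r[2] - r[3];                              /* G3P   */
    ydot[3]  = r[3] + r[4] - r[5] - r[6];                    /* Pyr   */
    ydot[4]  = -r[4] + r[5];                                 /* Lac   */
    ydot[5]  = r[6] + r[7] + r[8] - r[9] - 2 * r[10] - r[11] - r[12];
    ydot[6]  = r[12] - r[13];                                /* X     */
    ydot[7]  = -r[7] - r[8] + r[9];                          /* Ac    */
    ydot[8]  = r[11];                                        /* EtOH  */
    ydot[9]  = -r[8] + r[10] - r[14] - r[15];                /* AACoA */
    ydot[10] = r[8] + r[15] - r[16];                         /* AcAc  */
    ydot[11] = r[14] + r[15] + r[17] - r[18] - r[19];        /* BCoA  */
    ydot[12] = -r[15] - r[17] + r[18];                       /* Buty  */
    ydot[13] = r[16];                                        /* An    */
    ydot[14] = r[19];                                        /* BuOH  */
    ydot[15] = r[3] - 2 * r[11] - 2 * r[14] - 2 * r[19];     /* NADH  */

    for (i = 0; i < 16; i++)
        ydot[i] *= X;

    if (p[76] != 0)
        ydot[15] = 0;
}

static const R_CMethodDef cMethods[] = {
    {"abe_init",   (DL_FUNC) &abe_init,   1},
    {"abe_derivs", (DL_FUNC) &abe_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_abekin(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
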