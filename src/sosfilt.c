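#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Cascade of biquad sections (direct form II transposed) applied down the
   columns of a numeric matrix. sos is nsec x 6: b0 b1 b2 a0 a1 a2 with
   a0 == 1. Returns a new matrix. */
SEXP C_sosfilt(SEXP x, SEXP sos)
{
    if (!isReal(x) || !isReal(sos))
        error("inputs must be numeric");
    SEXP dimx = getAttrib(x, R_DimSymbol);
    if (isNull(dimx) || LENGTH(dimx) != 2)
        error("x must be a matrix");
    int n = INTEGER(dimx)[0], m = INTEGER(dimx)[1];
    SEXP dims = getAttrib(sos, R_DimSymbol);
    if (isNull(dims) || LENGTH(dims) != 2 || INTEGER(dims)[1] != 6)
        error("sos must be an nsec x 6 matrix");
    int nsec = INTEGER(dims)[0];
    const double *s = REAL(sos);

    SEXP out = PROTECT(allocMatrix(REALSXP, n, m));
    double *y = REAL(out);
    const double *xin = REAL(x);
    memcpy(y, xin, (size_t) n * m * sizeof(double));

    for (int j = 0; j < m; j++) {
        double *col = y + (size_t) j * n;
        for (int k = 0; k < nsec; k++) {
            double b0 = s[k], b1 = s[k + nsec], b2 = s[k + 2 * nsec];
            double a1 = s[k + 4 * nsec], a2 = s[k + 5 * nsec];
            double z1 = 0.0, z2 = 0.0;
            for (int i = 0; i < n; i++) {
                double xi = col[i];
                double yi = b0 * xi + z1;
                z1 = b1 * xi - a1 * yi + z2;
                z2 = b2 * xi - a2 * yi;
                col[i] = yi;
            }
        }
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_sosfilt", (DL_FUNC) &C_sosfilt, 2},
    {NULL, NULL, 0}
};

void R_init_hybridbci(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
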