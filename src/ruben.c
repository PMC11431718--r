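/* Series coefficients for Ruben's mixture representation of a positive
 * quadratic form in normal variables: cc[k] = (1/(2k)) sum_m b[m] cc[k-m].
 * O(N^2); N can reach ~16k for strongly spread spectra. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP ruben_coef_c(SEXP b_, SEXP n_)
{
    int n = INTEGER(n_)[0];
    double *b = REAL(b_);
    SEXP cc_ = PROTECT(allocVector(REALSXP, n + 1));
    double *cc = REAL(cc_);
    cc[0] = 1.0;
    for (int k = 1; k <= n; k++) {
        double s = 0.0;
        for (int m = 1; m <= k; m++)
            s += b[m - 1] * cc[k - m];
        cc[k] = s / (2.0 * k);
    }
    UNPROTECT(1);
    return cc_;
}

static const R_CallMethodDef call_methods[] = {
    {"ruben_coef_c", (DL_FUNC) &ruben_coef_c, 2},
    {NULL, NULL, 0}
};

void R_init_taucor(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
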