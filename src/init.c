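#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_write(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_h5_read(SEXP, SEXP);
SEXP C_h5_exists(SEXP, SEXP);
SEXP C_h5_read_attr(SEXP, SEXP);
SEXP C_im2col(SEXP, SEXP, SEXP);
SEXP C_col2im(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_lstm_forward(SEXP, SEXP);
SEXP C_lstm_backward(SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_h5_write",      (DL_FUNC) &C_h5_write,      5},
    {"C_h5_read",       (DL_FUNC) &C_h5_read,       2},
    {"C_h5_exists",     (DL_FUNC) &C_h5_exists,     2},
    {"C_h5_read_attr",  (DL_FUNC) &C_h5_read_attr,  2},
    {"C_im2col",        (DL_FUNC) &C_im2col,        3},
    {"C_col2im",        (DL_FUNC) &C_col2im,        5},
    {"C_lstm_forward",  (DL_FUNC) &C_lstm_forward,  2},
    {"C_lstm_backward", (DL_FUNC) &C_lstm_backward, 3},
    {NULL, NULL, 0}
};

void R_init_seq2cov(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
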