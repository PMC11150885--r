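/* Hot inner loops of the network layers: im2col/col2im gather-scatter for
 * (transposed) convolutions and the LSTM time loops. Matrix products stay
 * in BLAS (dgemm); everything here is index bookkeeping R does slowly.
 * Layouts match the R side exactly: arrays are column-major, activations
 * are (B, L, C), the im2col matrix is (B*L_out) x (kernel*C) with batch
 * fastest in rows and kernel position fastest in columns.
 */

#include <string.h>
#include <math.h>

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif

static double sigm(double v) { return 1.0 / (1.0 + exp(-v)); }

/* x: (B, L, C); idx: integer (L_out, k), 1-based positions in the padded
 * axis; pad_left: scalar. Returns M: (B*L_out, k*C). */
SEXP C_im2col(SEXP x, SEXP idx, SEXP pad_left)
{
    SEXP dim = Rf_getAttrib(x, R_DimSymbol);
    const int B = INTEGER(dim)[0], L = INTEGER(dim)[1], C = INTEGER(dim)[2];
    SEXP idim = Rf_getAttrib(idx, R_DimSymbol);
    const int Lout = INTEGER(idim)[0], k = INTEGER(idim)[1];
    const int pl = Rf_asInteger(pad_left);
    const double *xp = REAL(x);
    const int *ix = INTEGER(idx);

    SEXP M = PROTECT(Rf_allocMatrix(REALSXP, (R_xlen_t) B * Lout,
                                    (R_xlen_t) k * C));
    double *mp = REAL(M);
    memset(mp, 0, (size_t) B * Lout * k * C * sizeof(double));
    for (int c = 0; c < C; c++) {
        for (int j = 0; j < k; j++) {
            double *dst0 = mp + (size_t) B * Lout * (j + (size_t) k * c);
            for (int o = 0; o < Lout; o++) {
                int p = ix[o + (size_t) Lout * j] - 1 - pl;
                if (p >= 0 && p < L) {
                    memcpy(dst0 + (size_t) B * o,
                           xp + (size_t) B * p + (size_t) B * L * c,
                           B * sizeof(double));
                }
            }
        }
    }
    UNPROTECT(1);
    return M;
}

/* Adjoint of C_im2col: scatter-add M (B*L_out, k*C) back to (B, L, C). */
SEXP C_col2im(SEXP M, SEXP idx, SEXP pad_left, SEXP L_, SEXP B_)
{
    SEXP idim = Rf_getAttrib(idx, R_DimSymbol);
    const int Lout = INTEGER(idim)[0], k = INTEGER(idim)[1];
    const int pl = Rf_asInteger(pad_left);
    const int L = Rf_asInteger(L_), B = Rf_asInteger(B_);
    const int C = (int) (Rf_ncols(M) / k);
    const double *mp = REAL(M);
    const int *ix = INTEGER(idx);

    SEXP out = PROTECT(Rf_alloc3DArray(REALSXP, B, L, C));
    double *xp = REAL(out);
    memset(xp, 0, (size_t) B * L * C * sizeof(double));
    for (int c = 0; c < C; c++) {
        for (int j = 0; j < k; j++) {
            const double *src0 = mp + (size_t) B * Lout *
                (j + (size_t) k * c);
            for (int o = 0; o < Lout; o++) {
                int p = ix[o + (size_t) Lout * j] - 1 - pl;
                if (p >= 0 && p < L) {
                    double *dst = xp + (size_t) B * p + (size_t) B * L * c;
                    const double *src = src0 + (size_t) B * o;
                    for (int b = 0; b < B; b++) dst[b] += src[b];
                }
            }
        }
    }
    UNPROTECT(1);
    return out;
}

/* LSTM forward over T steps. Ax: (B, T, 4U) holding x_t * Wx + b already;
 * Wh: (U, 4U). Gate order i, f, g, o. Returns y and the gate caches the
 * backward pass needs. */
SEXP C_lstm_forward(SEXP Ax, SEXP Wh)
{
    SEXP dim = Rf_getAttrib(Ax, R_DimSymbol);
    const int B = INTEGER(dim)[0], T = INTEGER(dim)[1];
    const int U4 = INTEGER(dim)[2], U = U4 / 4;
    const double *axp = REAL(Ax);
    const double *whp = REAL(Wh);

    SEXP y = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP gi = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP gf = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP gg = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP go = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP tc = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    SEXP cs = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U));
    double *yp = REAL(y), *gip = REAL(gi), *gfp = REAL(gf);
    double *ggp = REAL(gg), *gop = REAL(go), *tcp = REAL(tc);
    double *csp = REAL(cs);

    double *h = (double *) R_alloc((size_t) B * U, sizeof(double));
    double *cc = (double *) R_alloc((size_t) B * U, sizeof(double));
    double *A = (double *) R_alloc((size_t) B * U4, sizeof(double));
    memset(h, 0, (size_t) B * U * sizeof(double));
    memset(cc, 0, (size_t) B * U * sizeof(double));
    const double one = 1.0;

    for (int t = 0; t < T; t++) {
        for (int q = 0; q < U4; q++) {
            memcpy(A + (size_t) B * q,
                   axp + (size_t) B * t + (size_t) B * T * q,
                   B * sizeof(double));
        }
        /* A += h %*% Wh */
        F77_CALL(dgemm)("N", "N", &B, (int *) &U4, (int *) &U, &one,
                        h, &B, whp, (int *) &U, &one, A, &B
                        FCONE FCONE);
        for (int q = 0; q < U; q++) {
            for (int b = 0; b < B; b++) {
                const size_t bq = b + (size_t) B * q;
                const size_t btq = b + (size_t) B * t + (size_t) B * T * q;
                double ii = sigm(A[bq]);
                double ff = sigm(A[bq + (size_t) B * U]);
                double gv = tanh(A[bq + 2 * (size_t) B * U]);
                double oo = sigm(A[bq + 3 * (size_t) B * U]);
                double cn = ff * cc[bq] + ii * gv;
                double tv = tanh(cn);
                cc[bq] = cn;
                h[bq] = oo * tv;
                gip[btq] = ii; gfp[btq] = ff; ggp[btq] = gv; gop[btq] = oo;
                tcp[btq] = tv; csp[btq] = cn;
                yp[btq] = h[bq];
            }
        }
    }
    SEXP out = PROTECT(Rf_allocVector(VECSXP, 7));
    SET_VECTOR_ELT(out, 0, y);
    SET_VECTOR_ELT(out, 1, gi);
    SET_VECTOR_ELT(out, 2, gf);
    SET_VECTOR_ELT(out, 3, gg);
    SET_VECTOR_ELT(out, 4, go);
    SET_VECTOR_ELT(out, 5, tc);
    SET_VECTOR_ELT(out, 6, cs);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 7));
    const char *names[] = {"y", "i", "f", "g", "o", "tc", "c"};
    for (int i = 0; i < 7; i++) SET_STRING_ELT(nm, i, Rf_mkChar(names[i]));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(9);
    return out;
}

/* LSTM backward. dy: (B, T, U); fw: the list from C_lstm_forward;
 * Wh: (U, 4U). Returns dA (B, T, 4U) — gradients of the pre-activation
 * gate inputs, from which the caller derives dWx, db and dx — plus dWh. */
SEXP C_lstm_backward(SEXP dy, SEXP fw, SEXP Wh)
{
    SEXP dim = Rf_getAttrib(dy, R_DimSymbol);
    const int B = INTEGER(dim)[0], T = INTEGER(dim)[1];
    const int U = INTEGER(dim)[2], U4 = 4 * U;
    const double *dyp = REAL(dy);
    const double *yp = REAL(VECTOR_ELT(fw, 0));
    const double *gip = REAL(VECTOR_ELT(fw, 1));
    const double *gfp = REAL(VECTOR_ELT(fw, 2));
    const double *ggp = REAL(VECTOR_ELT(fw, 3));
    const double *gop = REAL(VECTOR_ELT(fw, 4));
    const double *tcp = REAL(VECTOR_ELT(fw, 5));
    const double *csp = REAL(VECTOR_ELT(fw, 6));
    const double *whp = REAL(Wh);

    SEXP dA_all = PROTECT(Rf_alloc3DArray(REALSXP, B, T, U4));
    SEXP dWh = PROTECT(Rf_allocMatrix(REALSXP, U, U4));
    double *dap = REAL(dA_all), *dwhp = REAL(dWh);
    memset(dwhp, 0, (size_t) U * U4 * sizeof(double));

    double *dh = (double *) R_alloc((size_t) B * U, sizeof(double));
    double *dc = (double *) R_alloc((size_t) B * U, sizeof(double));
    double *dA = (double *) R_alloc((size_t) B * U4, sizeof(double));
    memset(dh, 0, (size_t) B * U * sizeof(double));
    memset(dc, 0, (size_t) B * U * sizeof(double));
    const double one = 1.0, zero = 0.0;

    for (int t = T - 1; t >= 0; t--) {
        for (int q = 0; q < U; q++) {
            for (int b = 0; b < B; b++) {
                const size_t bq = b + (size_t) B * q;
                const size_t btq = b + (size_t) B * t + (size_t) B * T * q;
                double dhv = dh[bq] + dyp[btq];
                double tv = tcp[btq], oo = gop[btq], ii = gip[btq];
                double ff = gfp[btq], gv = ggp[btq];
                double cprev = (t > 0)
                    ? csp[b + (size_t) B * (t - 1) + (size_t) B * T * q]
                    : 0.0;
                double dov = dhv * tv;
                double dcv = dc[bq] + dhv * oo * (1.0 - tv * tv);
                dA[bq] = dcv * gv * ii * (1.0 - ii);
                dA[bq + (size_t) B * U] = dcv * cprev * ff * (1.0 - ff);
                dA[bq + 2 * (size_t) B * U] = dcv * ii * (1.0 - gv * gv);
                dA[bq + 3 * (size_t) B * U] = dov * oo * (1.0 - oo);
                dc[bq] = dcv * ff;
            }
        }
        if (t > 0) {
            /* dWh += h_prev^T %*% dA with h_prev = y[, t-1, ] */
            double *hprev = (double *) R_alloc((size_t) B * U,
                                               sizeof(double));
            for (int q = 0; q < U; q++) {
                memcpy(hprev + (size_t) B * q,
                       yp + (size_t) B * (t - 1) + (size_t) B * T * q,
                       B * sizeof(double));
            }
            F77_CALL(dgemm)("T", "N", (int *) &U, (int *) &U4, (int *) &B,
                            &one, hprev, (int *) &B, dA, (int *) &B, &one,
                            dwhp, (int *) &U FCONE FCONE);
        }
        /* dh = dA %*% Wh^T */
        F77_CALL(dgemm)("N", "T", (int *) &B, (int *) &U, (int *) &U4,
                        &one, dA, (int *) &B, whp, (int *) &U, &zero,
                        dh, (int *) &B FCONE FCONE);
        for (int q = 0; q < U4; q++) {
            memcpy(dap + (size_t) B * t + (size_t) B * T * q,
                   dA + (size_t) B * q, B * sizeof(double));
        }
    }
    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dA_all);
    SET_VECTOR_ELT(out, 1, dWh);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, Rf_mkChar("dA"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("dWh"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}
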