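// Call glue for the exported C++ kernels

#include <Rcpp.h>
using namespace Rcpp;

NumericMatrix fmm_solve_cpp(LogicalMatrix blocked, double h, double v, int init_col, int order);
RcppExport SEXP _frontobstacles_fmm_solve_cpp(SEXP blockedSEXP, SEXP hSEXP, SEXP vSEXP, SEXP init_colSEXP, SEXP orderSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< LogicalMatrix >::type blocked(blockedSEXP);
    Rcpp::traits::input_parameter< double >::type h(hSEXP);
    Rcpp::traits::input_parameter< double >::type v(vSEXP);
    Rcpp::traits::input_parameter< int >::type init_col(init_colSEXP);
    Rcpp::traits::input_parameter< int >::type order(orderSEXP);
    rcpp_result_gen = Rcpp::wrap(fmm_solve_cpp(blocked, h, v, init_col, order));
    return rcpp_result_gen;
END_RCPP
}

NumericVector fkpp_rhs_cpp(NumericVector u, NumericVector kmap, double D, double h, int nx, int ny, int n_clamp_lo, int n_clamp_hi);
RcppExport SEXP _frontobstacles_fkpp_rhs_cpp(SEXP uSEXP, SEXP kmapSEXP, SEXP DSEXP, SEXP hSEXP, SEXP nxSEXP, SEXP nySEXP, SEXP n_clamp_loSEXP, SEXP n_clamp_hiSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< NumericVector >::type u(uSEXP);
    Rcpp::traits::input_parameter< NumericVector >::type kmap(kmapSEXP);
    Rcpp::traits::input_parameter< double >::type D(DSEXP);
    Rcpp::traits::input_parameter< double >::type h(hSEXP);
    Rcpp::traits::input_parameter< int >::type nx(nxSEXP);
    Rcpp::traits::input_parameter< int >::type ny(nySEXP);
    Rcpp::traits::input_parameter< int >::type n_clamp_lo(n_clamp_loSEXP);
    Rcpp::traits::input_parameter< int >::type n_clamp_hi(n_clamp_hiSEXP);
    rcpp_result_gen = Rcpp::wrap(fkpp_rhs_cpp(u, kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi));
    return rcpp_result_gen;
END_RCPP
}

NumericMatrix nine_point_lap_cpp(NumericMatrix u, double h);
RcppExport SEXP _frontobstacles_nine_point_lap_cpp(SEXP uSEXP, SEXP hSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< NumericMatrix >::type u(uSEXP);
    Rcpp::traits::input_parameter< double >::type h(hSEXP);
    rcpp_result_gen = Rcpp::wrap(nine_point_lap_cpp(u, h));
    return rcpp_result_gen;
END_RCPP
}

List eden_run_cpp(IntegerVector init_state, int nrow, int ncol, int stop_row, int max_events);
RcppExport SEXP _frontobstacles_eden_run_cpp(SEXP init_stateSEXP, SEXP nrowSEXP, SEXP ncolSEXP, SEXP stop_rowSEXP, SEXP max_eventsSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::RNGScope rcpp_rngScope_gen;
    Rcpp::traits::input_parameter< IntegerVector >::type init_state(init_stateSEXP);
    Rcpp::traits::input_parameter< int >::type nrow(nrowSEXP);
    Rcpp::traits::input_parameter< int >::type ncol(ncolSEXP);
    Rcpp::traits::input_parameter< int >::type stop_row(stop_rowSEXP);
    Rcpp::traits::input_parameter< int >::type max_events(max_eventsSEXP);
    rcpp_result_gen = Rcpp::wrap(eden_run_cpp(init_state, nrow, ncol, stop_row, max_events));
    return rcpp_result_gen;
END_RCPP
}

void fkpp_set_ctx(NumericVector kmap, double D, double h, int nx, int ny, int n_clamp_lo, int n_clamp_hi);
RcppExport SEXP _frontobstacles_fkpp_set_ctx(SEXP kmapSEXP, SEXP DSEXP, SEXP hSEXP, SEXP nxSEXP, SEXP nySEXP, SEXP n_clamp_loSEXP, SEXP n_clamp_hiSEXP) {
BEGIN_RCPP
    Rcpp::traits::input_parameter< NumericVector >::type kmap(kmapSEXP);
    Rcpp::traits::input_parameter< double >::type D(DSEXP);
    Rcpp::traits::input_parameter< double >::type h(hSEXP);
    Rcpp::traits::input_parameter< int >::type nx(nxSEXP);
    Rcpp::traits::input_parameter< int >::type ny(nySEXP);
    Rcpp::traits::input_parameter< int >::type n_clamp_lo(n_clamp_loSEXP);
    Rcpp::traits::input_parameter< int >::type n_clamp_hi(n_clamp_hiSEXP);
    fkpp_set_ctx(kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi);
    return R_NilValue;
END_RCPP
}

extern "C" void fkpp_deriv_c(int* neq, double* t, double* y, double* ydot, double* yout, int* ip);

static const R_CMethodDef CEntries[] = {
    {"fkpp_deriv_c", (DL_FUNC) &fkpp_deriv_c, 6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
    {"_frontobstacles_fmm_solve_cpp", (DL_FUNC) &_frontobstacles_fmm_solve_cpp, 5},
    {"_frontobstacles_fkpp_rhs_cpp", (DL_FUNC) &_frontobstacles_fkpp_rhs_cpp, 8},
    {"_frontobstacles_nine_point_lap_cpp", (DL_FUNC) &_frontobstacles_nine_point_lap_cpp, 2},
    {"_frontobstacles_eden_run_cpp", (DL_FUNC) &_frontobstacles_eden_run_cpp, 5},
    {"_frontobstacles_fkpp_set_ctx", (DL_FUNC) &_frontobstacles_fkpp_set_ctx, 7},
    {NULL, NULL, 0}
};

RcppExport void R_init_frontobstacles(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
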