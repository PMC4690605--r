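# .Call glue for the exported C++ kernels

fmm_solve_cpp <- function(blocked, h, v, init_col, order) {
    .Call(`_frontobstacles_fmm_solve_cpp`, blocked, h, v, init_col, order)
}

fkpp_rhs_cpp <- function(u, kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi) {
    .Call(`_frontobstacles_fkpp_rhs_cpp`, u, kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi)
}

nine_point_lap_cpp <- function(u, h) {
    .Call(`_frontobstacles_nine_point_lap_cpp`, u, h)
}

fkpp_set_ctx <- function(kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi) {
    invisible(.Call(`_frontobstacles_fkpp_set_ctx`, kmap, D, h, nx, ny, n_clamp_lo, n_clamp_hi))
}

eden_run_cpp <- function(init_state, nrow, ncol, stop_row, max_events) {
    .Call(`_frontobstacles_eden_run_cpp`, init_state, nrow, ncol, stop_row, max_events)
}
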