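# Independent re-statement of the equation of state, written out directly
# from its printed form; kept separate from the package routine so tests
# compare two implementations.
eq1_oracle <- function(lam, E, beta) {
  (E / 9) * (lam^2 - 1 / lam) *
    (1 + 2 * (1 - beta * (lam^2 + 2 / lam) / 3)^(-2))
}

eq2_oracle <- function(E, beta) (E / 3) * (1 + 2 / (1 - beta)^2)

# Parameter grid used by several property suites.
param_grid <- expand.grid(E = c(1, 5, 20), beta = c(0.05, 0.12, 0.24, 0.31))

# A hand-built segmented-cycles object for metric edge cases.
make_cycles <- function(A1_down, A1_up, A2_down, A2_up,
                        load1 = 1, load2 = 1, P1 = 1, P2 = 1) {
  mk <- function(Ad, Au, load, P, t0) list(
    time = c(t0, t0 + load, t0 + load + 1), force = c(0, P, 0),
    peak_index = 2L, t_start = t0, t_peak = t0 + load,
    t_end = t0 + load + 1, peak_force = P, A_down = Ad, A_up = Au)
  structure(list(mk(A1_down, A1_up, load1, P1, 0),
                 mk(A2_down, A2_up, load2, P2, 10)),
            baseline = 0, class = "bb_tpa_cycles")
}
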