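# shared fixtures: everything is generated in code, no stored data

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)

# truth vector aligned with estimate_all() output names
truth_from_params <- function(p) {
  c(g = p$lamT - p$d_T, lamT = p$lamT, d_T = p$d_T, mu1 = p$mu1,
    lam1 = p$lam1, lam2 = p$lam2, lamE = p$lamE, K_E1 = p$K_E1,
    K_E2 = p$K_E2, lamG = p$lamG, eta1 = p$eta1, eta2 = p$eta2)
}

# closed-form solution of du/dt = P - d u, used as an independent oracle
lin_closed <- function(u0, P, d, t) P / d + (u0 - P / d) * exp(-d * t)

# uniform-field initial state for oracle comparisons
uniform_fields <- function(grid, values) {
  n <- grid$N + 1L
  structure(matrix(rep(values, each = n), ncol = 5,
                   dimnames = list(NULL, c("I27", "I10", "E", "G", "T"))),
            class = "il27_fields", time = 0)
}
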