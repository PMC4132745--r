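# canonical parameter sets used across tests
std_wlc <- function() wlc_params(P_ds = 50, B_ds = 0.34, S_ds = 1200)
std_binding <- function() binding_params(K_D = 2.3, omega = 23, n = 26)
std_endpoints <- function() list(P_D = 50, P_L = 8, B_D = 0.34, B_L = 0.40,
                                 F_ov_D = 62, F_ov_L = 68)
std_conc_grid <- function() c(0, 0.02, 0.05, 0.2, 0.5, 1, 2, 5, 20)

# independent bisection oracle for the cooperative isotherm, written directly
# from the fixed-point form Theta = RHS(Theta); used to cross-check the
# package's closed-form-inversion solver
mvh_bisect_oracle <- function(c_nM, K_D, omega, n, tol = 1e-12) {
  rhs <- function(th) {
    if (th == 0) return(0)
    R <- sqrt((1 - (n + 1) * th / n)^2 + 4 * omega * th * (1 - th) / n)
    br1 <- if (n == 1) 1 else
      (((2 * omega - 1) * (1 - th) + th / n - R) / (2 * (omega - 1) * (1 - th)))^(n - 1)
    br2 <- ((1 - (n + 1) * th / n + R) / (2 * (1 - th)))^2
    (c_nM * n / K_D) * (1 - th) * br1 * br2
  }
  lo <- 0; hi <- 1 - 1e-9
  # g(th) = th - rhs(th): negative at 0+ (rhs > 0), positive near saturation
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid - rhs(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
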