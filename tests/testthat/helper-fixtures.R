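# Shared fixtures: scenario presets are loaded once; small builders keep
# individual tests terse.

cb1 <- buildScenario("CB1")
cb4 <- buildScenario("CB4")            # derived P_0 (default)
cb4_table <- buildScenario("CB4", p0_source = "table")
cbiw <- buildScenario("CBIW")

# trapezoid quadrature of a function on [0, t_f] -- independent oracle for
# the closed-form cell-time integrals
trapezoid <- function(f, t_f, n = 1e4) {
  t <- seq(0, t_f, length.out = n + 1)
  y <- f(t)
  sum((y[-1] + y[-length(y)]) / 2 * diff(t))
}

# a scenario with a perfectly balanced carbon budget (nothing consumed)
balanced_scenario <- function(N = 1e6) {
  scenarioDefinition(name = "balanced", N_f = N, P_0 = 1e12, D_0 = 1e11,
                     P_f = 1e12, D_f = 1e11, alpha_D = 10, mu_max = 0.01)
}

# quick simulateBrine wrapper with loose output grid
sim <- function(p, init, t_f_days, n_out = 201L, ...) {
  simulateBrine(p, init, t_f_days = t_f_days, n_out = n_out, ...)
}
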