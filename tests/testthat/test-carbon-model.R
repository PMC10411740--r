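# ODE carbon-cycle model: process terms, conservation, closed-form limits
# and event handling.

p_base <- modelParameters(mu_max = 0.06, m = 0.2, gamma_cell = 0.01,
                          alpha_D = 15.7, K_D = 8.82e5, N_max = 1e9)

test_that("growth term has the Monod and logistic limits", {
  p <- p_base
  # saturation: D >> K_D, N << N_max -> growth ~ mu_max * N
  s <- c(N = 1e4, P = 0, D = 1e6 * p$K_D, I = 0)
  expect_equal(growthTerm(s, p), p$mu_max * 1e4, tolerance = 1e-4)
  # half-velocity: D = K_D halves the specific rate
  s <- c(N = 1e4, P = 0, D = p$K_D, I = 0)
  expect_equal(growthTerm(s, p),
               p$mu_max * 1e4 / 2 * (1 - 1e4 / p$N_max))
  # carrying capacity stops growth
  s <- c(N = p$N_max, P = 0, D = 1e12, I = 0)
  expect_equal(growthTerm(s, p), 0)
  # no substrate, no growth
  s <- c(N = 1e4, P = 0, D = 0, I = 0)
  expect_equal(growthTerm(s, p), 0)
})

test_that("starvation death counts the cells whose demand exceeds DOC", {
  p <- modelParameters(mu_max = 0, m = 1, gamma_cell = 0, alpha_D = 10)
  expect_identical(starvationDeath(c(N = 10, P = 0, D = 20, I = 0), p), 0)
  expect_equal(starvationDeath(c(N = 10, P = 0, D = 0, I = 0), p), 10)
  expect_equal(starvationDeath(c(N = 10, P = 0, D = 4, I = 0), p), 6)
  # clamped: cannot kill more cells than exist
  expect_equal(starvationDeath(c(N = 10, P = 0, D = -5, I = 0), p), 10)
  p0 <- modelParameters(mu_max = 0, m = 0, gamma_cell = 0, alpha_D = 10)
  expect_identical(starvationDeath(c(N = 10, P = 0, D = 20, I = 0), p0), 0)
})

test_that("hydrolysis flux never exceeds the remaining POC", {
  p <- modelParameters(mu_max = 0, m = 0, gamma_cell = 0.012, alpha_D = 10)
  expect_identical(eeaFlux(c(N = 1e7, P = 0, D = 0, I = 0), p), 0)
  expect_equal(eeaFlux(c(N = 1e7, P = 1e9, D = 0, I = 0), p), 0.012 * 1e7)
  expect_equal(eeaFlux(c(N = 1e7, P = 1e4, D = 0, I = 0), p), 1e4)
})

test_that("derivatives conserve total carbon algebraically", {
  set.seed(42)
  for (i in 1:50) {
    p <- modelParameters(mu_max = runif(1, 0, 1), m = runif(1, 0, 2),
                         gamma_cell = runif(1, 0, 1),
                         alpha_D = runif(1, 1, 100),
                         K_D = 10^runif(1, 3, 7),
                         N_max = 10^runif(1, 7, 10),
                         I_xr = sample(c(0, runif(1, 0, 10)), 1))
    s <- c(N = 10^runif(1, 0, 9), P = 10^runif(1, 0, 13),
           D = 10^runif(1, 0, 12), I = 10^runif(1, 0, 10))
    d <- carbonDerivatives(0, s, p)[[1]]
    # alpha_I = 0: d(P + D + I + alpha_D N)/dt = 0 identically, up to
    # floating-point cancellation on the individual flux scale
    flux_scale <- max(1, abs(d[2]), abs(d[3]), abs(d[4]),
                      p$alpha_D * abs(d[1]))
    expect_lt(abs(d[2] + d[3] + d[4] + p$alpha_D * d[1]) / flux_scale,
              1e-12)
  }
})

test_that("derivatives handle exhausted pools", {
  p <- modelParameters(mu_max = 0.06, m = 0.2, gamma_cell = 0.01,
                       alpha_D = 15.7)
  # no DOC and no POC: every cell starves, biomass returns to DOC
  d <- carbonDerivatives(0, c(N = 1e6, P = 0, D = 0, I = 0), p)[[1]]
  expect_equal(d[1], -1e6)
  expect_equal(d[3], 15.7 * 1e6)
  # DIC fixation contributes nothing when the DIC pool is empty
  p_fix <- modelParameters(mu_max = 0, m = 0, gamma_cell = 0,
                           alpha_D = 10, I_xr = 5)
  d0 <- carbonDerivatives(0, c(N = 0, P = 0, D = 0, I = 0), p_fix)[[1]]
  expect_equal(d0, c(0, 0, 0, 0))
})

test_that("simulation matches the exponential closed form", {
  # K_D -> 0, no metabolism, no hydrolysis, N << N_max, abundant DOC:
  # pure exponential growth
  p <- modelParameters(mu_max = 0.05, m = 0, gamma_cell = 0,
                       alpha_D = 15.7, K_D = 1e-6, N_max = 1e15)
  traj <- sim(p, c(N = 1e3, P = 0, D = 1e12, I = 0), t_f_days = 100)
  expect_equal(traj$N, 1e3 * exp(0.05 * traj$time), tolerance = 1e-5)
})

test_that("simulation matches the logistic closed form", {
  # D >> K_D and m = 0: logistic growth at rate mu_max
  mu <- 0.05; N0 <- 1e5; Nmax <- 1e8
  p <- modelParameters(mu_max = mu, m = 0, gamma_cell = 0,
                       alpha_D = 15.7, K_D = 1e-6, N_max = Nmax)
  traj <- sim(p, c(N = N0, P = 0, D = 1e14, I = 0), t_f_days = 300)
  analytic <- Nmax / (1 + (Nmax / N0 - 1) * exp(-mu * traj$time))
  expect_equal(traj$N, analytic, tolerance = 1e-4)
})

test_that("a non-growing population drains its DOC and then declines", {
  p <- modelParameters(mu_max = 0, m = 1, gamma_cell = 0, alpha_D = 5)
  traj <- sim(p, c(N = 1e4, P = 0, D = 1e6, I = 0), t_f_days = 2000)
  # DOC is consumed down to a negligible residue and the population dies
  expect_lt(traj$D[nrow(traj)], 1e-4 * 1e6)
  expect_lt(traj$N[nrow(traj)], 1)
  # POC untouched without hydrolysis
  expect_true(all(traj$P == 0))
})

test_that("POC is non-increasing whenever hydrolysis is active", {
  p <- modelParameters(mu_max = 0.01, m = 0.1, gamma_cell = 0.5,
                       alpha_D = 15.7)
  traj <- sim(p, c(N = 1e6, P = 1e10, D = 1e9, I = 0), t_f_days = 5000)
  expect_true(all(diff(traj$P) <= 1e-6 * traj$P[1]))
})

test_that("mass balance holds through pulsed additions and random draws", {
  # no additions: relative drift below 1e-6
  p <- modelParameters(mu_max = 0.06, m = 0.2, gamma_cell = 0.8,
                       alpha_D = 15.7)
  traj <- sim(p, c(N = 1e5, P = 1.64e13, D = 3.41e10, I = 0),
              t_f_days = yearsToDays(40000))
  audit <- massBalanceAudit(traj)
  expect_lt(max(abs(audit$residual)), 1e-6)

  # a pulse shifts the uncorrected total by exactly the pulse size and
  # the corrected series stays flat
  p2 <- modelParameters(mu_max = 0.06, m = 0.2, gamma_cell = 0.8,
                        alpha_D = 15.7,
                        additions = data.frame(time = 500, D_in = 1e10,
                                               P_in = 5e9))
  traj2 <- sim(p2, c(N = 1e5, P = 1e12, D = 1e11, I = 0), t_f_days = 1000)
  audit2 <- massBalanceAudit(traj2)
  expect_lt(max(abs(audit2$residual)), 1e-6)
  raw <- attr(traj2, "raw")
  uncorrected <- raw$P + raw$D + raw$I + 15.7 * raw$N
  jump <- uncorrected[raw$time > 500][1] - uncorrected[1]
  expect_equal(jump, 1.5e10, tolerance = 1e-3)

  # seeded random-parameter property
  set.seed(11)
  for (i in 1:20) {
    pr <- modelParameters(mu_max = 10^runif(1, -7, 0),
                          m = 10^runif(1, -3, 1),
                          gamma_cell = 10^runif(1, -3, 1),
                          alpha_D = runif(1, 5, 100),
                          K_D = 10^runif(1, 3, 7),
                          N_max = 1e9)
    tr <- sim(pr, c(N = 10^runif(1, 3, 7), P = 10^runif(1, 10, 13),
                    D = 10^runif(1, 8, 12), I = 0),
              t_f_days = 10^runif(1, 2, 6), n_out = 51)
    expect_lt(max(abs(massBalanceAudit(tr)$residual)), 1e-6)
  }
})

test_that("budget estimator recovers the true metabolic rate", {
  # known constant m, DOC always saturating, no additions: applying the
  # budget-based rate with the numerically integrated cell-days recovers m
  m_true <- 0.15
  p <- modelParameters(mu_max = 3e-4, m = m_true, gamma_cell = 0.5,
                       alpha_D = 15.7, K_D = 1, N_max = 1e12)
  init <- c(N = 1e5, P = 1e13, D = 1e11, I = 0)
  traj <- sim(p, init, t_f_days = 20000, n_out = 2001)
  consumed <- (init[["P"]] + init[["D"]]) -
    (traj$P[nrow(traj)] + traj$D[nrow(traj)]) -
    p$alpha_D * (traj$N[nrow(traj)] - init[["N"]])
  cell_days <- sum((traj$N[-1] + traj$N[-nrow(traj)]) / 2 * diff(traj$time))
  expect_equal(consumed / cell_days, m_true, tolerance = 0.01)
})

test_that("pulsed additions jump the pools and rescue a collapsed population", {
  # population starves to (numerically) zero, then a large DOC pulse
  # arrives: the rescue rule re-seeds one viable cell which regrows
  p <- modelParameters(mu_max = 0.05, m = 1, gamma_cell = 0, alpha_D = 5,
                       K_D = 1e3, N_max = 1e9,
                       additions = data.frame(time = 3000, D_in = 1e10,
                                              P_in = 0))
  traj <- sim(p, c(N = 1e4, P = 0, D = 1e5, I = 0), t_f_days = 4000,
              n_out = 801)
  n_before <- traj$N[max(which(traj$time < 3000))]
  expect_lt(n_before, 1)
  # the re-seeded cell responds to the added DOC
  after <- traj[traj$time >= 3000, ]
  expect_gt(max(after$N), 100)
  expect_gt(max(after$D), 0.99e10)
})

test_that("simulateScenario seeds the brine from its surroundings", {
  tr <- simulateScenario(cbiw$scenario, cbiw$constants,
                         modelParameters(mu_max = 1e-7, m = 0.008,
                                         gamma_cell = 0.012,
                                         alpha_D = 15.7),
                         n_out = 101)
  expect_equal(tr$P[1], cbiw$scenario$P_0)
  expect_equal(tr$D[1], cbiw$scenario$D_0)
  expect_equal(tr$N[1], cbiw$constants$N_0)
  ev <- attr(tr, "events")
  expect_equal(ev$time, yearsToDays(29000))
  expect_equal(ev$D_in, 3.88e10)
})

test_that("invalid inputs are rejected before integration", {
  p <- p_base
  expect_error(simulateBrine(p, c(N = 1, P = 1, D = 1), 10), "init")
  expect_error(simulateBrine(p, c(N = -1, P = 1, D = 1, I = 0), 10),
               "non-negative")
  expect_error(modelParameters(mu_max = -1, m = 0, gamma_cell = 0,
                               alpha_D = 1), "non-negative")
  p_ev <- modelParameters(mu_max = 0.1, m = 0.1, gamma_cell = 0,
                          alpha_D = 1,
                          additions = data.frame(time = 100, D_in = 1,
                                                 P_in = 0))
  expect_error(simulateBrine(p_ev, c(N = 1, P = 1, D = 1, I = 0), 50),
               "strictly inside")
})
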