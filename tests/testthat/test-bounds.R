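# Closed-form energetic estimators: growth rates, carbon-budget rates,
# timespan inversion and conversions.

test_that("minimum growth rate connects the assumed start to the endpoint", {
  expect_equal(minimumGrowthRate(1e5, 5.70e6, 40000), 2.77e-7,
               tolerance = 0.005)
  expect_equal(minimumGrowthRate(1e5, 1.14e7, 40000), 3.24e-7,
               tolerance = 0.005)
  expect_equal(minimumGrowthRate(1e5, 1.39e8, 40000), 4.95e-7,
               tolerance = 0.005)
  expect_identical(minimumGrowthRate(1e5, 1e5, 40000), 0)
  expect_error(minimumGrowthRate(1e6, 1e5, 40000), "N_f < N_0")
})

test_that("doubling time inverts the growth rate", {
  expect_equal(doublingTime(2.77e-7), 6860, tolerance = 0.005)
  expect_equal(doublingTime(3.24e-7), 5850, tolerance = 0.005)
  expect_equal(doublingTime(log(2)), 1 / 365.25)
  expect_error(doublingTime(0), "positive")
})

test_that("cell-time integrals match their closed forms and quadrature", {
  t_f_days <- yearsToDays(40000)
  flat <- growthTrajectory("no_growth", N_f = 5.7e6, t_f_days = t_f_days)
  expect_equal(trajectoryCellTimeIntegral(flat), 5.7e6 * t_f_days)

  mu <- minimumGrowthRate(1e5, 5.7e6, 40000)
  expo <- growthTrajectory("exponential", N_0 = 1e5, N_f = 5.7e6,
                           t_f_days = t_f_days)
  expect_equal(expo$mu, mu)
  expect_equal(trajectoryCellTimeIntegral(expo), (5.7e6 - 1e5) / mu)

  # independent trapezoid quadrature oracle
  oracle <- trapezoid(function(t) 1e5 * exp(mu * t), t_f_days, n = 1e4)
  expect_equal(trajectoryCellTimeIntegral(expo), oracle, tolerance = 1e-6)

  # degenerate zero-rate exponential reduces to a constant at N_0
  degen <- growthTrajectory("exponential", N_0 = 2e5, N_f = 2e5,
                            t_f_days = 100)
  expect_equal(trajectoryCellTimeIntegral(degen), 2e5 * 100)

  expect_error(growthTrajectory("exponential", N_0 = 1e6, N_f = 1e5,
                                t_f_days = 10), "N_f >= N_0")
  expect_error(growthTrajectory("exponential", N_0 = 1e5, N_f = 1e6,
                                t_f_days = 10, mu = 1), "inconsistent")
})

test_that("metabolic-rate bounds reproduce the published estimates", {
  t_f_days <- yearsToDays(40000)
  flat1 <- growthTrajectory("no_growth", N_f = cb1$scenario$N_f,
                            t_f_days = t_f_days)
  exp1 <- growthTrajectory("exponential", N_0 = 1e5,
                           N_f = cb1$scenario$N_f, t_f_days = t_f_days)
  expect_equal(metabolicRate(cb1$scenario, flat1), 0.181, tolerance = 0.005)
  expect_equal(metabolicRate(cb1$scenario, exp1), 0.743, tolerance = 0.005)

  flatw <- growthTrajectory("no_growth", N_f = cbiw$scenario$N_f,
                            t_f_days = t_f_days)
  expw <- growthTrajectory("exponential", N_0 = 1e5,
                           N_f = cbiw$scenario$N_f, t_f_days = t_f_days)
  expect_equal(metabolicRate(cbiw$scenario, flatw), 0.008, tolerance = 0.01)
  expect_equal(metabolicRate(cbiw$scenario, expw), 0.057, tolerance = 0.01)

  # a balanced budget yields a zero rate
  bal <- balanced_scenario()
  flat_b <- growthTrajectory("no_growth", N_f = bal$N_f, t_f_days = 100)
  expect_identical(metabolicRate(bal, flat_b), 0)

  # an infeasible budget (more carbon now than at the start) errors
  rich <- scenarioDefinition("rich", N_f = 1e6, P_0 = 1e10, D_0 = 1e9,
                             P_f = 1e12, D_f = 1e11, alpha_D = 10,
                             mu_max = 0.01)
  expect_error(metabolicRate(rich, flat_b), "infeasible")
})

test_that("budget rates are linear in the consumed carbon", {
  t_f_days <- yearsToDays(40000)
  exp1 <- growthTrajectory("exponential", N_0 = 1e5, N_f = 5.7e6,
                           t_f_days = t_f_days)
  sc <- cb1$scenario
  # double every pool (and alpha_D) -> numerator doubles at fixed N terms
  sc2 <- sc
  for (f in c("P_0", "D_0", "P_f", "D_f", "alpha_D"))
    sc2[[f]] <- 2 * sc[[f]]
  expect_equal(metabolicRate(sc2, exp1), 2 * metabolicRate(sc, exp1))
  expect_equal(eeaRate(sc2, exp1), 2 * eeaRate(sc, exp1))
})

test_that("EEA-rate bounds reproduce the published estimates", {
  t_f_days <- yearsToDays(40000)
  exp1 <- growthTrajectory("exponential", N_0 = 1e5,
                           N_f = cb1$scenario$N_f, t_f_days = t_f_days)
  flat1 <- growthTrajectory("no_growth", N_f = cb1$scenario$N_f,
                            t_f_days = t_f_days)
  expect_equal(eeaRate(cb1$scenario, exp1), 0.802, tolerance = 0.005)
  expect_equal(eeaRate(cb1$scenario, flat1), 0.195, tolerance = 0.005)

  exp4 <- growthTrajectory("exponential", N_0 = 1e5,
                           N_f = cb4$scenario$N_f, t_f_days = t_f_days)
  expect_equal(eeaRate(cb4$scenario, exp4), 0.483, tolerance = 0.005)

  # untouched POC pool means no required hydrolysis
  bal <- balanced_scenario()
  expect_identical(eeaRate(bal, growthTrajectory("no_growth", N_f = bal$N_f,
                                                 t_f_days = 100)), 0)
})

test_that("timespan inversion matches the published predictions", {
  mu1 <- minimumGrowthRate(1e5, cb1$scenario$N_f, 40000)
  expect_equal(impliedTimespan(cb1$scenario, 1.22e-2, mu1, 1e5), 81200,
               tolerance = 0.005)
  muw <- minimumGrowthRate(1e5, cbiw$scenario$N_f, 40000)
  expect_equal(impliedTimespan(cbiw$scenario, 1.22e-2, muw, 1e5), 48700,
               tolerance = 0.005)
  mu4 <- minimumGrowthRate(1e5, cb4$scenario$N_f, 40000)
  expect_equal(impliedTimespan(cb4$scenario, 1.22e-2, mu4, 1e5), 71000,
               tolerance = 0.005)
})

test_that("timespan inversion is the exact algebraic inverse of the rate", {
  # gamma computed from the exponential trajectory over t* returns t*
  for (t_star in c(12000, 40000, 90000)) {
    t_days <- yearsToDays(t_star)
    mu <- minimumGrowthRate(1e5, cb1$scenario$N_f, 40000)
    N_f_star <- 1e5 * exp(mu * t_days)
    traj <- growthTrajectory("exponential", N_0 = 1e5, N_f = N_f_star,
                             t_f_days = t_days)
    gamma <- eeaRate(cb1$scenario, traj)
    expect_equal(impliedTimespan(cb1$scenario, gamma, mu, 1e5), t_star,
                 tolerance = 1e-9)
  }
})

test_that("metabolicBounds assembles a consistent Table-style result", {
  for (x in list(cb1, cb4, cbiw)) {
    b <- metabolicBounds(x$scenario, x$constants)
    expect_s3_class(b, "cryo_bounds")
    expect_lt(b$m_lower, b$m_upper)
    expect_lt(b$gamma_lower, b$gamma_upper)
    expect_gt(b$mu_min, 0)
    df <- as.data.frame(b)
    expect_identical(df$scenario, x$scenario$name)
  }
  # the ordering bound holds under perturbed inputs too
  for (sc in perturbTables(0.05, seed = 7)) {
    b <- metabolicBounds(sc, cb1$constants)
    expect_lt(b$m_lower, b$m_upper)
  }
})

test_that("carbon rates convert to plausible per-cell power", {
  expect_equal(wattsPerCell(0.743, 30), 0.743e-15 / 12.011 * 30e3 / 86400)
  expect_identical(wattsPerCell(0), 0)
  # order-of-magnitude window published for this system
  expect_equal(floor(log10(wattsPerCell(0.743))), -17)
  expect_equal(floor(log10(wattsPerCell(0.008))), -19)
})

test_that("C:N-based carbon consumption follows the molar arithmetic", {
  expect_equal(cnCarbonConsumption(1e-6, 1), 1.2011e10)
  expect_identical(cnCarbonConsumption(0, 15.8), 0)
  # millimolar-range ammonium (4.5 mM = 4.5e-6 mol N/mL) at the measured
  # sediment C:N lands on the e11 fg C/mL scale of the published
  # consistency check
  val <- cnCarbonConsumption(4.5e-6, 15.8)
  expect_gt(val, 1e11)
  expect_lt(val, 1e12)
})
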