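# Closed-form estimators of community energetics from endpoint
# measurements.  A closed brine contains a finite organic carbon budget;
# dividing the carbon consumed over the system lifetime by the cell-days
# lived gives a cell-specific metabolic rate.  Two bounding growth
# trajectories convert the unknown population history into bounds:
#
#   no growth   -- the population sat at N_f throughout, maximising
#                  cell-days and so minimising the per-cell rate;
#   exponential -- the slowest exponential connecting N_0 to N_f over the
#                  system age, minimising cell-days and so maximising it.

#' Bounding growth trajectory
#'
#' @param kind `"no_growth"` (constant density `N_f`) or `"exponential"`
#'   (the slowest exponential from `N_0` to `N_f` over `t_f_days`).
#' @param N_0 starting cell density, cells mL^-1 (exponential case).
#' @param N_f ending cell density, cells mL^-1.
#' @param t_f_days duration, days.
#' @param mu exponential rate, day^-1; computed from the endpoints when
#'   omitted, validated against them when supplied.
#' @return an object of class `cryo_trajectory_spec`.
#' @export
growthTrajectory <- function(kind = c("no_growth", "exponential"),
                             N_0 = NA_real_, N_f, t_f_days, mu = NULL) {
  kind <- match.arg(kind)
  stopifnot(N_f > 0, t_f_days > 0)
  if (kind == "exponential") {
    stopifnot(N_0 > 0)
    if (N_f < N_0)
      stop("exponential bounding trajectory needs N_f >= N_0", call. = FALSE)
    mu_implied <- log(N_f / N_0) / t_f_days
    if (is.null(mu)) {
      mu <- mu_implied
    } else if (mu_implied > 0 &&
               abs(mu - mu_implied) > 1e-9 * max(mu_implied, .Machine$double.eps)) {
      stop("supplied 'mu' is inconsistent with the trajectory endpoints",
           call. = FALSE)
    }
  } else {
    mu <- 0
  }
  structure(list(kind = kind, N_0 = N_0, N_f = N_f, t_f_days = t_f_days,
                 mu = mu),
            class = "cryo_trajectory_spec")
}

#' Minimum growth rate
#'
#' The slowest exponential rate connecting an assumed starting density to
#' the observed endpoint over the system age.
#'
#' @param N_0 starting cell density, cells mL^-1.
#' @param N_f observed ending cell density, cells mL^-1.
#' @param t_f_years system age, years.
#' @param days_per_year calendar conversion.
#' @return growth rate, day^-1.
#' @examples
#' minimumGrowthRate(1e5, 5.7e6, 40000)  # ~2.77e-7 /day
#' @export
minimumGrowthRate <- function(N_0, N_f, t_f_years, days_per_year = 365.25) {
  stopifnot(N_0 > 0, t_f_years > 0)
  if (N_f < N_0)
    stop("N_f < N_0: no exponential growth trajectory applies", call. = FALSE)
  log(N_f / N_0) / yearsToDays(t_f_years, days_per_year)
}

#' Doubling time of an exponential grower
#'
#' @param mu growth rate, day^-1.
#' @inheritParams minimumGrowthRate
#' @return doubling time, years.
#' @export
doublingTime <- function(mu, days_per_year = 365.25) {
  if (any(mu <= 0)) stop("'mu' must be positive", call. = FALSE)
  daysToYears(log(2) / mu, days_per_year)
}

#' Cell-days lived along a bounding trajectory
#'
#' The time integral of cell density, i.e. the denominator of the
#' budget-based rate estimators.  Closed forms: `N_f * t_f` for the
#' constant trajectory and `(N_f - N_0) / mu` for the exponential one
#' (degenerating to `N_0 * t_f` as `mu -> 0`).
#'
#' @param traj a [growthTrajectory()].
#' @return integral of N over time, cell day mL^-1.
#' @export
trajectoryCellTimeIntegral <- function(traj) {
  stopifnot(inherits(traj, "cryo_trajectory_spec"))
  if (traj$kind == "no_growth") return(traj$N_f * traj$t_f_days)
  if (traj$mu == 0) return(traj$N_0 * traj$t_f_days)
  (traj$N_f - traj$N_0) / traj$mu
}

.traj_n0 <- function(traj) if (traj$kind == "no_growth") traj$N_f else traj$N_0

#' Cell-specific metabolic rate from the carbon budget
#'
#' Total organic carbon consumed -- initial pools plus any pulsed
#' addition, minus what remains, minus the carbon locked into new
#' biomass -- divided by the cell-days lived along a bounding trajectory.
#' The rate covers every per-cell use of carbon except growth
#' (respiration, enzyme and polysaccharide production, turnover).
#'
#' @param scenario a [scenarioDefinition()].
#' @param traj a [growthTrajectory()].
#' @return cell-specific metabolic rate, fg C cell^-1 day^-1.
#' @export
metabolicRate <- function(scenario, traj) {
  stopifnot(inherits(scenario, "cryo_scenario"),
            inherits(traj, "cryo_trajectory_spec"))
  S0 <- scenario$P_0 + scenario$D_0
  Si <- scenario$P_in + scenario$D_in
  Sf <- scenario$P_f + scenario$D_f
  numer <- (S0 + Si) - Sf - scenario$alpha_D * (traj$N_f - .traj_n0(traj))
  if (numer < 0)
    stop("carbon budget infeasible: consumed carbon is negative",
         call. = FALSE)
  numer / trajectoryCellTimeIntegral(traj)
}

#' Cell-specific EEA rate from the POC budget
#'
#' Same construction as [metabolicRate()] but for the particulate pool
#' alone: the POC hydrolysed over the system lifetime divided by the
#' cell-days lived.
#'
#' @inheritParams metabolicRate
#' @return cell-specific extracellular enzyme activity rate,
#'   fg C cell^-1 day^-1.
#' @export
eeaRate <- function(scenario, traj) {
  stopifnot(inherits(scenario, "cryo_scenario"),
            inherits(traj, "cryo_trajectory_spec"))
  numer <- (scenario$P_0 + scenario$P_in) - scenario$P_f
  if (numer < 0)
    stop("POC budget infeasible: hydrolysed POC is negative", call. = FALSE)
  numer / trajectoryCellTimeIntegral(traj)
}

#' System timespan implied by a measured EEA rate
#'
#' Inverts the POC budget along the minimum-growth exponential
#' trajectory: solves `gamma * N_0 * (exp(mu t) - 1) / mu = deltaP` for
#' `t`, where `deltaP = (P_0 + P_in) - P_f`.  The growth rate is held at
#' the value fitted over the nominal system age; the inversion asks how
#' long the measured hydrolysis rate would need to supply the observed
#' POC drawdown.
#'
#' @inheritParams metabolicRate
#' @param gamma cell-specific EEA rate to invert, fg C cell^-1 day^-1.
#' @param mu exponential growth rate, day^-1.
#' @param N_0 starting cell density, cells mL^-1.
#' @param days_per_year calendar conversion.
#' @return implied timespan, years.
#' @export
impliedTimespan <- function(scenario, gamma, mu, N_0,
                            days_per_year = 365.25) {
  stopifnot(inherits(scenario, "cryo_scenario"), gamma > 0, mu > 0, N_0 > 0)
  deltaP <- (scenario$P_0 + scenario$P_in) - scenario$P_f
  if (deltaP <= 0)
    stop("POC drawdown must be positive to imply a timespan", call. = FALSE)
  t_days <- log1p(deltaP * mu / (gamma * N_0)) / mu
  daysToYears(t_days, days_per_year)
}

#' Convert a carbon-based metabolic rate to power per cell
#'
#' @param m cell-specific metabolic rate, fg C cell^-1 day^-1.
#' @param yield_kj_per_mol energetic yield of the metabolised carbon,
#'   kJ per mol C (30 is representative of anaerobic heterotrophy).
#' @return power, W cell^-1.
#' @export
wattsPerCell <- function(m, yield_kj_per_mol = 30) {
  if (any(m < 0)) stop("'m' must be non-negative", call. = FALSE)
  m * 1e-15 / .CARBON_MOLAR_MASS * yield_kj_per_mol * 1e3 / 86400
}

#' Organic carbon consumption implied by ammonium and a C:N ratio
#'
#' Under balanced remineralisation, the ammonium accumulated in a closed
#' brine times the molar C:N ratio of the source organic matter estimates
#' the organic carbon consumed.
#'
#' @param ammonium ammonium concentration, mol N mL^-1.
#' @param cn_ratio molar C:N ratio of the organic matter, mol C mol N^-1.
#' @return carbon consumed, fg C mL^-1.
#' @export
cnCarbonConsumption <- function(ammonium, cn_ratio) {
  if (any(ammonium < 0) || any(cn_ratio <= 0))
    stop("'ammonium' must be >= 0 and 'cn_ratio' > 0", call. = FALSE)
  gToFg(ammonium * cn_ratio * .CARBON_MOLAR_MASS)
}

#' Full set of closed-form energetic bounds for a scenario
#'
#' Computes the minimum growth rate, maximum doubling time, cell-specific
#' metabolic rate bounds, EEA rate bounds, and the system timespan implied
#' by the measured EEA rate.
#'
#' @param scenario a [scenarioDefinition()].
#' @param constants a [modelConstants()].
#' @return an object of class `cryo_bounds`: a list with fields `mu_min`
#'   (day^-1), `doubling_time` (years), `m_lower`, `m_upper`,
#'   `gamma_lower`, `gamma_upper` (all fg C cell^-1 day^-1) and
#'   `implied_timespan` (years).
#' @examples
#' cb1 <- buildScenario("CB1")
#' metabolicBounds(cb1$scenario, cb1$constants)
#' @export
metabolicBounds <- function(scenario, constants) {
  stopifnot(inherits(scenario, "cryo_scenario"),
            inherits(constants, "cryo_constants"))
  dpy <- constants$days_per_year
  t_f_days <- yearsToDays(constants$t_f, dpy)
  mu_min <- minimumGrowthRate(constants$N_0, scenario$N_f, constants$t_f, dpy)
  traj_flat <- growthTrajectory("no_growth", N_f = scenario$N_f,
                                t_f_days = t_f_days)
  traj_exp <- growthTrajectory("exponential", N_0 = constants$N_0,
                               N_f = scenario$N_f, t_f_days = t_f_days)
  structure(list(
    scenario = scenario$name,
    p0_source = scenario$p0_source,
    mu_min = mu_min,
    doubling_time = doublingTime(mu_min, dpy),
    m_lower = metabolicRate(scenario, traj_flat),
    m_upper = metabolicRate(scenario, traj_exp),
    gamma_lower = eeaRate(scenario, traj_flat),
    gamma_upper = eeaRate(scenario, traj_exp),
    implied_timespan = impliedTimespan(scenario, constants$gamma_measured,
                                       mu_min, constants$N_0, dpy)
  ), class = "cryo_bounds")
}

#' @export
print.cryo_bounds <- function(x, ...) {
  cat("Energetic bounds --", x$scenario,
      sprintf("(P_0 %s)\n", x$p0_source))
  cat(sprintf("  Minimum growth rate        : %.3g /day\n", x$mu_min))
  cat(sprintf("  Maximum doubling time      : %s years\n",
              format(signif(x$doubling_time, 3), big.mark = ",")))
  cat(sprintf("  Cell-specific metabolic rate: %.3g - %.3g fg C/cell/day\n",
              x$m_lower, x$m_upper))
  cat(sprintf("  Cell-specific EEA rate      : %.3g - %.3g fg C/cell/day\n",
              x$gamma_lower, x$gamma_upper))
  cat(sprintf("  Timespan implied by measured EEA: %s years\n",
              format(signif(x$implied_timespan, 3), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.cryo_bounds <- function(x, ...) {
  data.frame(scenario = x$scenario, p0_source = x$p0_source,
             mu_min = x$mu_min, doubling_time = x$doubling_time,
             m_lower = x$m_lower, m_upper = x$m_upper,
             gamma_lower = x$gamma_lower, gamma_upper = x$gamma_upper,
             implied_timespan = x$implied_timespan)
}
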