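# Synthetic scenarios with known ground truth.  A "field campaign" on a
# model brine observes only endpoints: the surrounding pools (equal to the
# initial pools), the final brine pools and the final cell density.  The
# generator forward-simulates the carbon model under known parameters and
# emits a scenario definition from those endpoints, optionally perturbed
# by multiplicative lognormal measurement noise, so that the closed-form
# estimators can be tested against known truth.

#' Specification of a synthetic brine scenario
#'
#' @param mu true net growth rate, day^-1.
#' @param m true cell-specific metabolic rate, fg C cell^-1 day^-1.
#' @param gamma_cell true cell-specific EEA rate, fg C cell^-1 day^-1.
#' @param alpha_D carbon per cell, fg C cell^-1.
#' @param N_0 starting cell density, cells mL^-1.
#' @param P_0,D_0 initial particulate/dissolved pools, fg C mL^-1.
#' @param t_f_years system age, years.
#' @param K_D,N_max Monod half-velocity and carrying capacity.
#' @param additions optional pulsed additions (see [modelParameters()]).
#' @param noise_pools,noise_density relative (lognormal) sd of the
#'   observed carbon pools and of the observed final cell density.
#' @param days_per_year calendar conversion.
#' @return an object of class `cryo_synth_spec`.
#' @export
syntheticSpec <- function(mu, m, gamma_cell, alpha_D,
                          N_0 = 1e5, P_0 = 1e13, D_0 = 1e11,
                          t_f_years = 40000, K_D = 8.82e5, N_max = 1e9,
                          additions = NULL,
                          noise_pools = 0, noise_density = 0,
                          days_per_year = 365.25) {
  stopifnot(noise_pools >= 0, noise_density >= 0, t_f_years > 0, N_0 > 0)
  structure(list(mu = mu, m = m, gamma_cell = gamma_cell,
                 alpha_D = alpha_D, N_0 = N_0, P_0 = P_0, D_0 = D_0,
                 t_f_years = t_f_years, K_D = K_D, N_max = N_max,
                 additions = additions,
                 noise_pools = noise_pools, noise_density = noise_density,
                 days_per_year = days_per_year),
            class = "cryo_synth_spec")
}

#' Forward-simulate the ground truth of a synthetic scenario
#'
#' @param spec a [syntheticSpec()].
#' @param ... solver arguments passed to [simulateBrine()].
#' @return list with the true endpoints (`N_f`, `P_f`, `D_f`, `I_f`), the
#'   full `trajectory`, and the `spec`.  A population that collapses
#'   before `t_f` (final density below one cell per mL) is flagged via
#'   `feasible = FALSE`.
#' @export
synthTruth <- function(spec, ...) {
  stopifnot(inherits(spec, "cryo_synth_spec"))
  p <- modelParameters(mu_max = spec$mu, m = spec$m,
                       gamma_cell = spec$gamma_cell,
                       alpha_D = spec$alpha_D, K_D = spec$K_D,
                       N_max = spec$N_max, additions = spec$additions)
  t_f_days <- yearsToDays(spec$t_f_years, spec$days_per_year)
  traj <- simulateBrine(p, c(N = spec$N_0, P = spec$P_0, D = spec$D_0,
                             I = 0),
                        t_f_days = t_f_days, ...)
  last <- traj[nrow(traj), ]
  list(N_f = last$N, P_f = last$P, D_f = last$D, I_f = last$I,
       feasible = last$N >= 1, trajectory = traj, spec = spec)
}

# mean-preserving multiplicative lognormal noise
.lognormal_perturb <- function(x, rel_sd) {
  if (rel_sd == 0) return(x)
  sdlog <- sqrt(log1p(rel_sd^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Observe a synthetic truth as a field campaign would
#'
#' Builds a [scenarioDefinition()] from simulated endpoints: surrounding
#' pools are the initial pools, brine pools and cell density are the final
#' states, each perturbed by multiplicative lognormal noise at the spec's
#' relative sd.
#'
#' @param truth output of [synthTruth()].
#' @param seed integer seed fixing the noise draw.
#' @return a `cryo_scenario` named `"synthetic"`.
#' @export
observeScenario <- function(truth, seed = 1L) {
  spec <- truth$spec
  set.seed(seed)
  pools <- .lognormal_perturb(c(spec$P_0, spec$D_0, truth$P_f, truth$D_f),
                              spec$noise_pools)
  N_f_obs <- .lognormal_perturb(truth$N_f, spec$noise_density)
  has_add <- !is.null(spec$additions) && nrow(spec$additions) > 0
  scenarioDefinition(
    name = "synthetic",
    N_f = N_f_obs,
    P_0 = pools[1], D_0 = pools[2], P_f = pools[3], D_f = pools[4],
    D_in = if (has_add) sum(spec$additions$D_in) else 0,
    P_in = if (has_add) sum(spec$additions$P_in) else 0,
    addition_time = if (has_add)
      daysToYears(spec$additions$time[1], spec$days_per_year)
    else NA_real_,
    alpha_D = spec$alpha_D, mu_max = spec$mu, p0_source = "synthetic"
  )
}

#' Generate a synthetic scenario with known ground truth
#'
#' Convenience wrapper: [synthTruth()] then [observeScenario()].
#'
#' @param spec a [syntheticSpec()].
#' @param seed seed for the observation noise.
#' @param ... solver arguments for the forward simulation.
#' @return list with `scenario` (the observed `cryo_scenario`),
#'   `ground_truth` (true endpoints and spec) and `feasible`.
#' @export
generateScenario <- function(spec, seed = 1L, ...) {
  truth <- synthTruth(spec, ...)
  scenario <- NULL
  if (!truth$feasible) {
    warning("population collapsed before t_f; scenario flagged infeasible",
            call. = FALSE)
  } else {
    scenario <- observeScenario(truth, seed = seed)
  }
  list(scenario = scenario,
       ground_truth = truth[c("N_f", "P_f", "D_f", "I_f", "spec")],
       feasible = truth$feasible)
}

#' Perturb scenario tables to propagate input rounding uncertainty
#'
#' Resamples every carbon pool, addition, cell density and per-cell
#' quantity of the given scenarios with multiplicative lognormal noise of
#' relative sd `rel_sd`, e.g. to quantify how table rounding moves the
#' closed-form bounds.
#'
#' @param rel_sd relative standard deviation of the perturbation.
#' @param seed integer seed.
#' @param scenarios list of `cryo_scenario` (default: the three shipped
#'   presets).
#' @return list of perturbed `cryo_scenario` objects.
#' @export
perturbTables <- function(rel_sd, seed = 1L, scenarios = NULL) {
  stopifnot(rel_sd >= 0)
  if (is.null(scenarios)) {
    scenarios <- lapply(c("CB1", "CB4", "CBIW"),
                        function(nm) buildScenario(nm)$scenario)
    names(scenarios) <- c("CB1", "CB4", "CBIW")
  }
  set.seed(seed)
  fields <- c("N_f", "P_0", "D_0", "P_f", "D_f", "D_in", "P_in", "alpha_D")
  lapply(scenarios, function(sc) {
    for (f in fields) sc[[f]] <- .lognormal_perturb(sc[[f]], rel_sd)
    sc
  })
}
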