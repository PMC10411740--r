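# Bound-combination simulation grid and trajectory-outcome diagnostics.
# Each scenario is simulated under all 8 combinations of growth rate
# (minimum/maximum), cell-specific metabolic rate (lower/upper bound) and
# EEA rate (calculated/measured), and each trajectory is classified
# against the observed endpoint cell density.

#' The eight bound combinations of the simulation grid
#'
#' @return data frame with columns `growth_case` (`"minimum"`/`"maximum"`),
#'   `metabolic_case` (`"lower"`/`"upper"`) and `eea_case`
#'   (`"calculated"`/`"measured"`).
#' @export
gridCombinations <- function() {
  g <- expand.grid(growth_case = c("minimum", "maximum"),
                   metabolic_case = c("lower", "upper"),
                   eea_case = c("calculated", "measured"),
                   stringsAsFactors = FALSE)
  rownames(g) <- NULL
  g
}

#' Classify a trajectory outcome against the observed cell density
#'
#' @param traj a `cryo_trajectory`.
#' @param N_f_observed observed endpoint cell density, cells mL^-1.
#' @param tol_factor a trajectory "reaches" the observation when its final
#'   density lies within this factor of `N_f_observed` (default 2,
#'   consistent with order-of-magnitude analysis).
#' @return one of `"reaches_observed"`, `"collapse"`, `"partial_recovery"`,
#'   `"plateau_decline"`.
#' @export
classifyOutcome <- function(traj, N_f_observed, tol_factor = 2) {
  stopifnot(inherits(traj, "cryo_trajectory"), N_f_observed > 0,
            tol_factor >= 1)
  final_N <- traj$N[nrow(traj)]
  ratio <- final_N / N_f_observed
  if (ratio >= 1 / tol_factor && ratio <= tol_factor)
    return("reaches_observed")
  if (final_N < 1) return("collapse")
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    # did the population rise after an addition without reaching N_f?
    after <- traj$N[traj$time >= min(ev$time)]
    if (length(after) > 1 && max(after) > 1.5 * max(after[1], 1))
      return("partial_recovery")
  }
  "plateau_decline"
}

#' Run the eight-combination bound grid for one scenario
#'
#' Combination semantics: "minimum" growth uses the scenario's fitted
#' minimum growth rate and "maximum" its culture-derived `mu_max`;
#' "lower"/"upper" metabolic rates are the closed-form bounds; the
#' "calculated" EEA rate is the Eq.-style POC-budget rate along the
#' chosen calculated trajectory (exponential by default) and "measured"
#' is the laboratory rate in the constants.
#'
#' @param scenario a [scenarioDefinition()].
#' @param constants a [modelConstants()].
#' @param t_f_years simulation horizon, years.
#' @param calculated_eea which closed-form EEA bound feeds "calculated"
#'   grid cells: the exponential-trajectory value (`"exponential"`,
#'   default -- the rate needed to supply a growing population) or the
#'   no-growth value (`"no_growth"`).
#' @param n_out output time points per run.
#' @param ... further solver arguments to [simulateBrine()].
#' @return an object of class `cryo_grid`: list with `outcomes` (data
#'   frame of final states and classifications per combination),
#'   `trajectories` (named list of `cryo_trajectory`) and `bounds`
#'   (the [metabolicBounds()] used).
#' @export
runGrid <- function(scenario, constants, t_f_years = constants$t_f,
                    calculated_eea = c("exponential", "no_growth"),
                    n_out = 401L, ...) {
  calculated_eea <- match.arg(calculated_eea)
  b <- metabolicBounds(scenario, constants)
  gamma_calc <- if (calculated_eea == "exponential") b$gamma_upper
                else b$gamma_lower
  combos <- gridCombinations()
  trajectories <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cmb <- combos[i, ]
    mu <- switch(cmb$growth_case, minimum = b$mu_min,
                 maximum = scenario$mu_max)
    m <- switch(cmb$metabolic_case, lower = b$m_lower, upper = b$m_upper)
    gam <- switch(cmb$eea_case, calculated = gamma_calc,
                  measured = constants$gamma_measured)
    p <- modelParameters(mu_max = mu, m = m, gamma_cell = gam,
                         alpha_D = scenario$alpha_D,
                         alpha_I = constants$alpha_I,
                         K_D = constants$K_D, N_max = constants$N_max,
                         I_xr = constants$I_xr)
    label <- paste(cmb$growth_case, cmb$metabolic_case, cmb$eea_case,
                   sep = "_")
    traj <- tryCatch(
      simulateScenario(scenario, constants, p, t_f_years = t_f_years,
                       n_out = n_out, ...),
      error = function(e) e
    )
    if (inherits(traj, "error")) {
      rows[[i]] <- data.frame(cmb, final_N = NA_real_, final_P = NA_real_,
                              final_D = NA_real_, final_I = NA_real_,
                              reached_fraction = NA_real_,
                              classification = "solver_failure",
                              error = conditionMessage(traj))
      trajectories[i] <- list(NULL)
    } else {
      last <- traj[nrow(traj), ]
      rows[[i]] <- data.frame(cmb, final_N = last$N, final_P = last$P,
                              final_D = last$D, final_I = last$I,
                              reached_fraction = last$N / scenario$N_f,
                              classification =
                                classifyOutcome(traj, scenario$N_f),
                              error = "")
      trajectories[[i]] <- traj
    }
    names(trajectories)[i] <- label
    rownames(rows[[i]]) <- label
  }
  structure(list(scenario = scenario$name,
                 outcomes = do.call(rbind, rows),
                 trajectories = trajectories,
                 bounds = b,
                 calculated_eea = calculated_eea),
            class = "cryo_grid")
}

#' @export
print.cryo_grid <- function(x, ...) {
  cat("Bound-combination grid --", x$scenario, "\n")
  print(x$outcomes[c("growth_case", "metabolic_case", "eea_case",
                     "final_N", "reached_fraction", "classification")])
  invisible(x)
}

#' Compare modeled final DIC with a measurement
#'
#' @param traj a `cryo_trajectory` tracking the DIC pool.
#' @param measured_dic measured DIC, fg C mL^-1.
#' @return list with `modeled`, `measured`, and `log10_ratio`
#'   (`log10(modeled / measured)`, `NA` with a flag when either is zero).
#' @export
dicComparison <- function(traj, measured_dic) {
  stopifnot(inherits(traj, "cryo_trajectory"), measured_dic >= 0)
  modeled <- traj$I[nrow(traj)]
  if (modeled <= 0 || measured_dic <= 0) {
    return(list(modeled = modeled, measured = measured_dic,
                log10_ratio = NA_real_, defined = FALSE))
  }
  list(modeled = modeled, measured = measured_dic,
       log10_ratio = log10(modeled / measured_dic), defined = TRUE)
}
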