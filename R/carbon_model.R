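# Monod-based ODE model of the brine organic carbon cycle.  Four state
# variables: cell density N (cells mL^-1) and the particulate (P),
# dissolved (D) and inorganic (I) carbon pools (fg C mL^-1).  Processes:
# Monod/logistic growth on DOC, starvation death when DOC cannot cover
# the per-cell metabolic demand, enzymatic hydrolysis of POC to DOC
# capped by the remaining POC, respiration of DOC to DIC, and optional
# DIC fixation.  Pulsed carbon additions are applied as discrete state
# jumps at event times, not as spikes in the derivative.

#' Model parameters for the carbon-cycle ODE
#'
#' @param mu_max maximum net growth rate, day^-1.
#' @param m cell-specific metabolic rate, fg C cell^-1 day^-1.
#' @param gamma_cell cell-specific EEA rate, fg C cell^-1 day^-1.
#' @param alpha_D organic carbon per cell, fg C cell^-1.
#' @param alpha_I DIC per cell, fg C cell^-1 (0 disables autotrophic
#'   biomass routing).
#' @param K_D Monod half-velocity constant, fg C mL^-1.
#' @param N_max carrying capacity, cells mL^-1.
#' @param I_xr DIC fixation rate, fg C mL^-1 day^-1 (0 disables it).
#' @param additions data frame of pulsed additions with columns `time`
#'   (days since start, strictly inside the simulated window), `D_in`,
#'   `P_in` and optionally `I_in` (fg C mL^-1).
#' @return an object of class `cryo_parameters`.
#' @export
modelParameters <- function(mu_max, m, gamma_cell, alpha_D,
                            alpha_I = 0, K_D = 8.82e5, N_max = 1e9,
                            I_xr = 0, additions = NULL) {
  p <- list(mu_max = mu_max, m = m, gamma_cell = gamma_cell,
            alpha_D = alpha_D, alpha_I = alpha_I, K_D = K_D,
            N_max = N_max, I_xr = I_xr)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0)
      stop("parameter '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (is.null(additions)) {
    additions <- data.frame(time = numeric(0), D_in = numeric(0),
                            P_in = numeric(0), I_in = numeric(0))
  } else {
    additions <- as.data.frame(additions)
    if (!all(c("time", "D_in", "P_in") %in% names(additions)))
      stop("'additions' needs columns time, D_in, P_in", call. = FALSE)
    if (is.null(additions$I_in)) additions$I_in <- 0
    if (any(additions$time <= 0))
      stop("addition times must be strictly positive", call. = FALSE)
    additions <- additions[order(additions$time), , drop = FALSE]
  }
  p$additions <- additions
  structure(p, class = "cryo_parameters")
}

.state_nonneg <- function(state) pmax(state, 0)

#' Monod/logistic growth term
#'
#' `mu_max * D / (K_D + D) * N * (1 - N / N_max)`: growth saturates in
#' DOC and is capped logistically at the carrying capacity.
#'
#' @param state named numeric vector with elements `N`, `P`, `D`, `I`.
#' @param p a [modelParameters()].
#' @return growth rate, cells mL^-1 day^-1.
#' @export
growthTerm <- function(state, p) {
  s <- .state_nonneg(state)
  p$mu_max * s[["D"]] / (p$K_D + s[["D"]]) * s[["N"]] *
    (1 - s[["N"]] / p$N_max)
}

#' Starvation death term
#'
#' The number of cells whose daily metabolic demand `m * N` exceeds the
#' available DOC: `max(m N - D, 0) / m`, clamped to `N` (more cells than
#' exist cannot die -- relevant only for transient `D < 0` overshoots).
#'
#' @inheritParams growthTerm
#' @return death rate, cells mL^-1 day^-1.
#' @export
starvationDeath <- function(state, p) {
  s <- .state_nonneg(state)
  deficit <- p$m * s[["N"]] - s[["D"]]
  if (deficit <= 0) return(0)
  if (p$m == 0)
    stop("metabolic demand deficit with m = 0 is undefined", call. = FALSE)
  min(deficit / p$m, s[["N"]])
}

#' Enzymatic hydrolysis flux from POC to DOC
#'
#' `min(gamma_cell * N, P)`: the community-wide EEA, never exceeding the
#' remaining particulate pool.
#'
#' @inheritParams growthTerm
#' @return hydrolysis flux, fg C mL^-1 day^-1.
#' @export
eeaFlux <- function(state, p) {
  s <- .state_nonneg(state)
  min(p$gamma_cell * s[["N"]], s[["P"]])
}

#' Time derivatives of the carbon-cycle state
#'
#' Couples growth, starvation death, hydrolysis, respiration and DIC
#' fixation.  Pulsed additions do not appear here; they are applied as
#' state jumps by [simulateBrine()].  With `alpha_I = 0` the total
#' `P + D + I + alpha_D * N` is algebraically conserved between pulses.
#'
#' @inheritParams growthTerm
#' @param t time, days (unused; the system is autonomous between events).
#' @return list of one numeric vector `c(dN, dP, dD, dI)`, as required by
#'   [deSolve::ode()].
#' @export
carbonDerivatives <- function(t, state, p) {
  s <- .state_nonneg(state)
  G <- p$mu_max * s[["D"]] / (p$K_D + s[["D"]]) * s[["N"]] *
    (1 - s[["N"]] / p$N_max)
  deficit <- p$m * s[["N"]] - s[["D"]]
  Delta <- if (deficit <= 0 || p$m == 0) 0 else min(deficit / p$m, s[["N"]])
  gam <- min(p$gamma_cell * s[["N"]], s[["P"]])
  fix <- min(p$I_xr, s[["I"]])
  survivors_demand <- p$m * (s[["N"]] - Delta)
  dN <- G - Delta
  dP <- -gam
  dD <- p$alpha_D * (Delta - G) - survivors_demand + gam + fix
  dI <- p$alpha_I * (Delta - G) + survivors_demand - fix
  list(c(dN, dP, dD, dI))
}

#' Integrate the brine carbon-cycle model
#'
#' Solves the initial-value problem with an adaptive stiff-capable solver.
#' At each configured addition time the P, D and I pools jump by the pulse
#' amounts and a population that has declined below one viable cell per mL
#' is rescued to `N = 1`, so that a carbon pulse can restart growth.
#' Reported states are clipped to zero; the raw solver output is kept in
#' the attribute `"raw"` for diagnostics.
#'
#' @param p a [modelParameters()].
#' @param init named numeric vector `c(N, P, D, I)` of initial values.
#' @param t_f_days integration horizon, days.
#' @param n_out number of equally spaced output times (including 0 and
#'   `t_f_days`).
#' @param times explicit output times, days; overrides `n_out`.
#' @param method solver passed to [deSolve::ode()]; `"lsoda"` switches
#'   automatically between stiff and non-stiff integrators.
#' @param rtol,atol relative tolerance and per-state absolute tolerances
#'   (defaults: 1 cell for N, 1 fg C for the pools).
#' @param maxsteps maximum internal steps per output interval.
#' @return an object of class `cryo_trajectory`: a data frame with
#'   columns `time` (days), `N`, `P`, `D`, `I`, with the parameters,
#'   events and solver diagnostics as attributes.
#' @examples
#' p <- modelParameters(mu_max = 0.06, m = 0.2, gamma_cell = 0.8,
#'                      alpha_D = 15.7)
#' traj <- simulateBrine(p, c(N = 1e5, P = 1.64e13, D = 3.41e10, I = 0),
#'                       t_f_days = 1000, n_out = 11)
#' @export
simulateBrine <- function(p, init, t_f_days, n_out = 501L, times = NULL,
                          method = "lsoda", rtol = 1e-8,
                          atol = c(N = 1, P = 1, D = 1, I = 1),
                          maxsteps = 100000L) {
  stopifnot(inherits(p, "cryo_parameters"))
  if (!all(c("N", "P", "D", "I") %in% names(init)))
    stop("'init' must name N, P, D and I", call. = FALSE)
  init <- init[c("N", "P", "D", "I")]
  if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
  stopifnot(t_f_days > 0)

  if (is.null(times)) times <- seq(0, t_f_days, length.out = n_out)
  times <- sort(unique(times))

  additions <- p$additions
  events <- NULL
  if (nrow(additions) > 0) {
    if (any(additions$time >= t_f_days))
      stop("addition times must fall strictly inside (0, t_f_days)",
           call. = FALSE)
    # event times must be present in the output grid for deSolve
    times <- sort(unique(c(times, additions$time)))
    eventfun <- function(t, y, parms) {
      row <- additions[abs(additions$time - t) < 1e-6, , drop = FALSE]
      y["P"] <- y["P"] + sum(row$P_in)
      y["D"] <- y["D"] + sum(row$D_in)
      y["I"] <- y["I"] + sum(row$I_in)
      if (y["N"] < 1) y["N"] <- 1  # single-viable-cell rescue
      y
    }
    events <- list(func = eventfun, time = additions$time)
  }

  out <- deSolve::ode(y = init, times = times, func = carbonDerivatives,
                      parms = p, method = method, rtol = rtol, atol = atol,
                      maxsteps = maxsteps, events = events)
  diagn <- attributes(out)[c("istate", "rstate")]
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  raw <- df
  df[c("N", "P", "D", "I")] <- lapply(df[c("N", "P", "D", "I")],
                                      function(col) pmax(col, 0))
  structure(df,
            class = c("cryo_trajectory", "data.frame"),
            parameters = p,
            init = init,
            events = additions,
            solver = list(method = method, rtol = rtol, atol = atol,
                          diagnostics = diagn),
            raw = raw)
}

#' Simulate a borehole scenario
#'
#' Convenience wrapper around [simulateBrine()]: the brine at enclosure is
#' assumed to hold the surrounding-sediment carbon pools (`P_0`, `D_0`),
#' the starting density is `N_0` from the constants, initial DIC defaults
#' to zero, and the scenario's pulsed addition (if any) is scheduled.
#'
#' @param scenario a [scenarioDefinition()].
#' @param constants a [modelConstants()].
#' @param p a [modelParameters()]; its `additions` are replaced by the
#'   scenario's pulse.
#' @param t_f_years horizon in years (default: the constants' `t_f`).
#' @param I_0 initial DIC, fg C mL^-1.
#' @param ... further arguments to [simulateBrine()].
#' @return a `cryo_trajectory`.
#' @export
simulateScenario <- function(scenario, constants, p,
                             t_f_years = constants$t_f, I_0 = 0, ...) {
  stopifnot(inherits(scenario, "cryo_scenario"),
            inherits(constants, "cryo_constants"))
  dpy <- constants$days_per_year
  additions <- NULL
  if (!is.na(scenario$addition_time) &&
      (scenario$D_in > 0 || scenario$P_in > 0)) {
    additions <- data.frame(time = yearsToDays(scenario$addition_time, dpy),
                            D_in = scenario$D_in, P_in = scenario$P_in,
                            I_in = 0)
  }
  p$additions <- if (is.null(additions)) {
    data.frame(time = numeric(0), D_in = numeric(0), P_in = numeric(0),
               I_in = numeric(0))
  } else additions
  init <- c(N = constants$N_0, P = scenario$P_0, D = scenario$D_0, I = I_0)
  simulateBrine(p, init, t_f_days = yearsToDays(t_f_years, dpy), ...)
}

#' Mass-balance audit of a trajectory
#'
#' With `alpha_I = 0`, the total carbon `P + D + I + alpha_D * N` changes
#' only by the pulsed additions; the audit subtracts the cumulative pulses
#' and reports the relative drift of the corrected total.
#'
#' @param traj a `cryo_trajectory`.
#' @param p parameters; defaults to those stored in the trajectory.
#' @return data frame with columns `time`, `total` (corrected total
#'   carbon) and `residual` (relative deviation from the initial total).
#' @export
massBalanceAudit <- function(traj, p = attr(traj, "parameters")) {
  stopifnot(inherits(traj, "cryo_trajectory"))
  raw <- attr(traj, "raw")
  biomass_c <- p$alpha_D + p$alpha_I
  total <- raw$P + raw$D + raw$I + biomass_c * raw$N
  additions <- p$additions
  if (nrow(additions) > 0) {
    # the solver reports the pre-event state at the event time itself,
    # so the pulse enters the running total only strictly after it
    pulse <- rowSums(vapply(seq_len(nrow(additions)), function(i) {
      amt <- additions$D_in[i] + additions$P_in[i] + additions$I_in[i]
      ifelse(raw$time > additions$time[i], amt, 0)
    }, numeric(nrow(raw))))
    total <- total - pulse
  }
  data.frame(time = raw$time, total = total,
             residual = total / total[1] - 1)
}

#' @export
print.cryo_trajectory <- function(x, ...) {
  n <- nrow(x)
  ev <- attr(x, "events")
  cat(sprintf("Carbon-cycle trajectory: %d time points over %.4g days\n",
              n, x$time[n]))
  if (!is.null(ev) && nrow(ev) > 0)
    cat(sprintf("  %d pulsed addition(s) at day(s) %s\n", nrow(ev),
                paste(signif(ev$time, 4), collapse = ", ")))
  cat(sprintf("  final state: N %.4g cells/mL, P %.4g, D %.4g, I %.4g fg C/mL\n",
              x$N[n], x$P[n], x$D[n], x$I[n]))
  invisible(x)
}

#' Write a trajectory and its run metadata to disk
#'
#' @param traj a `cryo_trajectory`.
#' @param path output CSV path; a JSON sidecar `<path>.meta.json` records
#'   parameters and solver settings.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cryo_trajectory"))
  df <- as.data.frame(traj)
  ev <- attr(traj, "events")
  df$event <- ""
  if (!is.null(ev) && nrow(ev) > 0) {
    for (tt in ev$time) {
      i <- which.min(abs(df$time - tt))
      df$event[i] <- "addition"
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  p <- attr(traj, "parameters")
  meta <- list(parameters = p[setdiff(names(p), "additions")],
               additions = p$additions,
               init = as.list(attr(traj, "init")),
               solver = attr(traj, "solver")[c("method", "rtol", "atol")])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
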