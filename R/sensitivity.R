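# Sobol variance-based global sensitivity analysis.  Saltelli paired
# sampling matrices with Jansen estimators for first-order and
# total-effect indices, bootstrap confidence intervals, and an optional
# sample-doubling loop that runs until the widest CI meets a target
# half-width.

.sobol_sample <- function(n, bounds) {
  k <- nrow(bounds)
  U <- matrix(runif(n * k), nrow = n, ncol = k)
  X <- matrix(NA_real_, n, k, dimnames = list(NULL, bounds$parameter))
  for (j in seq_len(k)) {
    lo <- bounds$lower[j]; hi <- bounds$upper[j]
    if (identical(bounds$scale[j], "log")) {
      X[, j] <- exp(log(lo) + U[, j] * (log(hi) - log(lo)))
    } else {
      X[, j] <- lo + U[, j] * (hi - lo)
    }
  }
  X
}

.jansen <- function(fA, fB, fAB, idx = seq_along(fA)) {
  fA <- fA[idx]; fB <- fB[idx]; fAB <- fAB[idx, , drop = FALSE]
  V <- stats::var(c(fA, fB))
  # a (re)sample whose output variance is negligible against the squared
  # output scale carries no attributable variance: all indices are zero
  # (this also guards bootstrap resamples drawn mostly from one regime)
  scale2 <- mean(c(fA, fB, fAB)^2)
  if (!is.finite(V) || V <= 1e-12 * scale2) {
    k <- ncol(fAB)
    return(list(first = rep(0, k), total = rep(0, k)))
  }
  first <- apply(fAB, 2, function(col) (V - mean((fB - col)^2) / 2) / V)
  total <- apply(fAB, 2, function(col) mean((fA - col)^2) / 2 / V)
  list(first = first, total = total)
}

#' Sobol sensitivity indices of an arbitrary model
#'
#' Estimates first-order and total-effect Sobol indices by Monte Carlo
#' over paired sampling matrices (`n * (k + 2)` model evaluations for `k`
#' parameters), with Jansen's estimators and bootstrap confidence
#' intervals.  When `ci_target` is set, the base sample size doubles until
#' every CI half-width is below the target or `max_n` is reached.
#'
#' @param model function taking a numeric matrix (rows = parameter draws,
#'   columns named as in `bounds$parameter`) and returning one numeric
#'   output per row.
#' @param bounds data frame with columns `parameter`, `lower`, `upper`
#'   and optionally `scale` (`"linear"` default, or `"log"` for
#'   log-uniform sampling; requires a positive lower bound).
#' @param n base sample size per matrix.
#' @param seed integer seed fixing all sampling and bootstrap randomness.
#' @param conf confidence level of the bootstrap intervals.
#' @param n_boot bootstrap resamples.
#' @param ci_target optional CI half-width (in index units) to converge to.
#' @param max_n cap on the base sample size for the doubling loop.
#' @return an object of class `cryo_sobol`: data frame `indices` with
#'   per-parameter first-order and total-effect estimates and CI bounds,
#'   plus fields `samples_used` (base draws), `n_evaluations`, and
#'   `converged`.
#' @examples
#' add3 <- function(X) 2 * X[, 1] + 1 * X[, 2] + 0.5 * X[, 3]
#' b <- data.frame(parameter = c("a", "b", "c"), lower = 0, upper = 1)
#' sobolIndices(add3, b, n = 256, seed = 1)
#' @export
sobolIndices <- function(model, bounds, n = 256L, seed = 1L,
                         conf = 0.95, n_boot = 1000L,
                         ci_target = NULL, max_n = 8192L) {
  bounds <- as.data.frame(bounds)
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (is.null(bounds$scale)) bounds$scale <- "linear"
  if (any(bounds$lower >= bounds$upper))
    stop("each parameter needs lower < upper", call. = FALSE)
  if (any(bounds$scale == "log" & bounds$lower <= 0))
    stop("log-scale sampling requires positive lower bounds", call. = FALSE)
  stopifnot(conf > 0, conf < 1)
  k <- nrow(bounds)
  alpha <- (1 - conf) / 2

  n_cur <- as.integer(n)
  repeat {
    set.seed(seed)
    A <- .sobol_sample(n_cur, bounds)
    B <- .sobol_sample(n_cur, bounds)
    fA <- model(A)
    fB <- model(B)
    fAB <- matrix(NA_real_, n_cur, k, dimnames = list(NULL, bounds$parameter))
    for (j in seq_len(k)) {
      ABj <- A
      ABj[, j] <- B[, j]
      fAB[, j] <- model(ABj)
    }
    est <- .jansen(fA, fB, fAB)

    boot_first <- matrix(NA_real_, n_boot, k)
    boot_total <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_cur, n_cur, replace = TRUE)
      bs <- .jansen(fA, fB, fAB, idx)
      boot_first[b, ] <- bs$first
      boot_total[b, ] <- bs$total
    }
    ci <- list(
      first_lo = apply(boot_first, 2, stats::quantile, probs = alpha),
      first_hi = apply(boot_first, 2, stats::quantile, probs = 1 - alpha),
      total_lo = apply(boot_total, 2, stats::quantile, probs = alpha),
      total_hi = apply(boot_total, 2, stats::quantile, probs = 1 - alpha)
    )
    halfwidth <- max((ci$first_hi - ci$first_lo) / 2,
                     (ci$total_hi - ci$total_lo) / 2)
    converged <- is.null(ci_target) || halfwidth <= ci_target
    if (converged || 2L * n_cur > max_n) break
    n_cur <- 2L * n_cur
  }

  indices <- data.frame(
    parameter = bounds$parameter,
    first_order = est$first,
    first_order_lo = ci$first_lo,
    first_order_hi = ci$first_hi,
    total_effect = est$total,
    total_effect_lo = ci$total_lo,
    total_effect_hi = ci$total_hi,
    row.names = NULL
  )
  structure(list(indices = indices, samples_used = n_cur,
                 n_evaluations = n_cur * (k + 2L),
                 conf = conf, converged = converged, seed = seed),
            class = "cryo_sobol")
}

#' @export
print.cryo_sobol <- function(x, ...) {
  cat(sprintf(
    "Sobol sensitivity indices (%d base draws, %d model evaluations, %s)\n",
    x$samples_used, x$n_evaluations,
    if (x$converged) "converged" else "NOT converged"))
  df <- x$indices
  df[-1] <- lapply(df[-1], function(col) signif(col, 3))
  print(df)
  invisible(x)
}

#' Default sensitivity parameter bounds
#'
#' The literature-plausible sampling box shipped with the scenario
#' presets: growth rate, cell-specific metabolic rate, cell carbon
#' content, EEA rate, half-velocity constant, carrying capacity and
#' starting cell density.  Growth and metabolic rates span more than four
#' decades and are sampled log-uniformly; the rest are uniform.
#'
#' @param config_file optional alternative YAML preset.
#' @return data frame usable as `bounds` in [sobolIndices()].
#' @export
sensitivityBounds <- function(config_file = NULL) {
  cfg <- .load_preset(config_file)
  sb <- cfg$sensitivity_bounds
  if (is.null(sb))
    stop("preset lacks a 'sensitivity_bounds' block", call. = FALSE)
  data.frame(
    parameter = names(sb),
    lower = vapply(sb, function(x) as.numeric(x$lower), numeric(1)),
    upper = vapply(sb, function(x) as.numeric(x$upper), numeric(1)),
    scale = vapply(sb, function(x)
      if (is.null(x$scale)) "linear" else x$scale, character(1)),
    row.names = NULL
  )
}

#' Build the carbon-model evaluation function for sensitivity analysis
#'
#' Returns a vectorised model closure mapping sampled parameter rows to a
#' scalar trajectory summary.  Draws on which the solver fails (or that
#' overflow) are assigned a collapsed outcome (`final_N = 0`, and
#' `final_P` equal to its initial value) so the paired matrices stay
#' aligned.
#'
#' @param scenario a [scenarioDefinition()].
#' @param constants a [modelConstants()].
#' @param output trajectory summary: final cell density (`"final_N"`,
#'   default) or final POC (`"final_P"`).
#' @param rtol solver relative tolerance; the sensitivity sweep uses a
#'   looser default than single-trajectory work since only the endpoint
#'   summary is consumed.
#' @return function(matrix) -> numeric vector.
#' @export
sensitivityModel <- function(scenario, constants,
                             output = c("final_N", "final_P"),
                             rtol = 1e-6) {
  output <- match.arg(output)
  stopifnot(inherits(scenario, "cryo_scenario"),
            inherits(constants, "cryo_constants"))
  t_f_days <- yearsToDays(constants$t_f, constants$days_per_year)
  fail_value <- switch(output, final_N = 0, final_P = scenario$P_0)
  function(X) {
    vapply(seq_len(nrow(X)), function(i) {
      x <- X[i, ]
      # failed draws are expected across an aggressive sampling box; the
      # solver's failure chatter is captured so sweeps stay quiet
      solver_log <- utils::capture.output(out <- suppressWarnings(tryCatch({
        p <- modelParameters(
          mu_max = x[["growth_rate"]],
          m = x[["metabolic_rate"]],
          gamma_cell = x[["eea_rate"]],
          alpha_D = x[["cell_carbon"]],
          alpha_I = constants$alpha_I,
          K_D = x[["half_velocity"]],
          N_max = x[["carrying_capacity"]],
          I_xr = constants$I_xr
        )
        cst <- constants
        cst$N_0 <- min(x[["starting_density"]], x[["carrying_capacity"]])
        traj <- simulateScenario(scenario, cst, p,
                                 times = c(0, t_f_days), rtol = rtol,
                                 maxsteps = 200000L)
        val <- switch(output,
                      final_N = traj$N[nrow(traj)],
                      final_P = traj$P[nrow(traj)])
        if (!is.finite(val)) fail_value else val
      }, error = function(e) fail_value)), type = "output")
      out
    }, numeric(1))
  }
}

#' Sobol sensitivity analysis of the brine carbon model
#'
#' Runs [sobolIndices()] on the carbon-cycle model for one scenario over
#' the configured parameter bounds.
#'
#' @inheritParams sensitivityModel
#' @inheritParams sobolIndices
#' @param bounds sampling box; defaults to [sensitivityBounds()].
#' @return a `cryo_sobol` with the output metric recorded in
#'   `$output_metric`.
#' @export
sobolAnalysis <- function(scenario, constants,
                          output = c("final_N", "final_P"),
                          n = 256L, seed = 1L, bounds = NULL,
                          conf = 0.95, n_boot = 1000L,
                          ci_target = NULL, max_n = 2048L, rtol = 1e-6) {
  output <- match.arg(output)
  if (is.null(bounds)) bounds <- sensitivityBounds()
  model <- sensitivityModel(scenario, constants, output = output,
                            rtol = rtol)
  res <- sobolIndices(model, bounds, n = n, seed = seed, conf = conf,
                      n_boot = n_boot, ci_target = ci_target, max_n = max_n)
  res$output_metric <- output
  res$scenario <- scenario$name
  res
}
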