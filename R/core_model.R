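#' Competition configuration
#'
#' Bundles the environmental parameters of a serial-dilution competition.
#' `rho` is the initial density of resources per cell at the start of every
#' round (total resources divided by total bottleneck population). With
#' `consumption_mode = "total_cells"` (the primary assumption) resources are
#' consumed in proportion to the total number of cells, so strain i has used
#' `N_i(t)/Y_i` resources by time t; with `"divisions"` consumption is
#' proportional to cell divisions, `(N_i(t) - N_i(0))/Y_i`. The two modes
#' converge when the per-round fold change is large.
#'
#' @param rho Initial resources per cell, `> 0`.
#' @param consumption_mode `"total_cells"` (default) or `"divisions"`.
#' @param extinction_threshold Density below which a strain is treated as
#'   extinct during multi-round dynamics (absorbing); in `[0, 1)`. The
#'   default `1e-12` corresponds to the reciprocal of a large bottleneck
#'   population.
#' @param solver_tolerance Absolute time tolerance of the saturation-time
#'   root solve.
#' @return A list of class `competition_config`.
#' @export
competition_config <- function(rho,
                               consumption_mode = c("total_cells", "divisions"),
                               extinction_threshold = 1e-12,
                               solver_tolerance = 1e-10) {
  consumption_mode <- match.arg(consumption_mode)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    sc_error("rho must be a single finite positive number", "validation")
  if (!is.finite(extinction_threshold) || extinction_threshold < 0 ||
      extinction_threshold >= 1)
    sc_error("extinction_threshold must lie in [0, 1)", "validation")
  if (!is.finite(solver_tolerance) || solver_tolerance <= 0)
    sc_error("solver_tolerance must be > 0", "validation")
  structure(list(rho = rho, consumption_mode = consumption_mode,
                 extinction_threshold = extinction_threshold,
                 solver_tolerance = solver_tolerance),
            class = "competition_config")
}

# Resources consumed by time t, for nominal total initial population 1.
# total_cells mode counts all cells; divisions mode counts only new cells.
consumed_resources <- function(t, lag, tau, yield, x, mode) {
  n <- x * exp(pmax(0, t - lag) / tau)
  if (mode == "divisions") sum((n - x) / yield) else sum(n / yield)
}

# d(consumed)/dt; zero for strains still in lag phase. Identical in both
# consumption modes.
consumed_rate <- function(t, lag, tau, yield, x) {
  grown <- t > lag
  if (!any(grown)) return(0)
  sum((x * exp((t - lag) / tau) / (yield * tau))[grown])
}

#' Saturation time of a competition round
#'
#' Each strain is frozen at its initial size until its own lag time, then
#' grows exponentially with its own growth time. Growth stops for everyone at
#' the single time `t_sat` when the resources consumed by all strains equal
#' the initial resource pool `R = rho` (per unit initial population). The
#' consumed-resource function is piecewise smooth (kinks at the lag times)
#' and strictly increasing once any strain grows, so the root is unique; the
#' solver brackets it between sorted lag times and finishes with safeguarded
#' Newton polishing to drive the resource balance below relative `1e-12`.
#'
#' For a single strain this reduces to the closed form
#' `t_sat = lag + growth_time * log(rho * yield)`.
#'
#' @param strains Strain table.
#' @param x Initial densities on the simplex (default uniform).
#' @param config A [competition_config()].
#' @return The saturation time (scalar).
#' @seealso [grow_one_round()]
#' @export
saturation_time <- function(strains, x = uniform_densities(strains), config) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  lag <- strains$lag; tau <- strains$growth_time; yield <- strains$yield
  mode <- config$consumption_mode
  target <- config$rho

  initial <- consumed_resources(0, lag, tau, yield, x, mode)
  if (mode == "total_cells" && target <= initial * (1 + 1e-15))
    sc_error(paste0("no growth possible: rho * effective yield <= 1 ",
                    "(resources do not exceed those embodied in the initial cells)"),
             "no_growth")

  f <- function(t) consumed_resources(t, lag, tau, yield, x, mode) - target

  # Bracket between consecutive lag breakpoints of present strains.
  bp <- sort(unique(lag[x > 0]))
  lo <- bp[1]
  hi <- NA_real_
  if (length(bp) > 1L) {
    fb <- vapply(bp, f, numeric(1))
    idx <- which(fb >= 0)
    if (length(idx)) {
      if (idx[1] == 1L) return(bp[1])  # saturated exactly at first lag
      lo <- bp[idx[1] - 1L]; hi <- bp[idx[1]]
    } else {
      lo <- bp[length(bp)]
    }
  }
  if (is.na(hi)) {          # root beyond the last lag: expand exponentially
    step <- max(tau)
    hi <- lo + step
    while (f(hi) < 0) { lo <- hi; step <- 2 * step; hi <- hi + step }
  }

  t_sat <- stats::uniroot(f, lower = lo, upper = hi,
                          tol = config$solver_tolerance, maxiter = 1000L)$root
  # Newton polish to meet the resource-balance tolerance exactly.
  for (it in 1:4) {
    resid <- f(t_sat)
    if (abs(resid) <= 1e-13 * target) break
    rate <- consumed_rate(t_sat, lag, tau, yield, x)
    if (rate <= 0) break
    t_new <- t_sat - resid / rate
    if (!is.finite(t_new) || t_new < lo || t_new > hi) break
    t_sat <- t_new
  }
  t_sat
}

#' Grow a community for one competition round
#'
#' Runs the three-phase growth model for every strain up to the common
#' saturation time: strain i ends at `N_i(0) * exp((t_sat - lag_i)/tau_i)` if
#' its lag ended before saturation, otherwise at its initial size. Final
#' densities are the final sizes renormalized to the simplex. Population
#' sizes are never tracked absolutely: the round is closed in the densities
#' and `rho`, so a nominal total initial size of 1 is used throughout.
#'
#' @inheritParams saturation_time
#' @return A list with `densities` (final simplex vector, named),
#'   `t_sat`, `fold_changes` (per-strain final/initial size; 1 for absent
#'   strains), and `log_fold_changes`.
#' @export
grow_one_round <- function(strains, x = uniform_densities(strains), config) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  t_sat <- saturation_time(strains, x, config)
  lfc <- pmax(0, t_sat - strains$lag) / strains$growth_time
  lfc[x == 0] <- 0
  nf <- x * exp(lfc)
  list(densities = stats::setNames(nf / sum(nf), strains$label),
       t_sat = t_sat,
       fold_changes = stats::setNames(exp(lfc), strains$label),
       log_fold_changes = stats::setNames(lfc, strains$label))
}
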