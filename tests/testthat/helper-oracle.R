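# Independent brute-force oracle for one growth round: instead of root
# finding, tabulates the consumed-resource curve on successively refined
# time grids and linearly interpolates the crossing. Shares no code with the
# package's saturation solver.
oracle_round <- function(strains, x, rho, mode = "total_cells",
                         n_grid = 4000L, passes = 3L) {
  consumed_at <- function(tt) vapply(tt, function(t) {
    n <- x * exp(pmax(0, t - strains$lag) / strains$growth_time)
    if (mode == "divisions") sum((n - x) / strains$yield)
    else sum(n / strains$yield)
  }, numeric(1))
  # crude upper bound: time for any single present strain to exhaust the
  # pool on its own
  active <- x > 0
  t_hi <- max(strains$lag[active] + strains$growth_time[active] *
                log(rho * strains$yield[active] / x[active])) + 1
  t_lo <- 0
  for (p in seq_len(passes)) {
    grid <- seq(t_lo, t_hi, length.out = n_grid)
    cons <- consumed_at(grid)
    k <- which(cons >= rho)[1]
    stopifnot(!is.na(k), k > 1L)
    t_lo <- grid[k - 1L]; t_hi <- grid[k]
  }
  c_lo <- consumed_at(t_lo); c_hi <- consumed_at(t_hi)
  t_sat <- t_lo + (rho - c_lo) / (c_hi - c_lo) * (t_hi - t_lo)
  n_fin <- x * exp(pmax(0, t_sat - strains$lag) / strains$growth_time)
  list(t_sat = t_sat, densities = n_fin / sum(n_fin))
}

# Small fixed three-strain community used across tests.
three_strains <- function() {
  strain_table(c("A", "B", "C"),
               lag = c(1.0, 1.6, 0.7),
               growth_time = c(1.0, 1.3, 0.9),
               yield = c(2e4, 5e4, 3.5e4))
}

# Exactly collinear ensemble with the whole coexistence window above the
# monoculture growth floor (yield spread < exp(c)).
collinear_ensemble <- function(n = 4, c = 1.5, intercept = 8,
                               tau_range = c(1, 4),
                               yield_range = c(1e3, 4e3),
                               rule = "tradeoff", seed = 42) {
  generate_ensemble(ensemble_spec(
    n_strains = n, c = c, intercept = intercept, tau_range = tau_range,
    yield_spec = list(rule = rule, range = yield_range), seed = seed))
}

subset_strains <- function(strains, idx) {
  out <- strains[idx, , drop = FALSE]
  class(out) <- c("strain_table", "data.frame")
  out
}
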