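#' Serial-dilution dynamics over many rounds
#'
#' Iterates the exact one-round growth map: each round starts from the
#' previous round's final densities with the same resource density `rho`
#' (deterministic dilution; bottleneck sampling noise is out of scope).
#' Strains whose density falls below the configured extinction threshold are
#' set to exactly zero and the vector renormalized; extinction is absorbing
#' and the round at which it happens is recorded.
#'
#' @inheritParams saturation_time
#' @param n_rounds Number of competition rounds, `>= 1`.
#' @param stop_on_resolution If `TRUE`, stop early once only one strain
#'   remains or a fixed point is detected (checked every `check_every`
#'   rounds over a window of the same length with tolerance `fp_tol`).
#' @param check_every,fp_tol Early-stopping controls (see above).
#' @return An object of class `trajectory`: list with `densities`
#'   (matrix, rounds + 1 rows, one column per strain; row r+1 is the state at
#'   the start of round r), `round` (0-based index vector), `t_sat` (per
#'   round), `extinctions` (named vector, round of extinction or NA), and
#'   `resolved` (`"max_rounds"`, `"single_survivor"`, or `"fixed_point"`).
#' @export
run_serial_dilution <- function(strains, x = uniform_densities(strains),
                                config, n_rounds,
                                stop_on_resolution = FALSE,
                                check_every = 100L, fp_tol = 1e-8) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  if (n_rounds < 1L) sc_error("n_rounds must be >= 1", "validation")
  m <- nrow(strains)
  eps <- config$extinction_threshold
  dens <- matrix(NA_real_, n_rounds + 1L, m,
                 dimnames = list(NULL, strains$label))
  t_sat <- rep(NA_real_, n_rounds)
  extinct_round <- stats::setNames(rep(NA_integer_, m), strains$label)
  dens[1L, ] <- x
  resolved <- "max_rounds"
  last <- n_rounds
  for (r in seq_len(n_rounds)) {
    g <- grow_one_round(strains, x, config)
    xp <- g$densities
    newly_extinct <- xp > 0 & xp < eps
    if (any(newly_extinct)) {
      xp[newly_extinct] <- 0
      xp <- xp / sum(xp)
      extinct_round[newly_extinct] <- r
    }
    x <- xp
    dens[r + 1L, ] <- x
    t_sat[r] <- g$t_sat
    if (stop_on_resolution) {
      if (sum(x > 0) == 1L) { resolved <- "single_survivor"; last <- r; break }
      if (r %% check_every == 0L && r > check_every) {
        win <- dens[(r - check_every + 1L):(r + 1L), , drop = FALSE]
        if (max(abs(diff(win))) < fp_tol) {
          s <- selection_matrix(strains, x, config)
          if (max(abs(s), na.rm = TRUE) < fp_tol) {
            resolved <- "fixed_point"; last <- r; break
          }
        }
      }
    }
  }
  keep <- seq_len(last + 1L)
  structure(list(densities = dens[keep, , drop = FALSE],
                 round = 0:last,
                 t_sat = t_sat[seq_len(last)],
                 extinctions = extinct_round,
                 resolved = resolved,
                 strains = strains, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$densities) - 1L
  fin <- x$densities[n + 1L, ]
  cat(sprintf("Serial-dilution trajectory: %d strains, %d rounds (%s)\n",
              ncol(x$densities), n, x$resolved))
  cat("Final densities:\n")
  print(round(fin, 6))
  ext <- x$extinctions[!is.na(x$extinctions)]
  if (length(ext))
    cat("Extinctions:", paste(sprintf("%s@r%d", names(ext), ext),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns `round`, `t_sat`, then one density column per strain label, at
#' full double precision.
#'
#' @param trajectory A [run_serial_dilution()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  n <- length(trajectory$round)
  df <- data.frame(round = trajectory$round,
                   t_sat = c(NA, trajectory$t_sat)[seq_len(n)],
                   trajectory$densities, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Continuous-round ODE approximation of the dynamics
#'
#' Treats the round index r as continuous and integrates either the
#' linearized replicator form `dx_i/dr = x_i * sum_k x_k s_ik(x)` (valid when
#' all selection coefficients are small) or the unapproximated per-round
#' increment `dx_i/dr = x'_i(x) - x_i`, where `x'` is the exactly simulated
#' one-round map. Both vector fields conserve the simplex sum analytically;
#' residual integration drift is renormalized in the output.
#'
#' @inheritParams saturation_time
#' @param r_max Final round (integration horizon).
#' @param method `"linearized"` (default) or `"recurrence"`.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @param sample_every Output step in rounds.
#' @return A `trajectory`-like object with `densities` sampled at rounds
#'   `seq(0, r_max, by = sample_every)`.
#' @export
run_ode_approx <- function(strains, x = uniform_densities(strains), config,
                           r_max, method = c("linearized", "recurrence"),
                           rtol = 1e-8, atol = 1e-10, sample_every = 1) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  method <- match.arg(method)
  deriv <- function(r, y, parms) {
    y <- pmax(y, 0)
    tot <- sum(y)
    if (tot <= 0) return(list(rep(0, length(y))))
    y <- y / tot
    g <- grow_one_round(strains, y, config)
    if (method == "recurrence") {
      dy <- g$densities - y
    } else {
      lfc <- g$log_fold_changes
      # s_ik = lfc_i - lfc_k; sum_k x_k s_ik = lfc_i - sum_k x_k lfc_k
      dy <- y * (lfc - sum(y * lfc))
    }
    list(unname(dy))
  }
  times <- seq(0, r_max, by = sample_every)
  sol <- deSolve::ode(y = unname(x), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    sc_error("ODE integration failed; see deSolve diagnostics", "integration")
  dens <- unname(sol[, -1, drop = FALSE])
  dens <- pmax(dens, 0)
  dens <- dens / rowSums(dens)
  colnames(dens) <- strains$label
  structure(list(densities = dens, round = times,
                 t_sat = rep(NA_real_, length(times) - 1L),
                 extinctions = stats::setNames(rep(NA_integer_, nrow(strains)),
                                               strains$label),
                 resolved = "ode", strains = strains, config = config),
            class = "trajectory")
}

#' Detect a fixed point at the end of a trajectory
#'
#' A state qualifies as a fixed point only if both criteria hold: the
#' maximum round-to-round density change over the trailing window is below
#' `tol` (density stasis) and every pairwise exact selection coefficient at
#' the final state is below `tol` in magnitude. Requiring both avoids
#' misclassifying slow transients as fixed points.
#'
#' @param trajectory A [run_serial_dilution()] result.
#' @param window Number of trailing rounds to test for stasis.
#' @param tol Tolerance for both criteria.
#' @return List with `fixed` (logical), `densities` (final state), and the
#'   two measured criteria `max_density_change` and `max_abs_selection`.
#' @export
detect_fixed_point <- function(trajectory, window = 100L, tol = 1e-8) {
  dens <- trajectory$densities
  n <- nrow(dens)
  if (n - 1L < window)
    sc_error("trajectory shorter than the detection window", "validation")
  win <- dens[(n - window):n, , drop = FALSE]
  dmax <- max(abs(diff(win)))
  x_fin <- dens[n, ]
  s <- selection_matrix(trajectory$strains, x_fin, trajectory$config)
  smax <- if (all(is.na(s))) 0 else max(abs(s), na.rm = TRUE)
  list(fixed = dmax < tol && smax < tol,
       densities = x_fin,
       max_density_change = dmax,
       max_abs_selection = smax)
}

#' Map basins of attraction over the 3-strain simplex
#'
#' For every point of a regular grid on the 2-simplex of initial densities,
#' runs the serial-dilution dynamics (with early stopping) and records the
#' outcome: the winning strain's label, or the `+`-joined labels of the
#' coexisting survivors.
#'
#' @param strains Strain table with exactly 3 strains.
#' @param config A [competition_config()].
#' @param grid_resolution Number of subdivisions per simplex edge, `>= 2`.
#' @param n_rounds Round cap per grid point.
#' @return A data frame with columns `x1`, `x2`, `x3` (initial densities,
#'   named after the strains) and `outcome`.
#' @export
basin_map <- function(strains, config, grid_resolution, n_rounds) {
  validate_strains(strains)
  if (nrow(strains) != 3L)
    sc_error("basin_map requires exactly 3 strains", "validation")
  if (grid_resolution < 2L)
    sc_error("grid_resolution must be >= 2", "validation")
  g <- grid_resolution
  pts <- list(); out <- character()
  for (a in 0:g) for (b in 0:(g - a)) {
    x0 <- c(a, b, g - a - b) / g
    present <- x0 > 0
    if (sum(present) == 1L) {
      res <- strains$label[present]
    } else {
      sub <- strains[present, , drop = FALSE]
      class(sub) <- c("strain_table", "data.frame")
      tr <- run_serial_dilution(sub, x0[present] / sum(x0[present]), config,
                                n_rounds, stop_on_resolution = TRUE)
      fin <- tr$densities[nrow(tr$densities), ]
      surv <- sub$label[fin > config$extinction_threshold]
      res <- paste(sort(surv), collapse = "+")
    }
    pts[[length(pts) + 1L]] <- x0
    out <- c(out, res)
  }
  grid <- do.call(rbind, pts)
  df <- data.frame(grid, outcome = out, stringsAsFactors = FALSE)
  names(df)[1:3] <- paste0("x", 1:3)
  attr(df, "strain_labels") <- strains$label
  df
}
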