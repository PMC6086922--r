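#' Fit the lag-growth tradeoff line
#'
#' Neutral coexistence of many strains requires their lag and growth times
#' to fall on a common line `lag = -c * growth_time + intercept` with
#' tradeoff slope magnitude `c > 0`. This fits that line by least squares
#' and reports the worst residual; for exactly two strains the pairwise
#' slope `c_ij = -d_lag/d_tau` is exact. A fitted `c <= 0` indicates a
#' lag-growth synergy rather than a tradeoff and is flagged.
#'
#' @param strains Strain table with at least 2 strains of distinct growth
#'   times.
#' @param tol Absolute residual tolerance deciding the `collinear` flag. The
#'   default scales `1e-9` by the lag-time spread (or 1 if the lags are all
#'   equal).
#' @return List of class `tradeoff_fit`: `c` (slope magnitude), `intercept`,
#'   `max_residual`, `collinear`, `synergy` (`TRUE` when `c <= 0`).
#' @export
fit_tradeoff <- function(strains, tol = NULL) {
  validate_strains(strains)
  if (nrow(strains) < 2L)
    sc_error("tradeoff fit needs at least 2 strains", "validation")
  tau <- strains$growth_time; lag <- strains$lag
  if (diff(range(tau)) == 0)
    sc_error("tradeoff fit degenerate: all growth times equal",
             "degenerate_fit")
  if (is.null(tol)) tol <- 1e-9 * max(diff(range(lag)), 1)
  if (nrow(strains) == 2L) {
    slope <- (lag[2] - lag[1]) / (tau[2] - tau[1])
    intercept <- lag[1] - slope * tau[1]
    resid <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, tau), lag)
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
    resid <- max(abs(fit$residuals))
  }
  structure(list(c = unname(-slope), intercept = unname(intercept),
                 max_residual = resid, collinear = resid < tol,
                 synergy = unname(-slope) <= 0, tol = tol),
            class = "tradeoff_fit")
}

#' Resource-density window for neutral coexistence
#'
#' For strains sharing an exact lag-growth tradeoff with slope `c > 0`, a
#' community fixed point exists when the effective yield can reach its
#' critical value `exp(c)/rho`, which requires the resource density to lie
#' in the open window `(exp(c)/max(Y), exp(c)/min(Y))`. The hard floor
#' `rho > 1/min(Y)` (below it some strains cannot grow at all) is always
#' below the window's upper bound because `c > 0`, so a viable window always
#' exists above the floor.
#'
#' @inheritParams fit_tradeoff
#' @return List of class `rho_window`: `lower`, `upper` (open interval),
#'   `floor` (`1/min(Y)`), `c`, `intercept`, `degenerate` (`TRUE` when all
#'   yields are equal, collapsing the window to a point).
#' @export
coexistence_rho_window <- function(strains, tol = NULL) {
  fit <- fit_tradeoff(strains, tol)
  if (!fit$collinear)
    sc_error("no coexistence window: strains are not collinear in (tau, lag)",
             "no_window")
  if (fit$synergy)
    sc_error("no coexistence window: lag-growth slope is not a tradeoff (c <= 0)",
             "no_window")
  y <- strains$yield
  structure(list(lower = exp(fit$c) / max(y), upper = exp(fit$c) / min(y),
                 floor = 1 / min(y), c = fit$c, intercept = fit$intercept,
                 degenerate = max(y) == min(y)),
            class = "rho_window")
}

#' @export
print.rho_window <- function(x, ...) {
  cat(sprintf("Coexistence window: rho in (%.6g, %.6g)%s\n", x$lower, x$upper,
              if (x$degenerate) " [degenerate: all yields equal]" else ""))
  cat(sprintf("  lag-growth tradeoff c = %.6g, growth floor rho > %.6g\n",
              x$c, x$floor))
  invisible(x)
}

rho_in_window <- function(rho, window) {
  !window$degenerate && rho > window$lower && rho < window$upper
}

#' Fixed-point space of a neutrally coexisting community
#'
#' At a fixed point of collinear strains the effective yield equals its
#' critical value `exp(c)/rho`, so the densities satisfy the two affine
#' constraints `sum(x) = 1` and `sum(x/Y) = rho * exp(-c)` restricted to
#' `x >= 0`. For `M` strains with unequal yields this feasible set has
#' dimension `M - 2` (for `M = 2`, a unique density pair). The polytope's
#' vertices are the two-strain basic solutions whose yields straddle the
#' critical effective yield; an interior point is their average.
#'
#' @param strains Collinear strain table.
#' @param rho Resource density.
#' @param tol Collinearity tolerance, passed to [fit_tradeoff()].
#' @return List of class `fixed_point_space`: `feasible`, `dimension`
#'   (numeric: `M` minus the rank of the constraint matrix; `NA` when
#'   infeasible), `constraints` (list `A`, `b`), `interior` (a feasible
#'   interior density vector, or `NULL`), `vertices` (matrix, one row per
#'   polytope vertex), `window`.
#' @export
fixed_point_space <- function(strains, rho, tol = NULL) {
  validate_strains(strains)
  window <- coexistence_rho_window(strains, tol)
  m <- nrow(strains)
  y <- strains$yield
  a_mat <- rbind(rep(1, m), 1 / y)
  b <- c(1, rho * exp(-window$c))
  if (!rho_in_window(rho, window))
    return(structure(list(feasible = FALSE, dimension = NA_integer_,
                          constraints = list(A = a_mat, b = b),
                          interior = NULL, vertices = NULL, window = window),
                     class = "fixed_point_space"))
  target <- rho * exp(-window$c)   # required value of sum(x/Y)
  verts <- list()
  for (a in seq_len(m - 1L)) for (bb in (a + 1L):m) {
    iy_a <- 1 / y[a]; iy_b <- 1 / y[bb]
    if (iy_a == iy_b) next
    xa <- (target - iy_b) / (iy_a - iy_b)
    if (xa > 0 && xa < 1) {
      v <- rep(0, m); v[a] <- xa; v[bb] <- 1 - xa
      verts[[length(verts) + 1L]] <- v
    }
  }
  vertices <- do.call(rbind, verts)
  colnames(vertices) <- strains$label
  interior <- colMeans(vertices)
  rank <- qr(a_mat)$rank
  structure(list(feasible = TRUE, dimension = m - rank,
                 constraints = list(A = a_mat, b = b),
                 interior = interior, vertices = vertices, window = window),
            class = "fixed_point_space")
}

#' Sample random points of a fixed-point space
#'
#' Random convex combinations (Dirichlet weights) of the polytope vertices;
#' every sample satisfies both affine constraints and `x >= 0`.
#'
#' @param fps A feasible [fixed_point_space()].
#' @param n Number of samples.
#' @return Matrix with `n` rows of densities.
#' @export
sample_fixed_points <- function(fps, n) {
  if (!isTRUE(fps$feasible))
    sc_error("fixed-point space is empty for this rho", "validation")
  v <- fps$vertices
  w <- matrix(stats::rexp(n * nrow(v)), n, nrow(v))
  w <- w / rowSums(w)
  pts <- w %*% v
  colnames(pts) <- colnames(v)
  pts
}

#' Identify keystone strains of a coexisting community
#'
#' Strain k is a keystone if removing it leaves `rho` outside the
#' coexistence window of the remaining strains, so its loss collapses the
#' community (all but one of the others go extinct). Because the window
#' bounds depend only on the extreme yields, a keystone is necessarily the
#' least-efficient (minimum yield) or most-efficient (maximum yield) strain;
#' for `rho` in the central part of the window the community is robust and
#' the set is empty.
#'
#' @param strains Collinear strain table with `>= 3` strains.
#' @param rho Resource density, inside the community's window.
#' @param tol Collinearity tolerance.
#' @return Character vector of keystone labels (possibly empty).
#' @export
keystone_strains <- function(strains, rho, tol = NULL) {
  validate_strains(strains)
  if (nrow(strains) < 3L)
    sc_error("keystone analysis needs at least 3 strains", "validation")
  window <- coexistence_rho_window(strains, tol)
  if (!rho_in_window(rho, window))
    sc_error("rho is outside the community's coexistence window", "validation")
  keystones <- character()
  for (k in seq_len(nrow(strains))) {
    rest <- strains[-k, , drop = FALSE]
    class(rest) <- c("strain_table", "data.frame")
    wk <- coexistence_rho_window(rest, tol)
    if (!rho_in_window(rho, wk))
      keystones <- c(keystones, strains$label[k])
  }
  keystones
}

#' Predict and simulate the fate of an invading strain
#'
#' Residents neutrally coexisting on a lag-growth tradeoff line define a
#' diagonal in (growth time, lag) trait space. An invader above the line is
#' predicted to go extinct (even if it has the shortest lag or growth time
#' of all); below the line it takes over or, close enough to the line,
#' coexists with exactly one resident; on the line it joins the neutral set.
#' The prediction is verified by simulation from a small invader density,
#' and the simulated outcome is authoritative.
#'
#' @param residents Collinear strain table of coexisting residents.
#' @param invader Single-row strain table.
#' @param rho Resource density inside the residents' window.
#' @param config A [competition_config()] (its `rho` is ignored in favor of
#'   the `rho` argument).
#' @param x_invader Initial invader density (default `1e-6`).
#' @param max_rounds Simulation cap.
#' @param line_tol Distance from the line treated as exactly on it.
#' @return List: `geometric` (prediction: `"extinct"`,
#'   `"takeover_or_coexist"`, or `"neutral_marginal"`), `simulated`
#'   (`"extinct"`, `"takeover"`, `"coexist_with_one"`, or `"neutral"`),
#'   `agree`, `deviation` (signed vertical trait-space distance from the
#'   line), and the final `trajectory`.
#' @export
invasion_outcome <- function(residents, invader, rho, config,
                             x_invader = 1e-6, max_rounds = 50000L,
                             line_tol = 1e-9) {
  validate_strains(residents)
  validate_strains(invader)
  if (nrow(invader) != 1L)
    sc_error("invader must be a single strain", "validation")
  fps <- fixed_point_space(residents, rho)
  if (!fps$feasible)
    sc_error("residents do not coexist at this rho", "validation")
  window <- fps$window
  dev <- invader$lag - (window$intercept - window$c * invader$growth_time)
  geometric <- if (abs(dev) <= line_tol * max(1, abs(window$intercept)))
    "neutral_marginal"
  else if (dev > 0) "extinct" else "takeover_or_coexist"

  combined <- rbind(as.data.frame(residents), as.data.frame(invader))
  class(combined) <- c("strain_table", "data.frame")
  validate_strains(combined)
  x0 <- c(unname(fps$interior) * (1 - x_invader), x_invader)
  cfg <- config
  cfg$rho <- rho
  tr <- run_serial_dilution(combined, x0 / sum(x0), cfg, max_rounds,
                            stop_on_resolution = TRUE)
  fin <- tr$densities[nrow(tr$densities), ]
  inv_label <- invader$label
  survivors <- combined$label[fin > cfg$extinction_threshold]
  simulated <- if (!(inv_label %in% survivors)) "extinct"
  else if (identical(survivors, inv_label)) "takeover"
  else if (length(survivors) == 2L) "coexist_with_one"
  else "neutral"
  agree <- switch(geometric,
                  extinct = simulated == "extinct",
                  takeover_or_coexist = simulated %in%
                    c("takeover", "coexist_with_one"),
                  neutral_marginal = simulated %in%
                    c("neutral", "coexist_with_one"))
  list(geometric = geometric, simulated = simulated, agree = agree,
       deviation = unname(dev), survivors = survivors, trajectory = tr)
}

#' Round-robin pairwise tournament
#'
#' Simulates every pair from equal initial densities (1/2 each) until one
#' strain goes extinct or a fixed point is reached, capped at `max_rounds`
#' (unresolved pairs are labeled `conditional`). A strain winning all its
#' pairs is the champion; a directed cycle among winners (i beats j beats k
#' beats i) marks the set as non-transitive.
#'
#' @param strains Strain table with `>= 2` strains.
#' @param rho Resource density (held fixed for every pair).
#' @param config A [competition_config()].
#' @param max_rounds Per-pair round cap.
#' @return List of class `tournament`: `outcomes` (data frame of pairs),
#'   `matrix` (character outcome matrix: winner label, `"coexist"`, or
#'   `"conditional"`), `classification` (`"champion"`,
#'   `"nontransitive_cycle"`, or `"conditional"`), `champion` (label or
#'   `NA`), `cycles` (list of label triples).
#' @export
pairwise_tournament <- function(strains, rho, config, max_rounds = 100000L) {
  validate_strains(strains)
  m <- nrow(strains)
  if (m < 2L) sc_error("tournament needs at least 2 strains", "validation")
  cfg <- config
  cfg$rho <- rho
  labels <- strains$label
  outm <- matrix(NA_character_, m, m, dimnames = list(labels, labels))
  rows <- list()
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    pair <- strains[c(a, b), , drop = FALSE]
    class(pair) <- c("strain_table", "data.frame")
    tr <- run_serial_dilution(pair, c(0.5, 0.5), cfg, max_rounds,
                              stop_on_resolution = TRUE)
    fin <- tr$densities[nrow(tr$densities), ]
    surv <- pair$label[fin > cfg$extinction_threshold]
    res <- if (length(surv) == 1L) surv
    else if (tr$resolved == "fixed_point") "coexist"
    else "conditional"
    outm[a, b] <- res; outm[b, a] <- res
    rows[[length(rows) + 1L]] <-
      data.frame(i = labels[a], j = labels[b], outcome = res,
                 rounds = max(tr$round), stringsAsFactors = FALSE)
  }
  wins <- matrix(FALSE, m, m, dimnames = list(labels, labels))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b && !is.na(outm[a, b]) && outm[a, b] == labels[a])
      wins[a, b] <- TRUE
  }
  champ <- labels[vapply(seq_len(m),
                         function(a) all(wins[a, -a]), logical(1))]
  cycles <- list()
  if (m >= 3L) {
    for (a in seq_len(m)) for (b in seq_len(m)) for (cc in seq_len(m)) {
      if (a < b || a < cc) next  # canonical rotation: a is the largest index
      if (length(unique(c(a, b, cc))) == 3L &&
          wins[a, b] && wins[b, cc] && wins[cc, a])
        cycles[[length(cycles) + 1L]] <- labels[c(a, b, cc)]
    }
  }
  classification <- if (length(champ) == 1L) "champion"
  else if (length(cycles)) "nontransitive_cycle"
  else "conditional"
  structure(list(outcomes = do.call(rbind, rows), matrix = outm,
                 classification = classification,
                 champion = if (length(champ) == 1L) champ else NA_character_,
                 cycles = cycles),
            class = "tournament")
}

#' @export
print.tournament <- function(x, ...) {
  cat("Pairwise tournament:", x$classification)
  if (!is.na(x$champion)) cat(" (champion:", x$champion, ")")
  cat("\n")
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Compare the pairwise champion with the mixed-competition outcome
#'
#' Runs the full tournament and a single mixed competition of all strains
#' from equal densities, then reports whether the pairwise champion (if any)
#' survives the mixed run, and for every pair whether the exact selection
#' coefficient changes sign between the pair-alone context (densities 1/2
#' each) and the mixed context (densities 1/M each). Sign changes are the
#' signature of higher-order effects: the presence of other strains alters
#' selection within the pair.
#'
#' @inheritParams pairwise_tournament
#' @param max_rounds Round cap for both tournament pairs and the mixed run.
#' @return List: `tournament`, `mixed_survivors`, `champion`,
#'   `champion_survives_mixed` (`NA` when there is no champion),
#'   `discrepancy`, `sign_changes` (data frame of per-pair s values in both
#'   contexts).
#' @export
mixed_vs_pairwise_report <- function(strains, rho, config,
                                     max_rounds = 100000L) {
  validate_strains(strains)
  if (nrow(strains) < 2L)
    sc_error("report needs at least 2 strains", "validation")
  cfg <- config
  cfg$rho <- rho
  tour <- pairwise_tournament(strains, rho, config, max_rounds)
  tr <- run_serial_dilution(strains, uniform_densities(strains), cfg,
                            max_rounds, stop_on_resolution = TRUE)
  fin <- tr$densities[nrow(tr$densities), ]
  mixed_survivors <- strains$label[fin > cfg$extinction_threshold]
  m <- nrow(strains)
  rows <- list()
  x_mixed <- uniform_densities(strains)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    pair <- strains[c(a, b), , drop = FALSE]
    class(pair) <- c("strain_table", "data.frame")
    s_pair <- selection_exact(pair$label[1], pair$label[2], pair,
                              c(0.5, 0.5), cfg)
    s_mix <- selection_exact(strains$label[a], strains$label[b], strains,
                             x_mixed, cfg)
    rows[[length(rows) + 1L]] <-
      data.frame(i = strains$label[a], j = strains$label[b],
                 s_pair_alone = s_pair, s_mixed = s_mix,
                 sign_changed = sign(s_pair) != sign(s_mix),
                 stringsAsFactors = FALSE)
  }
  champion <- tour$champion
  champion_survives <- if (is.na(champion)) NA else champion %in% mixed_survivors
  list(tournament = tour, mixed_survivors = mixed_survivors,
       champion = champion, champion_survives_mixed = champion_survives,
       discrepancy = isTRUE(!champion_survives),
       sign_changes = do.call(rbind, rows), mixed_trajectory = tr)
}

#' Classify the stability of a coexisting community's fixed point
#'
#' Numerically probes the fixed point by perturbing the interior fixed-point
#' densities orthogonally to the fixed-point affine space (along the
#' simplex-tangent projection of `1/Y`, the direction that changes the
#' effective yield) and simulating. If the constraint residual
#' `sum(x/Y) - rho*exp(-c)` decays for both perturbation signs the community
#' is neutrally coexisting (fluctuations within the space are neutral,
#' orthogonal ones relax back); if the perturbed runs diverge toward
#' distinct attractors or lose strains, it is multistable. The analytic
#' predictor — the sign of the rank correlation between growth time and
#' yield (tradeoff: slower growers more efficient, predicts neutral;
#' synergy predicts multistable) — is reported alongside with an agreement
#' flag.
#'
#' @param strains Collinear strain table.
#' @param rho Resource density inside the window.
#' @param config A [competition_config()].
#' @param perturbation Density perturbation magnitude (default `1e-3`),
#'   reduced automatically if needed to keep densities positive.
#' @param n_rounds Rounds to simulate each perturbed start.
#' @return List of class `stability_report`: `class` (one of
#'   `"neutral_coexistence"`, `"multistable"`, `"none"`), `predictor`
#'   (same levels, from the growth-yield rank correlation), `agree`,
#'   `residual_initial`, `residual_final` (per perturbation sign),
#'   `extinctions` (any strain lost in either run).
#' @export
classify_stability <- function(strains, rho, config, perturbation = 1e-3,
                               n_rounds = 3000L) {
  validate_strains(strains)
  fps <- tryCatch(fixed_point_space(strains, rho),
                  serialcoex_no_window_error = function(e) NULL)
  if (is.null(fps) || !fps$feasible)
    return(structure(list(class = "none", predictor = "none", agree = NA),
                     class = "stability_report"))
  cfg <- config
  cfg$rho <- rho
  x_star <- fps$interior
  y <- strains$yield
  v <- 1 / y - mean(1 / y)           # simplex-tangent, changes sum(x/Y)
  v <- v / sqrt(sum(v^2))
  eps <- min(perturbation, 0.45 * min(x_star) / max(abs(v)))
  target <- rho * exp(-fps$window$c)
  resid <- function(x) sum(x / y) - target
  runs <- lapply(c(1, -1), function(sgn) {
    x0 <- x_star + sgn * eps * v
    x0 <- x0 / sum(x0)
    tr <- run_serial_dilution(strains, x0, cfg, n_rounds,
                              stop_on_resolution = TRUE)
    fin <- tr$densities[nrow(tr$densities), ]
    list(r0 = resid(x_star + sgn * eps * v), r1 = resid(fin),
         fin = fin, extinct = strains$label[fin <= cfg$extinction_threshold])
  })
  r0 <- vapply(runs, function(r) abs(r$r0), numeric(1))
  r1 <- vapply(runs, function(r) abs(r$r1), numeric(1))
  lost <- unique(unlist(lapply(runs, `[[`, "extinct")))
  decayed <- all(r1 < 0.5 * r0) && length(lost) == 0L
  diverged <- length(lost) > 0L || any(r1 > 2 * r0)
  cls <- if (decayed) "neutral_coexistence"
  else if (diverged) "multistable" else "none"
  rc <- suppressWarnings(stats::cor(strains$growth_time, strains$yield,
                                    method = "spearman"))
  predictor <- if (is.na(rc) || rc == 0) "none"
  else if (rc > 0) "neutral_coexistence" else "multistable"
  structure(list(class = cls, predictor = predictor,
                 agree = cls == predictor,
                 residual_initial = r0, residual_final = r1,
                 extinctions = lost,
                 finals = lapply(runs, `[[`, "fin")),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability class:", x$class, "\n")
  if (!is.null(x$predictor))
    cat("Growth-yield predictor:", x$predictor,
        if (isTRUE(x$agree)) "(agrees)" else "(disagrees)", "\n")
  invisible(x)
}

#' Full coexistence report for a strain set
#'
#' Convenience wrapper assembling the tradeoff fit, coexistence window,
#' fixed-point space, keystone set, and stability class into one object
#' (serializable to JSON).
#'
#' @param strains Strain table.
#' @param rho Resource density.
#' @param config A [competition_config()].
#' @param tol Collinearity tolerance.
#' @return List of class `coexistence_report`.
#' @export
coexistence_report <- function(strains, rho, config, tol = NULL) {
  validate_strains(strains)
  fit <- fit_tradeoff(strains, tol)
  window <- tryCatch(coexistence_rho_window(strains, tol),
                     serialcoex_no_window_error = function(e) NULL)
  in_window <- !is.null(window) && rho_in_window(rho, window)
  fps <- if (in_window) fixed_point_space(strains, rho, tol) else NULL
  keystones <- if (in_window && nrow(strains) >= 3L)
    keystone_strains(strains, rho, tol) else character()
  stability <- if (in_window)
    classify_stability(strains, rho, config)
  else structure(list(class = "none", predictor = "none", agree = NA),
                 class = "stability_report")
  structure(list(tradeoff = fit, rho = rho, window = window,
                 rho_in_window = in_window,
                 critical_effective_yield = if (!is.null(window))
                   exp(window$c) / rho else NA_real_,
                 fixed_point_space = fps, keystones = keystones,
                 stability_class = stability$class, stability = stability),
            class = "coexistence_report")
}

#' @export
print.coexistence_report <- function(x, ...) {
  cat(sprintf("Coexistence report (rho = %.6g)\n", x$rho))
  cat(sprintf("  tradeoff c = %.6g, collinear = %s\n", x$tradeoff$c,
              x$tradeoff$collinear))
  if (!is.null(x$window))
    cat(sprintf("  window (%.6g, %.6g), rho in window: %s\n",
                x$window$lower, x$window$upper, x$rho_in_window))
  cat(sprintf("  keystones: %s\n",
              if (length(x$keystones)) paste(x$keystones, collapse = ", ")
              else "none"))
  cat(sprintf("  stability: %s\n", x$stability_class))
  invisible(x)
}
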