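#' Specification for a synthetic strain ensemble
#'
#' Describes a family of strains placed on (or scattered around) a common
#' lag-growth tradeoff line `lag = -c * growth_time + intercept`, with
#' yields coupled to growth time by a rank-based rule. Units are arbitrary
#' but consistent; the model is invariant under a common rescaling of all
#' times.
#'
#' @param n_strains Number of strains, `>= 2`.
#' @param c Tradeoff slope magnitude, `> 0`.
#' @param intercept Lag-axis intercept of the line; together with
#'   `tau_range` it must keep all lags non-negative.
#' @param tau_range Interval of growth times, e.g. `c(0.5, 5)`.
#' @param yield_spec Either an explicit numeric vector of `n_strains`
#'   yields, or a list `list(rule = , range = )` with rule `"tradeoff"`
#'   (yield increases with growth time: slower growers are more efficient),
#'   `"synergy"` (yield decreases with growth time), or `"uncorrelated"`
#'   (random assignment); yields are log-spaced across `range`.
#' @param noise_sigma Gaussian scatter (time units) of the lags off the
#'   line; `0` gives exact collinearity.
#' @param spacing `"even"` growth times across `tau_range`, or `"random"`.
#' @param seed Integer seed; identical specs give identical ensembles.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_strains, c, intercept, tau_range = c(0.5, 5),
                          yield_spec = list(rule = "tradeoff",
                                            range = c(1e3, 1e7)),
                          noise_sigma = 0, spacing = c("even", "random"),
                          seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_strains < 2L) sc_error("n_strains must be >= 2", "validation")
  if (!is.finite(c) || c <= 0)
    sc_error("tradeoff slope c must be > 0", "validation")
  if (length(tau_range) != 2L || tau_range[1] <= 0 ||
      tau_range[2] <= tau_range[1])
    sc_error("tau_range must be an increasing positive interval", "validation")
  if (noise_sigma < 0) sc_error("noise_sigma must be >= 0", "validation")
  if (is.numeric(yield_spec)) {
    if (length(yield_spec) != n_strains || any(yield_spec <= 0))
      sc_error("explicit yields must be n_strains positive values",
               "validation")
  } else if (!is.list(yield_spec) ||
             !yield_spec$rule %in% c("tradeoff", "synergy", "uncorrelated")) {
    sc_error("yield_spec must be explicit yields or a rule list", "validation")
  }
  # The line must keep lags non-negative over the noiseless tau range.
  if (intercept - c * tau_range[2] < 0)
    sc_error("infeasible spec: lag = -c*tau + intercept is negative at max tau",
             "validation")
  structure(list(n_strains = as.integer(n_strains), c = c,
                 intercept = intercept, tau_range = tau_range,
                 yield_spec = yield_spec, noise_sigma = noise_sigma,
                 spacing = spacing, seed = seed),
            class = "ensemble_spec")
}

#' Generate a strain ensemble from a specification
#'
#' Growth times are spread across `tau_range` (evenly, or uniformly sampled
#' and sorted); lags follow the tradeoff line plus Gaussian noise; yields
#' follow the rank-based coupling rule. Deterministic under the spec's seed.
#'
#' @param spec An [ensemble_spec()].
#' @return A [strain_table()] of `n_strains` strains labeled `S1..Sn`.
#' @export
generate_ensemble <- function(spec) {
  if (!inherits(spec, "ensemble_spec"))
    sc_error("spec must be an ensemble_spec", "validation")
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  n <- spec$n_strains
  tau <- if (spec$spacing == "even")
    seq(spec$tau_range[1], spec$tau_range[2], length.out = n)
  else sort(stats::runif(n, spec$tau_range[1], spec$tau_range[2]))
  lag <- -spec$c * tau + spec$intercept
  if (spec$noise_sigma > 0)
    lag <- lag + stats::rnorm(n, 0, spec$noise_sigma)
  if (any(lag < 0))
    sc_error("infeasible spec: noise drove a lag time negative", "validation")
  ys <- spec$yield_spec
  if (is.numeric(ys)) {
    yield <- ys
  } else {
    levels <- exp(seq(log(ys$range[1]), log(ys$range[2]), length.out = n))
    yield <- switch(ys$rule,
                    tradeoff = levels,           # tau ascending -> Y ascending
                    synergy = rev(levels),
                    uncorrelated = sample(levels))
  }
  strain_table(paste0("S", seq_len(n)), lag, tau, yield)
}

#' Pick a resource density inside the coexistence window
#'
#' Linear interpolation between the window bounds: `position` near 0 or 1
#' lands in the keystone sub-windows adjacent to the extreme-yield strains,
#' mid positions in the robust central region.
#'
#' @param strains Collinear strain table.
#' @param position Fraction in `(0, 1)`.
#' @return A `rho` value strictly inside the window.
#' @export
pick_rho <- function(strains, position) {
  if (position <= 0 || position >= 1)
    sc_error("position must lie strictly in (0, 1)", "validation")
  w <- coexistence_rho_window(strains)
  if (w$degenerate)
    sc_error("coexistence window is empty (all yields equal)", "validation")
  w$lower + position * (w$upper - w$lower)
}

# Pair outcome pre-screen: sign of the exact selection coefficient of strain
# 1 over strain 2 along a density grid. Constant sign predicts a
# deterministic winner; a sign change predicts coexistence or bistability.
pair_selection_profile <- function(pair, rho, config,
                                   grid = c(0.02, 0.1, 0.25, 0.5,
                                            0.75, 0.9, 0.98)) {
  cfg <- config
  cfg$rho <- rho
  vapply(grid, function(x1)
    tryCatch(selection_exact(pair$label[1], pair$label[2], pair,
                             c(x1, 1 - x1), cfg),
             serialcoex_error = function(e) NA_real_), numeric(1))
}

# Predicted winner of a pair started from equal densities: the strain
# favored at 1/2, provided selection keeps favoring it along its own
# increasing path (selection is frequency dependent, so a strain may win
# from 1/2 while unable to invade from rarity).
pair_winner_from_half <- function(pair, rho, config) {
  cfg <- config
  cfg$rho <- rho
  s_at <- function(x1)
    tryCatch(selection_exact(pair$label[1], pair$label[2], pair,
                             c(x1, 1 - x1), cfg),
             serialcoex_error = function(e) NA_real_)
  s_half <- s_at(0.5)
  if (is.na(s_half) || s_half == 0) return(NA_character_)
  path <- if (s_half > 0) c(0.75, 0.95, 0.995) else c(0.25, 0.05, 0.005)
  s_path <- vapply(path, s_at, numeric(1))
  if (anyNA(s_path) || any(sign(s_path) != sign(s_half)))
    return("frequency_dependent")
  if (s_half > 0) pair$label[1] else pair$label[2]
}

# Equal-density harmonic-mean yield of a pair; sets the pair's effective
# log(rho * Y_bar) at the start of an equal-density competition.
pair_half_yield <- function(y1, y2) 2 / (1 / y1 + 1 / y2)

#' Search for a strain set exhibiting a named competition phenomenon
#'
#' Randomized rejection search over trait space, guided by qualitative
#' pre-filters, with full simulation-based verification before anything is
#' returned:
#' \describe{
#'   \item{`"pairwise_champion_loses"`}{A short-lag, slow-growing, low-yield
#'     "hoarding" strain that beats each of two efficient fast growers
#'     one-on-one but goes extinct when all three are mixed, with at least
#'     one pairwise selection coefficient changing sign in the three-strain
#'     context.}
#'   \item{`"nontransitive_triple"`}{A rock-paper-scissors triple (each
#'     strain beats one and loses to another at equal-density pairwise
#'     starts) whose mixed-competition winner depends on the initial
#'     densities.}
#'   \item{`"bistable_pair"`}{Two strains on a lag-growth tradeoff line with
#'     a growth-yield synergy and rho inside the pair's window, so that
#'     whichever strain starts common excludes the other and invasions fail
#'     both ways.}
#' }
#'
#' @param kind Scenario name (see above).
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param max_tries Candidate draws before giving up.
#' @param config Base [competition_config()]; the searched `rho` overrides
#'   its `rho`.
#' @param max_rounds Verification round cap.
#' @return List: `strains`, `rho`, `kind`, `tries`, and `verification`
#'   (scenario-specific evidence from the verifying simulations).
#' @export
search_scenario <- function(kind = c("pairwise_champion_loses",
                                     "nontransitive_triple",
                                     "bistable_pair"),
                            seed = 1L, max_tries = 400L,
                            config = competition_config(rho = 1),
                            max_rounds = 30000L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  for (try_ in seq_len(max_tries)) {
    cand <- switch(kind,
                   pairwise_champion_loses = draw_champion_loses(),
                   nontransitive_triple = draw_nontransitive(),
                   bistable_pair = draw_bistable())
    if (is.null(cand)) next
    ver <- switch(kind,
                  pairwise_champion_loses =
                    verify_champion_loses(cand, config, max_rounds),
                  nontransitive_triple =
                    verify_nontransitive(cand, config, max_rounds),
                  bistable_pair = verify_bistable(cand, config, max_rounds))
    if (!is.null(ver))
      return(list(strains = cand$strains, rho = cand$rho, kind = kind,
                  tries = try_, verification = ver))
  }
  sc_error(sprintf("scenario search failed: no verified '%s' in %d tries",
                   kind, max_tries), "search_failure")
}

# --- candidate generators -------------------------------------------------
# Trait ranges: lag in [0, 10], tau in [0.5, 5], yields log-uniform in
# [1e3, 1e7]; the model is unit-free, so these wide arbitrary ranges cover
# the qualitative regimes.

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

draw_champion_loses <- function() {
  # Hoarder G: shortest lag, slowest growth, lowest yield.
  # Efficient fast growers B, O: longer lags, faster growth, higher yields.
  # G beats each one-on-one iff log(rho * Ybar_pair) stays below the pair
  # tradeoff c_G. = d_lag/d_tau; in the mixed start the extra efficient
  # strain raises the effective yield, pushing log(rho * Ybar) above that
  # threshold, so rho is placed just below the binding pairwise threshold.
  tau_g <- runif1(2.5, 5)
  tau_b <- runif1(0.5, 1.5)
  tau_o <- runif1(0.5, 1.5)
  lag_g <- runif1(0, 1)
  lag_b <- lag_g + runif1(0.5, 4)
  lag_o <- lag_g + runif1(0.5, 4)
  c_gb <- (lag_b - lag_g) / (tau_g - tau_b)
  c_go <- (lag_o - lag_g) / (tau_g - tau_o)
  # the two pairwise thresholds must be close for one rho to straddle both
  if (abs(c_gb - c_go) > 0.2) return(NULL)
  y_g <- exp(runif1(log(1e3), log(1e4)))
  y_b <- y_g * exp(runif1(log(5), log(100)))
  y_o <- y_g * exp(runif1(log(5), log(100)))
  strains <- strain_table(c("G", "B", "O"),
                          lag = c(lag_g, lag_b, lag_o),
                          growth_time = c(tau_g, tau_b, tau_o),
                          yield = c(y_g, y_b, y_o))
  margin <- runif1(0.02, 0.12)
  log_rho <- min(c_gb - log(pair_half_yield(y_g, y_b)),
                 c_go - log(pair_half_yield(y_g, y_o))) - margin
  rho <- exp(log_rho)
  if (rho * min(strains$yield) <= 1.05) return(NULL)
  list(strains = strains, rho = rho)
}

draw_nontransitive <- function() {
  # Rock-paper-scissors pattern: O beats B on lag, G beats O on growth and
  # efficiency, B beats G on lag and hoarding (lower yield). The three
  # equal-density pair conditions bound log(rho) from below (G must outgrow
  # O) and above (lag advantages must carry the other two pairs); a
  # candidate is kept only if that interval is nonempty.
  tau_g <- runif1(0.5, 1.5)
  tau_o <- tau_g + runif1(0.5, 2.5)
  tau_b <- tau_g + runif1(0.2, 3)
  lag_o <- runif1(0, 1.5)
  lag_b <- lag_o + runif1(0.2, 3)
  lag_g <- lag_b + runif1(0.2, 3)
  y_b <- exp(runif1(log(1e3), log(1e5)))
  y_o <- y_b * exp(runif1(log(1.5), log(30)))
  y_g <- y_o * exp(runif1(log(1.5), log(30)))
  # pair thresholds c_ij = d_lag_ij / d_tau_ij at equal densities
  c_go <- (lag_g - lag_o) / (tau_o - tau_g)   # G beats O iff log(rho*Ybar_GO) > c_go
  c_ob <- if (tau_o > tau_b) (lag_b - lag_o) / (tau_o - tau_b) else Inf
  c_bg <- (lag_g - lag_b) / (tau_b - tau_g)   # B beats G iff log(rho*Ybar_BG) < c_bg
  lo <- c_go - log(pair_half_yield(y_g, y_o))
  hi <- min(c_ob - log(pair_half_yield(y_o, y_b)),
            c_bg - log(pair_half_yield(y_b, y_g)))
  if (!is.finite(lo) || lo >= hi) return(NULL)
  rho <- exp((lo + hi) / 2)
  if (rho * min(y_b, y_o, y_g) <= 1.05) return(NULL)
  strains <- strain_table(c("B", "O", "G"),
                          lag = c(lag_b, lag_o, lag_g),
                          growth_time = c(tau_b, tau_o, tau_g),
                          yield = c(y_b, y_o, y_g))
  list(strains = strains, rho = rho)
}

draw_bistable <- function() {
  cc <- runif1(0.5, 2)
  tau <- sort(c(runif1(0.5, 2.5), runif1(0.5, 2.5) + 0.5))
  intercept <- cc * tau[2] + runif1(0.1, 2)
  lag <- -cc * tau + intercept
  y_hi <- exp(runif1(log(1e4), log(1e6)))
  y_lo <- y_hi / exp(runif1(log(2), log(20)))
  # synergy: the faster grower (smaller tau) gets the higher yield
  strains <- strain_table(c("F", "S"), lag = lag, growth_time = tau,
                          yield = c(y_hi, y_lo))
  rho <- exp(cc) / sqrt(y_hi * y_lo) # geometric mid-window
  list(strains = strains, rho = rho)
}

# --- verifiers ------------------------------------------------------------

verify_champion_loses <- function(cand, config, max_rounds) {
  strains <- cand$strains; rho <- cand$rho
  # cheap pre-screens before the expensive simulations: G must be favored
  # from the equal pair start in both pairs, and disfavored on net at the
  # uniform mixed start
  cfg <- config
  cfg$rho <- rho
  for (other in c("B", "O")) {
    pair <- strains[strains$label %in% c("G", other), , drop = FALSE]
    class(pair) <- c("strain_table", "data.frame")
    w <- pair_winner_from_half(pair, rho, config)
    if (is.na(w) || w != "G") return(NULL)
  }
  s_mix <- tryCatch(selection_matrix(strains, uniform_densities(strains), cfg),
                    serialcoex_error = function(e) NULL)
  if (is.null(s_mix) || s_mix["G", "B"] + s_mix["G", "O"] >= 0) return(NULL)
  rep <- tryCatch(mixed_vs_pairwise_report(strains, rho, config, max_rounds),
                  serialcoex_error = function(e) NULL)
  if (is.null(rep)) return(NULL)
  if (!identical(rep$champion, "G")) return(NULL)
  if (!isTRUE(rep$discrepancy)) return(NULL)
  if ("G" %in% rep$mixed_survivors) return(NULL)
  if (!any(rep$sign_changes$sign_changed)) return(NULL)
  list(report = rep)
}

verify_nontransitive <- function(cand, config, max_rounds) {
  strains <- cand$strains; rho <- cand$rho
  # pre-screen the three pair winners from equal starts: need a 3-cycle
  want <- list(c("O", "B", "O"), c("G", "O", "G"), c("B", "G", "B"))
  for (w in want) {
    pair <- strains[match(w[1:2], strains$label), , drop = FALSE]
    class(pair) <- c("strain_table", "data.frame")
    pw <- pair_winner_from_half(pair, rho, config)
    if (is.na(pw) || pw != w[3]) return(NULL)
  }
  tour <- tryCatch(pairwise_tournament(strains, rho, config, max_rounds),
                   serialcoex_error = function(e) NULL)
  if (is.null(tour) || tour$classification != "nontransitive_cycle")
    return(NULL)
  # mixed outcome must depend on initial densities: run from starts biased
  # toward each strain and require at least two distinct winners
  cfg <- config
  cfg$rho <- rho
  winners <- vapply(seq_len(3), function(k) {
    x0 <- rep(0.05, 3)
    x0[k] <- 0.9
    tr <- tryCatch(run_serial_dilution(strains, x0 / sum(x0), cfg, max_rounds,
                                       stop_on_resolution = TRUE),
                   serialcoex_error = function(e) NULL)
    if (is.null(tr)) return(NA_character_)
    fin <- tr$densities[nrow(tr$densities), ]
    surv <- strains$label[fin > cfg$extinction_threshold]
    if (length(surv) == 1L) surv else NA_character_
  }, character(1))
  if (anyNA(winners) || length(unique(winners)) < 2L) return(NULL)
  list(tournament = tour, biased_start_winners = winners)
}

verify_bistable <- function(cand, config, max_rounds) {
  strains <- cand$strains; rho <- cand$rho
  prof <- pair_selection_profile(strains, rho, config)
  if (anyNA(prof)) return(NULL)
  # bistability: the common strain must be favored at both ends
  if (!(prof[1] < 0 && prof[length(prof)] > 0)) return(NULL)
  cfg <- config
  cfg$rho <- rho
  winner_from <- function(x1) {
    tr <- tryCatch(run_serial_dilution(strains, c(x1, 1 - x1), cfg,
                                       max_rounds, stop_on_resolution = TRUE),
                   serialcoex_error = function(e) NULL)
    if (is.null(tr)) return(NA_character_)
    fin <- tr$densities[nrow(tr$densities), ]
    surv <- strains$label[fin > cfg$extinction_threshold]
    if (length(surv) == 1L) surv else NA_character_
  }
  w_hi <- winner_from(0.95)
  w_lo <- winner_from(0.05)
  if (is.na(w_hi) || is.na(w_lo) || w_hi == w_lo) return(NULL)
  if (w_hi != strains$label[1] || w_lo != strains$label[2]) return(NULL)
  list(winner_when_first_common = w_hi, winner_when_second_common = w_lo,
       selection_profile = prof)
}

#' Write a scenario bundle to a directory
#'
#' Writes `strains.csv` (core strain-table format), `config.yaml` (rho,
#' kind, seed), and `verification.json` (the evidence returned by the
#' search).
#'
#' @param scenario A [search_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_strain_table(scenario$strains, file.path(dir, "strains.csv"))
  yaml::write_yaml(list(kind = scenario$kind, rho = scenario$rho,
                        tries = scenario$tries),
                   file.path(dir, "config.yaml"))
  ver <- scenario$verification
  ver <- ver[!vapply(ver, function(v) is.list(v) && !is.data.frame(v),
                     logical(1))]  # drop nested result objects
  jsonlite::write_json(ver, file.path(dir, "verification.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
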