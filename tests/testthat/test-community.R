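test_that("tradeoff fit recovers exact lines and pairwise slopes", {
  st <- collinear_ensemble(n = 5, c = 1, intercept = 6, tau_range = c(1, 4))
  fit <- fit_tradeoff(st)
  expect_equal(fit$c, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 6, tolerance = 1e-10)
  expect_lt(fit$max_residual, 1e-12)
  expect_true(fit$collinear)
  # pairwise closed form
  pair <- strain_table(c("A", "B"), lag = c(2, 1), growth_time = c(1, 2),
                       yield = c(1, 2))
  fitp <- fit_tradeoff(pair)
  expect_equal(fitp$c, 1)
  expect_error(fit_tradeoff(strain_table(c("A", "B"), c(1, 2), c(1, 1),
                                         c(1, 1))),
               class = "serialcoex_degenerate_fit_error")
  # synergy flagged when lag rises with growth time
  syn <- strain_table(c("A", "B"), lag = c(1, 2), growth_time = c(1, 2),
                      yield = c(1, 2))
  expect_true(fit_tradeoff(syn)$synergy)
})

test_that("noisy ensembles report residuals of the noise scale", {
  spec <- ensemble_spec(30, c = 1, intercept = 8, tau_range = c(1, 4),
                        yield_spec = list(rule = "tradeoff",
                                          range = c(1e3, 2.5e3)),
                        noise_sigma = 0.05, seed = 9)
  st <- generate_ensemble(spec)
  fit <- fit_tradeoff(st)
  expect_false(fit$collinear)
  expect_gt(fit$max_residual, 0.01)
  expect_lt(fit$max_residual, 0.5)
})

test_that("the coexistence window follows the closed form and the floor is reported", {
  st <- strain_table(c("A", "B"), lag = c(2, 1), growth_time = c(1, 2),
                     yield = c(1, 2))   # c = 1
  w <- coexistence_rho_window(st)
  expect_equal(w$lower, exp(1) / 2)
  expect_equal(w$upper, exp(1))
  expect_equal(w$floor, 1)
  expect_false(w$degenerate)
  # equal yields: degenerate window
  st_eq <- strain_table(c("A", "B"), lag = c(2, 1), growth_time = c(1, 2),
                        yield = c(2, 2))
  expect_true(coexistence_rho_window(st_eq)$degenerate)
  # non-collinear or synergistic sets have no window
  st_nc <- strain_table(c("A", "B", "C"), lag = c(2, 1, 2.5),
                        growth_time = c(1, 2, 3), yield = c(1, 2, 3))
  expect_error(coexistence_rho_window(st_nc),
               class = "serialcoex_no_window_error")
  st_syn <- strain_table(c("A", "B"), lag = c(1, 2), growth_time = c(1, 2),
                         yield = c(1, 2))
  expect_error(coexistence_rho_window(st_syn),
               class = "serialcoex_no_window_error")
})

test_that("rho inside the window sustains all strains; outside it loses one", {
  st <- collinear_ensemble()
  w <- coexistence_rho_window(st)
  cfg_in <- competition_config(rho = pick_rho(st, 0.5))
  tr_in <- run_serial_dilution(st, c(0.4, 0.1, 0.2, 0.3), cfg_in, 2500)
  expect_true(all(tr_in$densities[nrow(tr_in$densities), ] > 1e-3))
  cfg_out <- competition_config(rho = w$upper * 1.3,
                                extinction_threshold = 1e-10)
  tr_out <- run_serial_dilution(st, c(0.4, 0.1, 0.2, 0.3), cfg_out, 30000,
                                stop_on_resolution = TRUE)
  expect_gt(sum(!is.na(tr_out$extinctions)), 0)
})

test_that("fixed-point space has dimension M - 2 and zero selection throughout", {
  st <- collinear_ensemble()
  rho <- pick_rho(st, 0.5)
  fps <- fixed_point_space(st, rho)
  expect_true(fps$feasible)
  expect_equal(fps$dimension, 2)
  cfg <- competition_config(rho = rho)
  expect_lt(max(abs(selection_matrix(st, fps$interior, cfg)), na.rm = TRUE),
            1e-10)
  set.seed(77)
  pts <- sample_fixed_points(fps, 20)
  expect_lt(max(abs(pts %*% (1 / st$yield) - rho * exp(-fps$window$c))),
            1e-12)
  smax <- apply(pts, 1, function(x)
    max(abs(selection_matrix(st, x / sum(x), cfg)), na.rm = TRUE))
  expect_lt(max(smax), 1e-8)

  # M = 2: unique pair solving the 2x2 system
  pair <- subset_strains(st, c(1, 4))
  rho2 <- pick_rho(pair, 0.5)
  fps2 <- fixed_point_space(pair, rho2)
  expect_equal(fps2$dimension, 0)
  expect_equal(nrow(fps2$vertices), 1L)
  cfg2 <- competition_config(rho = rho2)
  expect_lt(abs(selection_exact(pair$label[1], pair$label[2], pair,
                                fps2$interior, cfg2)), 1e-10)
  # rho outside the window: empty feasible set, not an error
  fps_out <- fixed_point_space(st, fps$window$upper * 2)
  expect_false(fps_out$feasible)
})

test_that("rho at a window boundary puts the extreme-yield strain at zero density", {
  st <- collinear_ensemble()
  w <- coexistence_rho_window(st)
  # near the lower bound the critical effective yield approaches max(Y), so
  # the fixed point concentrates on the max-yield strain and the min-yield
  # strain's density goes to zero
  rho <- w$lower + 1e-6 * (w$upper - w$lower)
  fps <- fixed_point_space(st, rho)
  expect_lt(fps$interior[which.min(st$yield)], 1e-4)
  expect_gt(fps$interior[which.max(st$yield)], 0.99)
  # near the upper bound the fixed point concentrates on the min-yield strain
  rho2 <- w$upper - 1e-6 * (w$upper - w$lower)
  fps2 <- fixed_point_space(st, rho2)
  expect_gt(fps2$interior[which.min(st$yield)], 0.99)
})

test_that("keystones are the extreme-yield strains in the extreme sub-windows", {
  st <- collinear_ensemble()
  w <- coexistence_rho_window(st)
  ecY <- sort(exp(w$c) / st$yield)   # sub-window breakpoints
  # just above the lower bound: losing the max-yield strain collapses it
  rho_lo <- sqrt(ecY[1] * ecY[2])
  k_lo <- keystone_strains(st, rho_lo)
  expect_identical(k_lo, st$label[which.max(st$yield)])
  # central sub-window: robust to any single removal
  rho_mid <- sqrt(ecY[2] * ecY[3])
  expect_length(keystone_strains(st, rho_mid), 0)
  # just below the upper bound: the min-yield strain is the keystone
  rho_hi <- sqrt(ecY[3] * ecY[4])
  k_hi <- keystone_strains(st, rho_hi)
  expect_identical(k_hi, st$label[which.min(st$yield)])
})

test_that("removing the keystone collapses the community in simulation", {
  st <- collinear_ensemble()
  w <- coexistence_rho_window(st)
  ecY <- sort(exp(w$c) / st$yield)
  rho <- sqrt(ecY[3] * ecY[4])       # min-yield strain is the keystone
  key <- keystone_strains(st, rho)
  cfg <- competition_config(rho = rho, extinction_threshold = 1e-10)
  # full community coexists
  tr <- run_serial_dilution(st, uniform_densities(st), cfg, 2000)
  expect_true(all(tr$densities[nrow(tr$densities), ] > 1e-4))
  # removing the keystone: all but one of the rest go extinct
  rest <- subset_strains(st, which(st$label != key))
  tr2 <- run_serial_dilution(rest, uniform_densities(rest), cfg, 50000,
                             stop_on_resolution = TRUE)
  fin2 <- tr2$densities[nrow(tr2$densities), ]
  expect_equal(sum(fin2 > cfg$extinction_threshold), 1L)
  # removing any non-keystone strain preserves coexistence of the rest
  for (k in which(st$label != key)) {
    rest_k <- subset_strains(st, setdiff(seq_len(nrow(st)), k))
    tr_k <- run_serial_dilution(rest_k, uniform_densities(rest_k), cfg, 2000)
    expect_true(all(tr_k$densities[nrow(tr_k$densities), ] > 1e-4))
  }
})

test_that("invasion geometry predicts and simulation confirms", {
  st <- collinear_ensemble(n = 3, c = 1.2, intercept = 7,
                           tau_range = c(1, 3.5),
                           yield_range = c(1e3, 2.8e3))
  rho <- pick_rho(st, 0.5)
  cfg <- competition_config(rho = rho)
  line_lag <- function(tau) 7 - 1.2 * tau
  # invader above the line dies even with the shortest lag of all: a long
  # growth time puts the line low, so a lag shorter than every resident's
  # can still sit above it
  inv_above <- strain_table("INV", lag = min(st$lag) - 0.05,
                            growth_time = 3.6, yield = 1.5e3)
  expect_gt(inv_above$lag - line_lag(3.6), 0)
  out_a <- invasion_outcome(st, inv_above, rho, cfg)
  expect_equal(out_a$geometric, "extinct")
  expect_equal(out_a$simulated, "extinct")
  expect_true(out_a$agree)
  # invader well below the line takes over
  inv_b <- strain_table("INV", lag = line_lag(1.2) - 0.5, growth_time = 1.2,
                        yield = 1.5e3)
  out_b <- invasion_outcome(st, inv_b, rho, cfg)
  expect_equal(out_b$geometric, "takeover_or_coexist")
  expect_equal(out_b$simulated, "takeover")
  expect_true(out_b$agree)
  # invader marginally below the line, rho inside its pair window with the
  # min-yield resident: coexists with exactly that one resident
  y_inv <- 1.6e3
  rho_c <- sqrt(exp(1.2) / y_inv * exp(1.2) / min(st$yield))
  inv_c <- strain_table("INV", lag = line_lag(2) - 0.004, growth_time = 2,
                        yield = y_inv)
  out_c <- invasion_outcome(st, inv_c, rho_c, cfg)
  expect_equal(out_c$simulated, "coexist_with_one")
  expect_true(out_c$agree)
  # clone of a resident is neutral
  clone <- subset_strains(st, 2)
  clone$label <- "INV"
  out_d <- invasion_outcome(st, clone, rho, cfg)
  expect_equal(out_d$geometric, "neutral_marginal")
  expect_equal(out_d$simulated, "neutral")
})

test_that("a doubly superior strain is the tournament champion", {
  st <- strain_table(c("W", "L1", "L2"),
                     lag = c(0.5, 1.2, 1.4),
                     growth_time = c(0.8, 1.0, 1.1), yield = rep(1e4, 3))
  tour <- pairwise_tournament(st, rho = 1e-3,
                              competition_config(rho = 1e-3))
  expect_equal(tour$classification, "champion")
  expect_equal(tour$champion, "W")
  expect_length(tour$cycles, 0)
  # outcome matrix is symmetric in its unordered-pair entries
  expect_identical(tour$matrix["W", "L1"], tour$matrix["L1", "W"])
})

test_that("a conditionally neutral pair records coexistence, not a win", {
  st <- collinear_ensemble(n = 2, c = 1.5, intercept = 8,
                           tau_range = c(1, 3), yield_range = c(1e3, 3e3))
  rho <- pick_rho(st, 0.5)
  tour <- pairwise_tournament(st, rho, competition_config(rho = rho))
  expect_equal(tour$outcomes$outcome, "coexist")
})

test_that("pairs coexisting at different tradeoffs do not coexist together", {
  # A-B and B-C each coexist as pairs (at their own rho), but the three
  # pairwise tradeoffs differ, so no common fixed point exists for the trio
  stA <- strain_table("A", lag = 5.0, growth_time = 1, yield = 1000)
  stB <- strain_table("B", lag = 4.0, growth_time = 2, yield = 1500)  # c_AB = 1
  stC <- strain_table("C", lag = 2.6, growth_time = 3, yield = 2250)  # c_BC = 1.4
  trio <- rbind(stA, stB, stC)
  class(trio) <- c("strain_table", "data.frame")
  expect_false(fit_tradeoff(trio)$collinear)
  for (pr in list(rbind(stA, stB), rbind(stB, stC))) {
    class(pr) <- c("strain_table", "data.frame")
    rho_p <- pick_rho(pr, 0.5)
    cfg_p <- competition_config(rho = rho_p)
    tr <- run_serial_dilution(pr, c(0.5, 0.5), cfg_p, 3000)
    expect_true(all(tr$densities[nrow(tr$densities), ] > 1e-3))
  }
  expect_error(coexistence_rho_window(trio),
               class = "serialcoex_no_window_error")
  # simulated together at either pair's rho, at least one strain dies
  rho_ab <- pick_rho({p <- rbind(stA, stB); class(p) <- c("strain_table", "data.frame"); p}, 0.5)
  cfg <- competition_config(rho = rho_ab, extinction_threshold = 1e-10)
  tr3 <- run_serial_dilution(trio, uniform_densities(trio), cfg, 60000,
                             stop_on_resolution = TRUE)
  expect_gt(sum(!is.na(tr3$extinctions)), 0)
})

test_that("growth-yield coupling separates neutral coexistence from multistability", {
  st_t <- collinear_ensemble(rule = "tradeoff")
  rho_t <- pick_rho(st_t, 0.5)
  rep_t <- classify_stability(st_t, rho_t, competition_config(rho = rho_t))
  expect_equal(rep_t$class, "neutral_coexistence")
  expect_equal(rep_t$predictor, "neutral_coexistence")
  expect_true(rep_t$agree)

  st_s <- collinear_ensemble(rule = "synergy")
  rho_s <- pick_rho(st_s, 0.5)
  rep_s <- classify_stability(st_s, rho_s, competition_config(rho = rho_s))
  expect_equal(rep_s$class, "multistable")
  expect_equal(rep_s$predictor, "multistable")

  # M = 2 tradeoff pair: unique fixed point, stability as in the pair case
  pair <- collinear_ensemble(n = 2, rule = "tradeoff")
  rho_p <- pick_rho(pair, 0.5)
  rep_p <- classify_stability(pair, rho_p, competition_config(rho = rho_p))
  expect_equal(rep_p$class, "neutral_coexistence")
})

test_that("multistable ensembles reach distinct states from different starts", {
  st <- collinear_ensemble(rule = "synergy")
  rho <- pick_rho(st, 0.5)
  cfg <- competition_config(rho = rho, extinction_threshold = 1e-10)
  finals <- lapply(list(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7)),
                   function(x0) {
                     tr <- run_serial_dilution(st, x0, cfg, 30000,
                                               stop_on_resolution = TRUE)
                     tr$densities[nrow(tr$densities), ]
                   })
  expect_gt(max(abs(finals[[1]] - finals[[2]])), 0.5)
})

test_that("the coexistence report assembles consistently", {
  st <- collinear_ensemble()
  rho <- pick_rho(st, 0.5)
  rep <- coexistence_report(st, rho, competition_config(rho = rho))
  expect_true(rep$rho_in_window)
  expect_equal(rep$critical_effective_yield, exp(rep$window$c) / rho)
  expect_equal(rep$stability_class, "neutral_coexistence")
  expect_equal(rep$fixed_point_space$dimension, 2)
})
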