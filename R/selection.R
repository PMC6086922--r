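#' Effective population growth time and yield
#'
#' Density-weighted harmonic means over the community:
#' `tau_bar = sum(x_k/Y_k) / sum(x_k/(Y_k tau_k))` and
#' `y_bar = 1 / sum(x_k/Y_k)`. Both are dominated by the smallest trait
#' values, so the effective growth time tracks the fastest grower and the
#' effective yield tracks the least-efficient strain.
#'
#' @inheritParams saturation_time
#' @return A list with `tau_bar` and `y_bar`.
#' @export
effective_params <- function(strains, x = uniform_densities(strains)) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  w <- x / strains$yield
  list(tau_bar = sum(w) / sum(w / strains$growth_time),
       y_bar = 1 / sum(w))
}

# Log fold changes of every strain over one round; the building block for
# exact selection coefficients (differences telescope, so antisymmetry and
# additivity hold to machine precision).
log_fold_changes <- function(strains, x, config) {
  grow_one_round(strains, x, config)$log_fold_changes
}

#' Exact pairwise selection coefficient
#'
#' The per-round change in log density ratio of strain `i` over strain `j`:
#' `s_ij = log(x'_i/x'_j) - log(x_i/x_j)`, with the primed densities obtained
#' by one exactly simulated round. Computed as the difference of log fold
#' changes, so the identities `s_ij = -s_ji` and `s_ij = s_ik + s_kj` hold to
#' machine precision.
#'
#' @param i,j Strain labels.
#' @inheritParams saturation_time
#' @return Scalar selection coefficient (dimensionless).
#' @export
selection_exact <- function(i, j, strains, x = uniform_densities(strains),
                            config) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  ii <- match(i, strains$label); jj <- match(j, strains$label)
  if (is.na(ii) || is.na(jj))
    sc_error("unknown strain label", "validation")
  if (x[ii] <= 0 || x[jj] <= 0)
    sc_error("selection coefficient undefined for zero-density strains",
             "undefined_selection")
  lfc <- log_fold_changes(strains, x, config)
  unname(lfc[ii] - lfc[jj])
}

#' Matrix of exact selection coefficients
#'
#' `s[i, j]` for every ordered pair of present strains (NA for pairs
#' involving an absent strain).
#'
#' @inheritParams saturation_time
#' @return An `M x M` matrix with dimnames from the strain labels.
#' @export
selection_matrix <- function(strains, x = uniform_densities(strains), config) {
  x <- validate_densities(x, strains)
  lfc <- log_fold_changes(strains, x, config)
  s <- outer(lfc, lfc, `-`)
  s[x == 0, ] <- NA_real_
  s[, x == 0] <- NA_real_
  dimnames(s) <- list(strains$label, strains$label)
  s
}

#' Decompose a pairwise selection coefficient
#'
#' First-order analytic decomposition of `s_ij` into additive components:
#' \itemize{
#'   \item lag: `-(tau_bar/(tau_i tau_j)) * d_lag_ij`
#'   \item growth: `-(tau_bar/(tau_i tau_j)) * d_tau_ij * log(rho * y_bar)`
#'   \item coupling through every strain k (including i and j):
#'     `-(tau_bar * y_bar/(tau_i tau_j)) * (x_k/(tau_k Y_k)) *
#'      (d_tau_ik * d_lag_kj - d_lag_ik * d_tau_kj)`
#' }
#' where `d_lag`, `d_tau` are pairwise trait differences. The coupling term
#' of strain k is proportional to the signed area spanned by the three
#' strains in (growth time, lag) space: it vanishes when k is collinear with
#' i and j, in particular when all three share a lag time or a growth time.
#' The sum of components approximates the exact coefficient to first order
#' in the trait differences (the error is quadratic). The exact value from
#' one simulated round is attached for comparison.
#'
#' @inheritParams selection_exact
#' @return A list of class `selection_decomposition` with `s_lag`,
#'   `s_growth`, `coupling` (named vector over all strains), `total_approx`
#'   (their sum), and `total_exact`.
#' @export
selection_decomposition <- function(i, j, strains,
                                    x = uniform_densities(strains), config) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  ii <- match(i, strains$label); jj <- match(j, strains$label)
  if (is.na(ii) || is.na(jj))
    sc_error("unknown strain label", "validation")
  if (x[ii] <= 0 || x[jj] <= 0)
    sc_error("selection coefficient undefined for zero-density strains",
             "undefined_selection")
  tau <- strains$growth_time; lag <- strains$lag; yield <- strains$yield
  ep <- effective_params(strains, x)
  pref <- ep$tau_bar / (tau[ii] * tau[jj])
  d_lag <- lag[ii] - lag[jj]
  d_tau <- tau[ii] - tau[jj]
  s_lag <- -pref * d_lag
  s_growth <- -pref * d_tau * log(config$rho * ep$y_bar)
  cross <- (tau[ii] - tau) * (lag - lag[jj]) - (lag[ii] - lag) * (tau - tau[jj])
  coupling <- -pref * ep$y_bar * x / (tau * yield) * cross
  names(coupling) <- strains$label
  structure(list(i = i, j = j,
                 s_lag = s_lag, s_growth = s_growth, coupling = coupling,
                 total_approx = s_lag + s_growth + sum(coupling),
                 total_exact = selection_exact(i, j, strains, x, config),
                 tau_bar = ep$tau_bar, y_bar = ep$y_bar),
            class = "selection_decomposition")
}

#' @export
print.selection_decomposition <- function(x, ...) {
  cat(sprintf("Selection decomposition: %s vs %s\n", x$i, x$j))
  cat(sprintf("  s_lag      = % .6g\n", x$s_lag))
  cat(sprintf("  s_growth   = % .6g\n", x$s_growth))
  cat(sprintf("  coupling   = % .6g (sum over %d strains)\n",
              sum(x$coupling), length(x$coupling)))
  cat(sprintf("  approx sum = % .6g\n", x$total_approx))
  cat(sprintf("  exact      = % .6g\n", x$total_exact))
  invisible(x)
}

#' Relative magnitude of selection on growth versus lag
#'
#' `(d_tau_ij / d_lag_ij) * log(rho * y_bar)`: increasing the resource
#' density increases the weight of the growth phase relative to the lag
#' phase, because growth then occupies a larger share of the round.
#'
#' @inheritParams selection_exact
#' @return Scalar ratio.
#' @export
growth_lag_ratio <- function(i, j, strains, x = uniform_densities(strains),
                             config) {
  validate_strains(strains)
  x <- validate_densities(x, strains)
  ii <- match(i, strains$label); jj <- match(j, strains$label)
  if (is.na(ii) || is.na(jj))
    sc_error("unknown strain label", "validation")
  d_lag <- strains$lag[ii] - strains$lag[jj]
  if (d_lag == 0)
    sc_error("growth/lag selection ratio undefined when lag times are equal",
             "undefined_ratio")
  d_tau <- strains$growth_time[ii] - strains$growth_time[jj]
  ep <- effective_params(strains, x)
  (d_tau / d_lag) * log(config$rho * ep$y_bar)
}

#' Geometric classification of a third strain's coupling effect
#'
#' Classifies strain `k` by which side of the straight line through strains
#' `i` and `j` in (growth time, lag time) space it falls on. A strain above
#' the line consumes fewer resources than a collinear strain would, leaving
#' more for `i` and `j` and thereby boosting selection on whichever of the
#' pair grows faster; a strain below the line boosts the slower grower.
#' Collinear strains (within tolerance) are neutral, covering the special
#' cases of all-equal lag times or all-equal growth times.
#'
#' @param i,j,k Single-row strain tables or rows of one (the pair and the
#'   third strain).
#' @param tol Relative tolerance of the collinearity band, applied to the
#'   magnitude of the cross-product terms.
#' @return One of `"boosts_faster_grower"`, `"boosts_slower_grower"`,
#'   `"neutral"`.
#' @export
coupling_sign <- function(i, j, k, tol = 1e-9) {
  pt <- function(s) c(tau = s$growth_time[1], lag = s$lag[1])
  pi_ <- pt(i); pj <- pt(j); pk <- pt(k)
  if (pi_["tau"] == pj["tau"])
    sc_error("coupling geometry degenerate: i and j have equal growth times",
             "degenerate_line")
  a <- (pi_["tau"] - pk["tau"]) * (pk["lag"] - pj["lag"])
  b <- (pi_["lag"] - pk["lag"]) * (pk["tau"] - pj["tau"])
  cross <- a - b
  scale <- max(abs(a), abs(b), .Machine$double.eps)
  if (abs(cross) < tol * scale) return("neutral")
  # Vertical deviation of k from the i-j line decides the side.
  slope <- (pj["lag"] - pi_["lag"]) / (pj["tau"] - pi_["tau"])
  dev <- pk["lag"] - (pi_["lag"] + slope * (pk["tau"] - pi_["tau"]))
  if (dev > 0) "boosts_faster_grower" else "boosts_slower_grower"
}
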