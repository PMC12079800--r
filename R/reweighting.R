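# WHAM path reweighting across nested interface ensembles, crossing
# probability, flux and rate assembly.

#' Maximum order-parameter value along a path
#'
#' @param path a [ppa_path].
#' @return The maximum of `lambda` over the stored frames.
#' @export
lambda_max <- function(path) {
  max(path$frames$lambda)
}

#' WHAM weights for nested interface path ensembles
#'
#' Assigns each `[i+]` path a statistical weight such that the weighted
#' distribution of \eqn{\lambda_{max}} matches the unbiased first-crossing
#' distribution of an (effectively infinite) unchopped trajectory. The nested
#' step-function biases of interface ensembles admit a non-iterative WHAM
#' solution: processing interfaces left to right, a path with maximum `m`
#' receives
#' \deqn{w(m) = \Big[\sum_{k:\ \lambda_k \le m} n_k / \hat P(\lambda_k|\lambda_A)\Big]^{-1}}
#' where \eqn{n_k} is the path count of ensemble `[k+]` and the crossing
#' probabilities \eqn{\hat P} are built recursively from the already-weighted
#' paths, starting from \eqn{\hat P(\lambda_0|\lambda_A) = 1}. Weights of
#' `[0-]` paths are left untouched; returned `[i+]` weights are normalised to
#' mean one.
#'
#' @param paths list of [ppa_path] objects (any mixture of `[0-]` and `[i+]`).
#' @param interfaces a [ppa_interfaces] object the ensembles are nested on.
#' @return The same paths with `weight` set.
#' @references Validated in the test-suite against direct counting on an
#'   unchopped synthetic trajectory rather than trusted as a formula.
#' @export
wham_weights <- function(paths, interfaces) {
  stopifnot(inherits(interfaces, "ppa_interfaces"))
  ens <- vapply(paths, `[[`, "", "ensemble")
  plus <- which(ens != "0-")
  if (!length(plus)) ppa_error("no [i+] paths to reweight", "ppa_value_error")
  idx <- vapply(ens[plus], ensemble_index, 0L)
  if (max(idx) > length(interfaces$lambdas) - 2L)
    ppa_error("ensemble index beyond the interface set", "ppa_value_error")
  m <- vapply(paths[plus], lambda_max, 0)
  ks <- sort(unique(idx))
  lam_k <- interfaces$lambdas[ks + 1L]
  n_k <- vapply(ks, function(k) sum(idx == k), 0L)
  bad <- which(m < lam_k[match(idx, ks)])
  if (length(bad))
    ppa_error(sprintf(
      "degenerate ensemble: path '%s' in [%s] never crosses its interface",
      paths[[plus[bad[1L]]]]$path_id, ens[plus[bad[1L]]]),
      "ppa_degenerate_error")

  phat <- numeric(length(ks))
  phat[1L] <- 1
  for (j in seq_along(ks)[-1L]) {
    # provisional weights from ensembles processed so far
    seen <- idx %in% ks[seq_len(j - 1L)]
    denom <- rep(0, sum(seen))
    mm <- m[seen]
    for (q in seq_len(j - 1L))
      denom <- denom + ifelse(mm >= lam_k[q], n_k[q] / phat[q], 0)
    w <- 1 / denom
    phat[j] <- sum(w[mm >= lam_k[j]]) / sum(w)
    if (phat[j] <= 0)
      ppa_error(sprintf(
        "degenerate ensemble: no path below [%d+] reaches lambda_%d",
        ks[j], ks[j]), "ppa_degenerate_error")
  }

  denom <- rep(0, length(m))
  for (q in seq_along(ks))
    denom <- denom + ifelse(m >= lam_k[q], n_k[q] / phat[q], 0)
  w <- 1 / denom
  w <- w / mean(w)
  for (i in seq_along(plus)) paths[[plus[i]]]$weight <- w[i]
  paths
}

#' Crossing-probability curve from weighted paths
#'
#' \eqn{P_A(\lambda|\lambda_A)}: the weighted fraction of paths whose maximum
#' order-parameter value reaches at least \eqn{\lambda}, among all paths that
#' left state A. `[0-]` paths are ignored. The curve is reported only up to
#' the largest \eqn{\lambda} reached by any path; beyond that it is undefined
#' rather than zero.
#'
#' @param paths list of weighted [ppa_path] objects.
#' @param lam_grid increasing numeric vector of query positions.
#' @param lam_A reactant boundary; defaults to the first grid value.
#' @return An object of class `ppa_crossing_curve` with fields `lambda` and
#'   `prob` (non-increasing, `prob[1] == 1` when the grid starts at `lam_A`).
#' @export
crossing_curve <- function(paths, lam_grid, lam_A = min(lam_grid)) {
  ens <- vapply(paths, `[[`, "", "ensemble")
  paths <- paths[ens != "0-"]
  if (!length(paths)) ppa_error("no [i+] paths", "ppa_value_error")
  m <- vapply(paths, lambda_max, 0)
  w <- vapply(paths, `[[`, 0, "weight")
  denom <- sum(w[m >= lam_A])
  if (denom <= 0) ppa_error("no path reaches lam_A", "ppa_value_error")
  lam_grid <- sort(lam_grid)
  lam_grid <- lam_grid[lam_grid <= max(m)]
  prob <- vapply(lam_grid, function(l) sum(w[m >= l]) / denom, 0)
  structure(list(lambda = lam_grid, prob = prob), class = "ppa_crossing_curve")
}

#' @export
as.data.frame.ppa_crossing_curve <- function(x, ...) {
  data.frame(lambda = x$lambda, prob = x$prob)
}

#' @export
print.ppa_crossing_curve <- function(x, ...) {
  cat(sprintf(
    "<ppa_crossing_curve> %d points, lambda in [%.4g, %.4g], P(end) = %.4g\n",
    length(x$lambda), x$lambda[1L], x$lambda[length(x$lambda)],
    x$prob[length(x$prob)]))
  invisible(x)
}

#' Initial flux out of state A
#'
#' \eqn{f_A = 1 / (\langle\tau\rangle_{0^-} + \langle\tau\rangle_{0^+})},
#' from the average path durations of the `[0-]` and `[0+]` ensembles.
#' A path's duration is the time span of its stored frames (one shared
#' endpoint per junction), so consecutive segments of a chopped trajectory
#' sum to the trajectory duration. Times are in fs; the flux is returned in
#' ns^-1.
#'
#' @param paths_0minus,paths_0plus lists of [ppa_path] objects.
#' @return Flux in ns^-1.
#' @export
flux_estimate <- function(paths_0minus, paths_0plus) {
  if (!length(paths_0minus)) ppa_error("empty [0-] ensemble", "ppa_value_error")
  if (!length(paths_0plus)) ppa_error("empty [0+] ensemble", "ppa_value_error")
  dur <- function(p) {
    t <- p$frames$time
    t[length(t)] - t[1L]
  }
  t0m <- vapply(paths_0minus, dur, 0)
  t0p <- vapply(paths_0plus, dur, 0)
  tot <- mean(t0m) + mean(t0p)
  if (tot <= 0)
    ppa_error("zero total path duration; cannot estimate a flux",
              "ppa_value_error")
  1e6 / tot
}

#' Assemble the rate constant from flux and crossing curve
#'
#' \eqn{k_{AB} = f_A \times P_A(\lambda_B|\lambda_A)}, taking the total
#' crossing probability from the last point of the curve (which must reach
#' \eqn{\lambda_B}).
#'
#' @param flux flux in ns^-1, from [flux_estimate()].
#' @param curve a `ppa_crossing_curve`.
#' @return An object of class `ppa_rate`: list with `flux_ns`,
#'   `total_crossing_prob` and `rate_ns` (`rate_ns == flux_ns *
#'   total_crossing_prob` exactly).
#' @export
rate_estimate <- function(flux, curve) {
  stopifnot(inherits(curve, "ppa_crossing_curve"))
  p <- curve$prob[length(curve$prob)]
  structure(list(flux_ns = flux, total_crossing_prob = p, rate_ns = flux * p),
            class = "ppa_rate")
}

#' @export
print.ppa_rate <- function(x, ...) {
  cat(sprintf(
    "<ppa_rate> f_A = %.6g ns^-1, P_A(lambda_B|lambda_A) = %.6g, k_AB = %.6g ns^-1\n",
    x$flux_ns, x$total_crossing_prob, x$rate_ns))
  invisible(x)
}
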