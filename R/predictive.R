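# Overlap integral, predictive capacity and (lambda_c, lambda_r) maps.

guard_eps <- function(d) 1e-8 * max(d$t)

#' Overlap integral of the reactive and unreactive densities
#'
#' \eqn{O = \int r(\Psi)\, u(\Psi) / t(\Psi)\, d\Psi}, with the integrand
#' set to zero wherever the total density falls below `1e-8` of its peak
#' (guarding the 0/0 tails). Trapezoidal quadrature on the estimation grid
#' for Savitzky-Golay densities; for binned densities the integral is the
#' bin sum \eqn{\sum_q r_q u_q / t_q \, V_{bin}}.
#'
#' @param d a `ppa_density`.
#' @return The nonnegative overlap integral.
#' @export
overlap_integral <- function(d) {
  stopifnot(inherits(d, "ppa_density"))
  eps <- guard_eps(d)
  z <- ifelse(d$t >= eps, d$r * d$u / d$t, 0)
  density_integral(d, z)
}

#' Predictive capacity of a collective variable
#'
#' The reactive-weighted average of the local success probability
#' \eqn{r/t}:
#' \deqn{\mathcal{P} = \frac{1}{\bar p}\int \frac{r(\Psi)^2}{t(\Psi)}\,d\Psi
#'   \;=\; 1 - \frac{O}{\bar p},}
#' with \eqn{\bar p = \int r} and overlap integral \eqn{O}. It ranges from
#' \eqn{\bar p} for a CV carrying no information about reaction success to 1
#' for a fully predictive CV. Both algebraic forms are evaluated on the same
#' guarded grid and must agree to 1e-9 (internal consistency check).
#'
#' @param d a `ppa_density`.
#' @return An object of class `ppa_capacity`: list with `p_bar`, `overlap`,
#'   `capacity`, `n_samples`, `query`.
#' @export
predictive_capacity <- function(d) {
  stopifnot(inherits(d, "ppa_density"))
  eps <- guard_eps(d)
  ok <- d$t >= eps
  p_bar <- density_integral(d, ifelse(ok, d$r, 0))
  if (p_bar <= 0)
    ppa_error("no reactive density: p_bar is zero", "ppa_value_error")
  O <- density_integral(d, ifelse(ok, d$r * d$u / d$t, 0))
  cap_direct <- density_integral(d, ifelse(ok, d$r^2 / d$t, 0)) / p_bar
  cap <- 1 - O / p_bar
  if (abs(cap - cap_direct) > 1e-9)
    stop("internal error: the two forms of the predictive capacity disagree")
  structure(list(p_bar = p_bar, overlap = O, capacity = cap,
                 n_samples = NA_integer_, query = NULL),
            class = "ppa_capacity")
}

#' @export
print.ppa_capacity <- function(x, ...) {
  cat(sprintf(
    "<ppa_capacity> P = %.4f (bounds [p_bar, 1] = [%.4f, 1]), overlap = %.4g, n = %s\n",
    x$capacity, x$p_bar, x$overlap,
    if (is.na(x$n_samples)) "?" else x$n_samples))
  invisible(x)
}

#' Predictive capacity straight from a weighted sample set
#'
#' [estimate_densities()] followed by [predictive_capacity()]. The
#' density-level \eqn{\bar p = \int r} is cross-checked against the
#' sample-level [mean_crossing_prob()]; a discrepancy beyond 1e-3 raises a
#' diagnostic warning (class `ppa_diagnostic_warning`), not an error.
#'
#' @param s a `ppa_samples` data.frame.
#' @param settings a [sg_settings()] object.
#' @param cv CV column; may be omitted when there is only one.
#' @return A `ppa_capacity` with `n_samples` and `query` filled in.
#' @export
capacity_from_samples <- function(s, settings = sg_settings(), cv = NULL) {
  d <- estimate_densities(s, settings, cv)
  res <- predictive_capacity(d)
  res$n_samples <- nrow(s)
  lam_c <- attr(s, "lam_c")
  lam_r <- attr(s, "lam_r")
  if (!is.null(lam_c) && !is.na(lam_c))
    res$query <- ppa_query(lam_c, lam_r, lam_A = lam_c)
  p_s <- attr(d, "p_bar_sample")
  if (abs(res$p_bar - p_s) > 1e-3)
    warning(warningCondition(
      sprintf("density-level p_bar (%.5f) differs from sample-level (%.5f)",
              res$p_bar, p_s),
      class = "ppa_diagnostic_warning"))
  res
}

#' Predictive-capacity map over a (lambda_c, lambda_r) grid
#'
#' For every pair \eqn{\lambda^c \le \lambda^r}, computes the crossing
#' probability \eqn{P = P_A(\lambda^r|\lambda_A)/P_A(\lambda^c|\lambda_A)}
#' from the weighted paths, and the predictive capacity of the named CV from
#' the first-crossing samples at \eqn{\lambda^c} labelled with respect to
#' \eqn{\lambda^r}. First crossings are extracted once per \eqn{\lambda^c}
#' and relabelled per \eqn{\lambda^r}. Cells with fewer than `n_min` samples,
#' or with degenerate densities, are flagged undefined rather than raising.
#'
#' @param paths list of weighted [ppa_path] objects.
#' @param cv_name name of the CV column in the path frames.
#' @param lc_grid,lr_grid increasing vectors of interface positions.
#' @param settings a [sg_settings()] object.
#' @param n_min minimum sample count per cell (default 200).
#' @param lam_A reactant boundary; defaults to `min(lc_grid)`.
#' @return An object of class `ppa_map`: list with `lc`, `lr`, matrices `P`,
#'   `capacity`, `ratio` (capacity / P) and logical `defined` (rows index
#'   `lc`, columns `lr`; cells with `lc > lr` are `NA`/undefined).
#' @export
ppa_scan <- function(paths, cv_name, lc_grid, lr_grid,
                     settings = sg_settings(), n_min = 200L,
                     lam_A = min(lc_grid)) {
  ens <- vapply(paths, `[[`, "", "ensemble")
  paths <- paths[ens != "0-"]
  if (!length(paths)) ppa_error("no [i+] paths", "ppa_value_error")
  avail <- cv_names_of(paths[[1L]])
  if (!cv_name %in% avail)
    ppa_error(sprintf("unknown CV '%s'; available: %s", cv_name,
                      paste(avail, collapse = ", ")), "ppa_value_error")
  lc_grid <- sort(lc_grid)
  lr_grid <- sort(lr_grid)
  np <- length(paths)
  w <- vapply(paths, `[[`, 0, "weight")
  m <- vapply(paths, lambda_max, 0)
  # running maxima are non-decreasing, so first crossings come from a
  # binary search per (path, lambda_c)
  cmx <- lapply(paths, function(p) cummax(p$frames$lambda))
  cvv <- lapply(paths, function(p) p$frames[[cv_name]])
  denom_A <- sum(w[m >= lam_A])

  nl <- length(lc_grid)
  nr <- length(lr_grid)
  P <- matrix(NA_real_, nl, nr)
  capacity <- matrix(NA_real_, nl, nr)
  defined <- matrix(FALSE, nl, nr)
  for (ic in seq_len(nl)) {
    lc <- lc_grid[ic]
    sel <- which(m >= lc)
    if (!length(sel)) next
    fci <- vapply(sel, function(j)
      findInterval(lc, cmx[[j]], left.open = TRUE) + 1L, 0L)
    psi <- vapply(seq_along(sel), function(k) cvv[[sel[k]]][fci[k]], 0)
    ws <- w[sel]
    ms <- m[sel]
    wc <- sum(ws)
    for (ir in seq_len(nr)) {
      lr <- lr_grid[ir]
      if (lr < lc) next
      P[ic, ir] <- sum(ws[ms >= lr]) / wc
      if (length(sel) < n_min) next
      lab <- ifelse(ms >= lr, "reactive", "unreactive")
      cap <- tryCatch(
        predictive_capacity(density_from_vectors(psi, ws, lab, settings)),
        ppa_error = function(e) NULL)
      if (!is.null(cap)) {
        capacity[ic, ir] <- cap$capacity
        defined[ic, ir] <- TRUE
      }
    }
  }
  structure(list(lc = lc_grid, lr = lr_grid, P = P, capacity = capacity,
                 ratio = capacity / P, defined = defined, n_min = n_min),
            class = "ppa_map")
}

# shared fast path: density estimation from bare vectors
density_from_vectors <- function(psi, w, lab, settings) {
  s <- structure(data.frame(path_id = seq_along(psi), cv = psi,
                            weight = w, label = lab),
                 class = c("ppa_samples", "data.frame"))
  estimate_densities(s, settings)
}

#' @export
as.data.frame.ppa_map <- function(x, ...) {
  g <- expand.grid(lc = x$lc, lr = x$lr)
  data.frame(g, P = as.vector(x$P), capacity = as.vector(x$capacity),
             ratio = as.vector(x$ratio), defined = as.vector(x$defined))
}
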