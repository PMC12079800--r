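# Density estimation from weighted first-crossing samples: integrated
# empirical distributions, plateau padding and Savitzky-Golay differentiation,
# plus a naive binned estimator used as fallback and as a contrast case.

#' Savitzky-Golay estimator settings
#'
#' Defaults follow the production protocol: the integrated distributions are
#' mapped to a 2000-point regular grid between the smallest and largest
#' sampled CV values, extended by plateaus of one quarter of the grid on each
#' side, and smoothed with a second-order polynomial filter whose window
#' covers about 1/16 of the CV range (window 125 for a 2000-point grid).
#' Polynomial orders above 2 can produce negative density amplitudes and are
#' only accepted with `allow_high_order = TRUE`.
#'
#' @param n_gp number of grid points (default 2000).
#' @param window_fraction fraction of the grid covered by the filter window
#'   (default 1/16).
#' @param polyorder polynomial order of the filter (default 2).
#' @param pad_fraction plateau length as a fraction of the grid (default 1/4).
#' @param allow_high_order allow `polyorder > 2`.
#' @return An object of class `ppa_sg_settings`.
#' @export
sg_settings <- function(n_gp = 2000L, window_fraction = 1 / 16,
                        polyorder = 2L, pad_fraction = 1 / 4,
                        allow_high_order = FALSE) {
  if (n_gp < 16L) ppa_error("n_gp must be at least 16", "ppa_value_error")
  if (window_fraction <= 0 || window_fraction >= 1)
    ppa_error("window_fraction must be in (0, 1)", "ppa_value_error")
  if (polyorder < 0) ppa_error("polyorder must be >= 0", "ppa_value_error")
  if (polyorder > 2L && !allow_high_order)
    ppa_error(paste("polyorder > 2 can yield negative densities;",
                    "set allow_high_order = TRUE to override"),
              "ppa_value_error")
  if (pad_fraction < 0) ppa_error("pad_fraction must be >= 0", "ppa_value_error")
  structure(list(n_gp = as.integer(n_gp), window_fraction = window_fraction,
                 polyorder = as.integer(polyorder),
                 pad_fraction = pad_fraction),
            class = "ppa_sg_settings")
}

#' Stepwise weighted integrated distributions R and U
#'
#' At each distinct sorted CV value, `R` is the cumulative weight of reactive
#' samples up to and including that value divided by the total weight `W`
#' (reactive and unreactive together), and `U` likewise for unreactive
#' samples. Duplicate CV values merge into a single step of combined height.
#'
#' @param s a `ppa_samples` data.frame.
#' @param cv name of the CV column; may be omitted when there is only one.
#' @return An object of class `ppa_cdfs`: list with sorted distinct `cv`
#'   values, step values `R`, `U`, and the total weight `W`.
#' @export
weighted_cdfs <- function(s, cv = NULL) {
  cv <- samples_cv_column(s, cv)
  psi <- s[[cv]]
  o <- order(psi)
  psi <- psi[o]
  wr <- s$weight[o] * (s$label[o] == "reactive")
  wu <- s$weight[o] * (s$label[o] != "reactive")
  W <- sum(wr) + sum(wu)
  ux <- unique(psi)
  if (length(ux) < 2L)
    ppa_error("degenerate support: fewer than two distinct CV values",
              "ppa_degenerate_error")
  grp <- match(psi, ux)
  R <- cumsum(rowsum(wr, grp)[, 1L]) / W
  U <- cumsum(rowsum(wu, grp)[, 1L]) / W
  structure(list(cv = ux, R = unname(R), U = unname(U), W = W),
            class = "ppa_cdfs")
}

#' Map step distributions onto a regular grid
#'
#' Linear interpolation of the stepwise `R` and `U` values onto `n_gp`
#' equally spaced points spanning exactly the sampled CV range
#' `[min(cv), max(cv)]`. Monotonicity is preserved.
#'
#' @param cdfs a `ppa_cdfs` object.
#' @param n_gp number of grid points (>= 16).
#' @return An object of class `ppa_icdf`: list with `grid`, `R`, `U`.
#' @export
regrid <- function(cdfs, n_gp = 2000L) {
  stopifnot(inherits(cdfs, "ppa_cdfs"))
  if (n_gp < 16L) ppa_error("n_gp must be at least 16", "ppa_value_error")
  grid <- seq(cdfs$cv[1L], cdfs$cv[length(cdfs$cv)], length.out = n_gp)
  structure(list(grid = grid,
                 R = stats::approx(cdfs$cv, cdfs$R, grid, rule = 2)$y,
                 U = stats::approx(cdfs$cv, cdfs$U, grid, rule = 2)$y,
                 n_pad = 0L),
            class = "ppa_icdf")
}

#' Extend integrated distributions with horizontal plateaus
#'
#' Prepends `round(pad_fraction * n_gp)` grid points at height zero and
#' appends the same number at the final heights, continuing the regular grid
#' spacing on both sides. The plateaus remove boundary transients of the
#' subsequent Savitzky-Golay differentiation.
#'
#' @param d a `ppa_icdf` from [regrid()].
#' @param pad_fraction plateau length as a fraction of the grid (default 1/4).
#' @return The extended `ppa_icdf`; its `n_pad` element records the pad
#'   length per side.
#' @export
pad_plateaus <- function(d, pad_fraction = 1 / 4) {
  stopifnot(inherits(d, "ppa_icdf"))
  n <- length(d$grid)
  n_pad <- as.integer(round(pad_fraction * n))
  if (n_pad == 0L) return(d)
  h <- (d$grid[n] - d$grid[1L]) / (n - 1L)
  structure(list(
    grid = c(d$grid[1L] - h * rev(seq_len(n_pad)), d$grid,
             d$grid[n] + h * seq_len(n_pad)),
    R = c(rep(0, n_pad), d$R, rep(d$R[n], n_pad)),
    U = c(rep(0, n_pad), d$U, rep(d$U[n], n_pad)),
    n_pad = n_pad), class = "ppa_icdf")
}

#' Savitzky-Golay window length
#'
#' The odd integer nearest to `n_gp * window_fraction` (ties rounding up),
#' clamped below at 5: e.g. 125 for a 2000-point grid at the default 1/16.
#'
#' @param n_gp grid size (>= 16).
#' @param window_fraction fraction of the grid the window covers.
#' @return An odd integer window length.
#' @export
sg_window <- function(n_gp, window_fraction = 1 / 16) {
  if (n_gp < 16L) ppa_error("n_gp must be at least 16", "ppa_value_error")
  k <- n_gp * window_fraction
  w <- 2L * as.integer(floor(k / 2)) + 1L
  max(w, 5L)
}

#' Densities as Savitzky-Golay derivatives of the integrated distributions
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial of order
#' `polyorder`, window from [sg_window()]) to the padded integrated
#' distributions and returns their first derivatives with respect to the CV,
#' restricted to the original (unpadded) grid. The total density is
#' `t = r + u`. Slightly negative derivative excursions are not clipped; the
#' overlap integrand guards against them instead.
#'
#' @param d a padded `ppa_icdf` from [pad_plateaus()].
#' @param settings a [sg_settings()] object.
#' @return An object of class `ppa_density`: list with `grid`, `r`, `u`, `t`,
#'   grid spacing `h` and `method = "sg"`.
#' @export
sg_derivative <- function(d, settings = sg_settings()) {
  stopifnot(inherits(d, "ppa_icdf"), inherits(settings, "ppa_sg_settings"))
  n_tot <- length(d$grid)
  n_pad <- d$n_pad
  n_gp <- n_tot - 2L * n_pad
  h <- (d$grid[2L] - d$grid[1L])
  win <- sg_window(n_gp, settings$window_fraction)
  if (win > n_tot) {
    win <- if (n_tot %% 2L == 1L) n_tot else n_tot - 1L
    if (win < settings$polyorder + 2L)
      ppa_error("window exceeds the data length", "ppa_value_error")
  }
  r_full <- signal::sgolayfilt(d$R, p = settings$polyorder, n = win,
                               m = 1L, ts = h)
  u_full <- signal::sgolayfilt(d$U, p = settings$polyorder, n = win,
                               m = 1L, ts = h)
  core <- (n_pad + 1L):(n_pad + n_gp)
  r <- r_full[core]
  u <- u_full[core]
  structure(list(grid = d$grid[core], r = r, u = u, t = r + u,
                 h = h, method = "sg"),
            class = "ppa_density")
}

#' Estimate r, u and t densities from a weighted sample set
#'
#' The full pipeline [weighted_cdfs()] -> [regrid()] -> [pad_plateaus()] ->
#' [sg_derivative()], sidestepping histogram binning entirely.
#'
#' @param s a `ppa_samples` data.frame.
#' @param settings a [sg_settings()] object.
#' @param cv CV column to use; may be omitted when there is only one.
#' @return A `ppa_density` (see [sg_derivative()]); its `p_bar_sample`
#'   attribute carries the sample-level [mean_crossing_prob()].
#' @export
estimate_densities <- function(s, settings = sg_settings(), cv = NULL) {
  d <- sg_derivative(
    pad_plateaus(regrid(weighted_cdfs(s, cv), settings$n_gp),
                 settings$pad_fraction),
    settings)
  attr(d, "p_bar_sample") <- mean_crossing_prob(s)
  d
}

#' @export
print.ppa_density <- function(x, ...) {
  cat(sprintf(
    "<ppa_density/%s> %d grid points on [%.4g, %.4g], int t = %.4f, int r = %.4f\n",
    x$method, length(x$grid), x$grid[1L], x$grid[length(x$grid)],
    density_integral(x, x$t), density_integral(x, x$r)))
  invisible(x)
}

density_integral <- function(d, z) {
  if (d$method == "binned") sum(z) * d$h
  else pracma::trapz(d$grid, z)
}

#' Binned (histogram) density estimate
#'
#' Weighted histograms of the reactive and unreactive samples on `n_bins`
#' equal-width bins spanning the sampled range, normalised to densities.
#' This is the binning estimator the Savitzky-Golay pipeline replaces; it is
#' kept as an oracle for well-populated bins and to expose the small-bin
#' failure mode in which bins holding zero or one point of either kind drive
#' the overlap to zero.
#'
#' @param s a `ppa_samples` data.frame.
#' @param n_bins number of bins (>= 2).
#' @param cv CV column to use; may be omitted when there is only one.
#' @return A `ppa_density` with `method = "binned"`, `grid` at bin centres
#'   and `h` the bin width.
#' @export
binned_densities <- function(s, n_bins, cv = NULL) {
  if (n_bins < 2L) ppa_error("n_bins must be at least 2", "ppa_value_error")
  cv <- samples_cv_column(s, cv)
  psi <- s[[cv]]
  breaks <- seq(min(psi), max(psi), length.out = n_bins + 1L)
  h <- breaks[2L] - breaks[1L]
  q <- pmin(findInterval(psi, breaks), n_bins)
  W <- sum(s$weight)
  acc <- function(mask) {
    out <- rep(0, n_bins)
    if (any(mask)) {
      tt <- rowsum(s$weight[mask], q[mask])
      out[as.integer(rownames(tt))] <- tt[, 1L]
    }
    out / (W * h)
  }
  r <- acc(s$label == "reactive")
  u <- acc(s$label != "reactive")
  structure(list(grid = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                 r = r, u = u, t = r + u, h = h, method = "binned"),
            class = "ppa_density")
}
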