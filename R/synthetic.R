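# Synthetic path ensembles and labelled CV samples with known ground truth,
# so every analysis stage has a direct-counting or quadrature oracle.

#' Parameters of the coupled double-well toy system
#'
#' Overdamped Langevin dynamics on
#' \deqn{V(x, y) = h\,(x^2 - 1)^2 + y^2/2 + g\,x\,y}
#' in units of kT = 1, with the order parameter \eqn{\lambda = x}. The
#' hidden coordinate `y` is dynamically coupled to the barrier crossing
#' through `g`, so its value at a first crossing carries clear predictive
#' information, while an additional recorded white-noise channel carries
#' none by construction. Defaults give a moderately rare transition with a
#' 3 kT barrier. State boundaries sit inside the wells at
#' \eqn{\lambda_A = -0.7}, \eqn{\lambda_B = 0.7}.
#'
#' @param barrier_height barrier parameter `h` in kT (default 3).
#' @param coupling x-y coupling `g` (default 1.5).
#' @param friction friction coefficient (default 1).
#' @param temperature kT (default 1).
#' @param dt Euler-Maruyama time step (default 0.01).
#' @param lam_A,lam_B state boundaries on \eqn{\lambda = x}.
#' @param seed RNG seed.
#' @return An object of class `ppa_dw_params`.
#' @export
doublewell_params <- function(barrier_height = 3, coupling = 1.5,
                              friction = 1, temperature = 1, dt = 0.01,
                              lam_A = -0.7, lam_B = 0.7, seed = 1L) {
  if (barrier_height <= 0) ppa_error("barrier_height must be > 0", "ppa_value_error")
  if (dt <= 0) ppa_error("dt must be > 0", "ppa_value_error")
  if (lam_A >= lam_B) ppa_error("need lam_A < lam_B", "ppa_value_error")
  structure(list(barrier_height = barrier_height, coupling = coupling,
                 friction = friction, temperature = temperature, dt = dt,
                 lam_A = lam_A, lam_B = lam_B, seed = as.integer(seed)),
            class = "ppa_dw_params")
}

#' Long Langevin trajectory on the coupled double well
#'
#' Seeded Euler-Maruyama integration starting in the reactant well at
#' `(-1, g)`. Every step is recorded: `lambda = x`, and the CVs carried are
#' the coupled hidden coordinate `y` plus an independent standard-normal
#' `noise` channel.
#'
#' @param params a [doublewell_params()].
#' @param n_steps number of integration steps.
#' @return A data.frame with columns `time`, `lambda`, `y`, `noise`
#'   (`n_steps + 1` rows).
#' @export
langevin_doublewell <- function(params, n_steps) {
  stopifnot(inherits(params, "ppa_dw_params"))
  set.seed(params$seed)
  tr <- .dw_integrate(as.integer(n_steps), params$barrier_height,
                      params$coupling, params$friction, params$temperature,
                      params$dt, -1, params$coupling)
  data.frame(time = (0:n_steps) * params$dt, lambda = tr$x, y = tr$y,
             noise = stats::rnorm(n_steps + 1L))
}

#' Chop a long trajectory into [0-] and [0+] path segments
#'
#' Emulates the target distribution of path sampling: the segments of an
#' effectively infinite trajectory. State A is \eqn{\lambda < \lambda_A},
#' state B \eqn{\lambda \ge \lambda_B}. Each excursion -- from the last
#' frame inside A before an exit to the first frame back inside A or
#' reaching B -- becomes a `[0+]` path with unit weight; each maximal run of
#' frames inside A becomes a `[0-]` path. Junction frames are shared, so
#' segment durations of the A-attributed part of the trajectory sum to its
#' span. Stretches between reaching B and the next re-entry into A belong
#' to neither ensemble.
#'
#' Alongside the paths, direct-counting summaries measured on the uncut
#' trajectory are returned; they are the oracles for the reweighting stack.
#'
#' @param traj data.frame with columns `time`, `lambda` and CV columns, as
#'   from [langevin_doublewell()].
#' @param lam_A,lam_B state boundaries.
#' @return A list of class `ppa_chopped`: `paths` (ppa_path list, ensembles
#'   `"0-"`/`"0+"`), and `summary` with `n_segments`, `n_ab`, `lam_max`
#'   (per `[0+]` segment), `time_A` (A-attributed duration), direct
#'   `flux_per_time` and `rate_per_time`.
#' @export
chop_trajectory <- function(traj, lam_A, lam_B) {
  lam <- traj$lambda
  time <- traj$time
  n <- length(lam)
  in_A <- lam < lam_A
  if (!any(in_A)) ppa_error("trajectory never visits state A", "ppa_value_error")
  cols <- as.list(traj)
  # validation-free constructor: segments of a valid trajectory are valid
  make_path <- function(i0, i1, ens, cyc, end_side) {
    idx <- i0:i1
    frames <- structure(lapply(cols, function(col) col[idx]),
                        class = "data.frame",
                        row.names = c(NA_integer_, -(i1 - i0 + 1L)))
    structure(list(path_id = sprintf("%s-%d", ens, cyc), ensemble = ens,
                   mc_cycle = cyc, weight = 1, start_side = "A",
                   end_side = end_side, frames = frames),
              class = "ppa_path")
  }
  runs <- rle(in_A)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  a_starts <- starts[runs$values]
  a_ends <- ends[runs$values]
  # first frame in A or B after each A-run: excursion endpoints
  idx_AB <- which(in_A | lam >= lam_B)
  pos <- findInterval(a_ends, idx_AB) + 1L
  exc_end <- ifelse(pos <= length(idx_AB), idx_AB[pmin(pos, length(idx_AB))],
                    NA_integer_)

  n_runs <- length(a_starts)
  paths <- vector("list", 2L * n_runs)
  np <- 0L
  lam_max_seg <- numeric(n_runs)
  end_b <- logical(n_runs)
  n0m <- 0L
  n0p <- 0L
  time_A <- 0
  i_resume <- 1L  # first frame from which A-runs count (skips B->A returns)
  for (k in seq_len(n_runs)) {
    a0 <- a_starts[k]
    a1 <- a_ends[k]
    if (a0 < i_resume) next
    n0m <- n0m + 1L
    np <- np + 1L
    paths[[np]] <- make_path(a0, a1, "0-", n0m, "A")
    time_A <- time_A + time[a1] - time[a0]
    j <- exc_end[k]
    if (is.na(j)) break  # unfinished excursion at the end: discarded
    hit_b <- lam[j] >= lam_B
    n0p <- n0p + 1L
    np <- np + 1L
    paths[[np]] <- make_path(a1, j, "0+", n0p, if (hit_b) "B" else "A")
    lam_max_seg[n0p] <- max(lam[a1:j])
    end_b[n0p] <- hit_b
    time_A <- time_A + time[j] - time[a1]
    if (hit_b) i_resume <- j + 1L  # skip B-committed frames: not inside A,
                                   # so subsequent A-runs resume counting
  }
  if (!n0p) ppa_error("trajectory never leaves state A", "ppa_value_error")
  paths <- paths[seq_len(np)]
  lam_max_seg <- lam_max_seg[seq_len(n0p)]
  end_b <- end_b[seq_len(n0p)]
  structure(list(
    paths = paths,
    summary = list(n_segments = n0p, n_ab = sum(end_b),
                   lam_max = lam_max_seg, time_A = time_A,
                   flux_per_time = n0p / time_A,
                   rate_per_time = sum(end_b) / time_A)),
    class = "ppa_chopped")
}

#' Direct-counting crossing probability from a chopped trajectory
#'
#' The fraction of `[0+]` segments whose maximum reaches `lam`; the
#' brute-force oracle the WHAM/crossing-curve machinery is tested against.
#'
#' @param chopped a `ppa_chopped`.
#' @param lam query position(s).
#' @return Crossing probabilities, one per `lam`.
#' @export
direct_crossing_prob <- function(chopped, lam) {
  vapply(lam, function(l) mean(chopped$summary$lam_max >= l), 0)
}

#' Nested interface ensembles with known ground-truth weights
#'
#' Builds TIS-like `[i+]` ensembles from `[0+]` segments by independently
#' keeping each segment with \eqn{\lambda_{max} \ge \lambda_i} at a recorded
#' per-ensemble rate (by default chosen so all ensembles have about equal
#' size, as interface placement achieves in practice). Because the rates are
#' known, each sampled path also carries its exact ground-truth weight
#' `truth_weight` (proportional to the inverse of its expected number of
#' copies), for oracle comparisons against [wham_weights()].
#'
#' @param chopped a `ppa_chopped` (or a list of `[0+]` [ppa_path]s).
#' @param interfaces a [ppa_interfaces()]; ensembles `[0+] ... [(n-2)+]`.
#' @param rates optional per-ensemble keep rates in (0, 1].
#' @param seed RNG seed for the subsampling.
#' @return A list: `paths` (relabelled, unit weights, `truth_weight` field),
#'   `rates`.
#' @export
tis_like_subsets <- function(chopped, interfaces, rates = NULL, seed = 1L) {
  stopifnot(inherits(interfaces, "ppa_interfaces"))
  paths <- if (inherits(chopped, "ppa_chopped")) {
    ens <- vapply(chopped$paths, `[[`, "", "ensemble")
    chopped$paths[ens == "0+"]
  } else chopped
  if (!length(paths)) ppa_error("no [0+] segments", "ppa_value_error")
  lams <- interfaces$lambdas
  n_ens <- length(lams) - 1L
  m <- vapply(paths, lambda_max, 0)
  elig <- lapply(seq_len(n_ens), function(i) which(m >= lams[i]))
  n_elig <- vapply(elig, length, 0L)
  if (any(n_elig == 0L))
    ppa_error(sprintf("no segment reaches interface %d", which(n_elig == 0L)[1L]),
              "ppa_value_error")
  if (is.null(rates)) rates <- pmin(1, min(n_elig) / n_elig)
  if (length(rates) != n_ens || any(rates <= 0) || any(rates > 1))
    ppa_error("rates must be one value in (0,1] per ensemble", "ppa_value_error")

  set.seed(seed)
  out <- list()
  for (i in seq_len(n_ens)) {
    keep <- elig[[i]][stats::runif(n_elig[i]) < rates[i]]
    if (!length(keep))
      ppa_error(sprintf("empty ensemble [%d+] after subsampling", i - 1L),
                "ppa_value_error")
    for (k in seq_along(keep)) {
      p <- paths[[keep[k]]]
      p$ensemble <- sprintf("%d+", i - 1L)
      p$path_id <- sprintf("%s@%d+", p$path_id, i - 1L)
      p$mc_cycle <- k
      p$weight <- 1
      out[[length(out) + 1L]] <- p
    }
  }
  # expected copies of a segment with maximum m: sum of rates of the
  # ensembles it is eligible for
  mm <- vapply(out, lambda_max, 0)
  expected <- rowSums(outer(mm, lams[seq_len(n_ens)], `>=`) *
                        matrix(rates, length(mm), n_ens, byrow = TRUE))
  tw <- (1 / expected) / mean(1 / expected)
  for (k in seq_along(out)) out[[k]]$truth_weight <- tw[k]
  list(paths = out, rates = rates)
}

#' Specification of a labelled Gaussian-mixture sample set
#'
#' Defines reactive and unreactive densities as Gaussian mixtures,
#' \eqn{r(\Psi)} with total mass \eqn{\bar p} and \eqn{u(\Psi)} with mass
#' \eqn{1 - \bar p}, from which weighted first-crossing-like samples can be
#' drawn with [sample_mixture()] and whose exact predictive capacity is
#' available by quadrature ([mixture_true_capacity()]).
#'
#' @param r_components,u_components data.frames with columns `mean`, `sd`,
#'   `mass`; `r` masses must sum to `p_bar`, `u` masses to `1 - p_bar`.
#' @param p_bar average transition probability in (0, 1).
#' @param n number of samples to draw.
#' @param weight_law `"uniform"` or `"lognormal"`.
#' @param weight_sigma log-sd of the lognormal weight law.
#' @param seed RNG seed.
#' @return An object of class `ppa_mixture_spec`.
#' @export
mixture_spec <- function(r_components, u_components, p_bar,
                         n = 10000L, weight_law = c("uniform", "lognormal"),
                         weight_sigma = 1, seed = 1L) {
  weight_law <- match.arg(weight_law)
  r_components <- as.data.frame(r_components)
  u_components <- as.data.frame(u_components)
  for (d in list(r_components, u_components)) {
    if (!all(c("mean", "sd", "mass") %in% names(d)))
      ppa_error("components need mean, sd, mass columns", "ppa_value_error")
    if (any(d$sd <= 0)) ppa_error("component sds must be > 0", "ppa_value_error")
  }
  if (p_bar <= 0 || p_bar >= 1)
    ppa_error("p_bar must be in (0, 1)", "ppa_value_error")
  if (abs(sum(r_components$mass) - p_bar) > 1e-9 ||
      abs(sum(u_components$mass) - (1 - p_bar)) > 1e-9)
    ppa_error("r masses must sum to p_bar and u masses to 1 - p_bar",
              "ppa_value_error")
  structure(list(r = r_components, u = u_components, p_bar = p_bar,
                 n = as.integer(n), weight_law = weight_law,
                 weight_sigma = weight_sigma, seed = as.integer(seed)),
            class = "ppa_mixture_spec")
}

#' Mixture densities r, u, t of a specification
#'
#' @param spec a [mixture_spec()].
#' @param x evaluation points.
#' @param which one of `"r"`, `"u"`, `"t"`.
#' @return Density values at `x`.
#' @export
mixture_density <- function(spec, x, which = c("t", "r", "u")) {
  which <- match.arg(which)
  dens <- function(comp) {
    out <- 0
    for (i in seq_len(nrow(comp)))
      out <- out + comp$mass[i] * stats::dnorm(x, comp$mean[i], comp$sd[i])
    out
  }
  switch(which, r = dens(spec$r), u = dens(spec$u),
         t = dens(spec$r) + dens(spec$u))
}

#' Exact predictive capacity of a mixture specification by quadrature
#'
#' Fine-grid trapezoidal quadrature of the generating densities; the
#' ground truth the sample-based estimators are compared against.
#'
#' @param spec a [mixture_spec()].
#' @param n_grid quadrature grid size.
#' @return List with `capacity`, `overlap`, `p_bar`.
#' @export
mixture_true_capacity <- function(spec, n_grid = 200001L) {
  comps <- rbind(spec$r, spec$u)
  lo <- min(comps$mean - 10 * comps$sd)
  hi <- max(comps$mean + 10 * comps$sd)
  x <- seq(lo, hi, length.out = n_grid)
  r <- mixture_density(spec, x, "r")
  u <- mixture_density(spec, x, "u")
  t <- r + u
  z <- ifelse(t > 1e-300, r * u / t, 0)
  O <- pracma::trapz(x, z)
  p <- pracma::trapz(x, r)
  list(capacity = 1 - O / p, overlap = O, p_bar = p)
}

#' Draw a weighted labelled sample set from a mixture specification
#'
#' Samples \eqn{\Psi} from the total density \eqn{t = r + u} and labels each
#' draw reactive with probability \eqn{r(\Psi)/t(\Psi)}, so the reactive and
#' unreactive sample densities match the specification by construction.
#' Weights follow the spec's weight law (statistically independent of
#' \eqn{\Psi}, mimicking reweighted path ensembles).
#'
#' @param spec a [mixture_spec()].
#' @return A `ppa_samples` data.frame with CV column `psi`.
#' @export
sample_mixture <- function(spec) {
  stopifnot(inherits(spec, "ppa_mixture_spec"))
  set.seed(spec$seed)
  comps <- rbind(spec$r, spec$u)
  idx <- sample.int(nrow(comps), spec$n, replace = TRUE, prob = comps$mass)
  psi <- stats::rnorm(spec$n, comps$mean[idx], comps$sd[idx])
  pr <- mixture_density(spec, psi, "r") / mixture_density(spec, psi, "t")
  lab <- ifelse(stats::runif(spec$n) < pr, "reactive", "unreactive")
  w <- switch(spec$weight_law,
              uniform = rep(1, spec$n),
              lognormal = stats::rlnorm(spec$n, 0, spec$weight_sigma))
  structure(data.frame(path_id = sprintf("s%d", seq_len(spec$n)),
                       psi = psi, weight = w, label = lab),
            lam_c = NA_real_, lam_r = NA_real_,
            class = c("ppa_samples", "data.frame"))
}

#' Toy solvated ion pair configuration
#'
#' A Na/Cl pair at a given separation on the x axis in the centre of an
#' orthorhombic box, surrounded by rigid three-site waters (O-H 0.9572 A,
#' H-O-H 104.52 degrees, random orientations) placed by seeded rejection
#' sampling with a minimum oxygen-oxygen / oxygen-ion distance. A fixture
#' generator for the descriptor module; not a physical water model.
#'
#' @param n_waters number of waters.
#' @param ion_distance Na-Cl separation (Angstrom).
#' @param box three box edge lengths (Angstrom).
#' @param seed RNG seed.
#' @param min_dist minimum O-O and O-ion distance (default 2.4 A).
#' @param max_tries rejection-sampling budget per water.
#' @return A [configuration()].
#' @export
toy_solvated_pair <- function(n_waters, ion_distance = 3.2,
                              box = c(12, 12, 12), seed = 1L,
                              min_dist = 2.4, max_tries = 2000L) {
  set.seed(seed)
  box <- as.numeric(box)
  centre <- box / 2
  species <- c("Na", "Cl")
  coords <- rbind(centre - c(ion_distance / 2, 0, 0),
                  centre + c(ion_distance / 2, 0, 0))
  occupied <- coords
  b_len <- 0.9572
  half_ang <- 104.52 / 2 * pi / 180
  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (i in seq_len(n_waters)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      o <- stats::runif(3) * box
      d <- mi_dist(occupied, o, box)
      if (all(d >= min_dist)) {
        u1 <- rand_unit()
        axis <- rand_unit()
        axis <- axis - sum(axis * u1) * u1
        axis <- axis / sqrt(sum(axis^2))
        h1 <- o + b_len * (cos(half_ang) * u1 + sin(half_ang) * axis)
        h2 <- o + b_len * (cos(half_ang) * u1 - sin(half_ang) * axis)
        species <- c(species, "O", "H", "H")
        coords <- rbind(coords, o, h1, h2)
        occupied <- rbind(occupied, o)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      ppa_error(sprintf(
        "could not place water %d after %d tries; use a larger box",
        i, max_tries), "ppa_value_error")
  }
  configuration(species, coords, box)
}

#' Reference suite of labelled mixture specifications
#'
#' Ten Gaussian-mixture specifications spanning the regimes the estimator
#' has to handle: a small average transition probability typical of
#' reweighted path ensembles, an uninformative CV, strong and weak
#' separation, bimodal reactive or unreactive populations, heterogeneous
#' (lognormal) sample weights, an essentially perfect predictor, and a
#' sparsely populated mixing zone between the reactive- and
#' unreactive-dominant regions -- the regime in which fine histogram bins
#' hold zero or one point of either kind and the binned overlap collapses
#' while the integrated-distribution estimate does not (spec 10).
#'
#' @param n samples per specification (default 50000).
#' @param seed base seed; spec i uses `seed + i`.
#' @return A list of ten [mixture_spec()] objects.
#' @export
example_mixture_specs <- function(n = 50000L, seed = 100L) {
  cmp <- function(mean, sd, mass) data.frame(mean = mean, sd = sd, mass = mass)
  list(
    mixture_spec(cmp(2, 1, 0.086), cmp(0, 1, 0.914), 0.086, n,
                 seed = seed + 1L),
    mixture_spec(cmp(0, 1, 0.3), cmp(0, 1, 0.7), 0.3, n, seed = seed + 2L),
    mixture_spec(cmp(3, 0.7, 0.5), cmp(0, 1, 0.5), 0.5, n, seed = seed + 3L),
    mixture_spec(cmp(1, 1, 0.3), cmp(0, 1.5, 0.7), 0.3, n, "lognormal",
                 weight_sigma = 0.5, seed = seed + 4L),
    mixture_spec(cmp(0.5, 0.8, 0.5), cmp(0, 0.8, 0.5), 0.5, n, "lognormal",
                 weight_sigma = 1, seed = seed + 5L),
    mixture_spec(cmp(c(-2, 2), c(0.5, 0.5), c(0.2, 0.2)), cmp(0, 1, 0.6),
                 0.4, n, seed = seed + 6L),
    mixture_spec(cmp(4, 2, 0.7), cmp(0, 1, 0.3), 0.7, n, "lognormal",
                 weight_sigma = 1, seed = seed + 7L),
    mixture_spec(cmp(1.5, 0.5, 0.15), cmp(c(0, 1), c(0.6, 1.2), c(0.5, 0.35)),
                 0.15, n, "lognormal", weight_sigma = 0.5, seed = seed + 8L),
    mixture_spec(cmp(0, 1, 0.5), cmp(6, 1, 0.5), 0.5, n, seed = seed + 9L),
    mixture_spec(cmp(c(0, 10), c(1, 2.5), c(0.495, 0.005)),
                 cmp(c(20, 10), c(1, 2.5), c(0.495, 0.005)), 0.5, n,
                 seed = seed + 10L))
}
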