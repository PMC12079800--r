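# Builders shared across the test files. Everything is generated in code;
# nothing is read from disk unless a test writes it first.

# a path from a bare lambda series (10 fs spacing), CVs default to lambda
make_path <- function(lams, id = "p1", ens = "0+", cycle = 0, weight = 1,
                      dt = 10, cvs = NULL, start = "A", end = "A") {
  fr <- data.frame(time = (seq_along(lams) - 1) * dt, lambda = lams)
  if (is.null(cvs)) cvs <- list(cv = lams)
  for (nm in names(cvs)) fr[[nm]] <- cvs[[nm]]
  ppa_path(id, fr, ensemble = ens, mc_cycle = cycle, weight = weight,
           start_side = start, end_side = end)
}

# a small random ensemble of [0+]-style paths for round-trip properties
make_random_ensemble <- function(n_paths = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_paths), function(i) {
    n <- sample(3:12, 1)
    lams <- signif(3.0 + cumsum(abs(rnorm(n, 0.1, 0.05))), 10)
    cvs <- list(NaO6 = signif(rnorm(n, 2.5, 0.3), 10),
                NB = signif(runif(n, 0, 3), 10))
    make_path(lams, id = sprintf("p%02d", i), ens = "0+", cycle = i - 1,
              weight = signif(runif(1, 0.5, 2), 10), cvs = cvs)
  })
}

# weighted labelled samples directly from vectors
make_samples <- function(psi, weight = rep(1, length(psi)), label,
                         lam_c = NA_real_, lam_r = NA_real_) {
  structure(data.frame(path_id = sprintf("s%d", seq_along(psi)), psi = psi,
                       weight = weight, label = label),
            lam_c = lam_c, lam_r = lam_r,
            class = c("ppa_samples", "data.frame"))
}

# chopped toy trajectory reused by several files (computed once per session)
toy_chopped <- local({
  cache <- NULL
  function(n_steps = 1.5e6, seed = 42) {
    if (is.null(cache)) {
      pp <- doublewell_params(seed = seed)
      traj <- langevin_doublewell(pp, n_steps)
      cache <<- list(params = pp, chopped = chop_trajectory(traj, pp$lam_A,
                                                            pp$lam_B))
    }
    cache
  }
})

toy_interfaces <- function() ppa_interfaces(c(-0.7, -0.55, -0.35, -0.1, 0.25, 0.7))

# weighted paths on the toy system, WHAM-reweighted nested subsets; keep
# rates target roomy ensembles so curve factors are well determined
toy_weighted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tc <- toy_chopped()
      ifc <- toy_interfaces()
      m <- tc$chopped$summary$lam_max
      n_elig <- vapply(ifc$lambdas[-length(ifc$lambdas)],
                       function(l) sum(m >= l), 0L)
      sub <- tis_like_subsets(tc$chopped, ifc,
                              rates = pmin(1, 3000 / n_elig), seed = 7)
      cache <<- list(paths = wham_weights(sub$paths, ifc), rates = sub$rates,
                     interfaces = ifc)
    }
    cache
  }
})

# labelled samples whose success probability is a logistic in a planted
# direction of two of the three carried CVs
planted_samples <- function(n = 20000, seed = 5) {
  set.seed(seed)
  A <- rnorm(n)
  B <- rnorm(n)
  lab <- ifelse(runif(n) < plogis(4 * (0.7 * A - 0.3 * B) - 1),
                "reactive", "unreactive")
  structure(data.frame(path_id = as.character(seq_len(n)), A = A, B = B,
                       C = rnorm(n), weight = 1, label = lab),
            lam_c = NA_real_, lam_r = NA_real_,
            class = c("ppa_samples", "data.frame"))
}
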