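test_that("the integrator is reproducible and flags divergence", {
  pp <- doublewell_params(seed = 99)
  a <- langevin_doublewell(pp, 5000)
  b <- langevin_doublewell(pp, 5000)
  expect_identical(a, b)
  expect_false(identical(a$lambda,
                         langevin_doublewell(doublewell_params(seed = 100),
                                             5000)$lambda))
  bad <- doublewell_params(dt = 5, seed = 1)
  expect_error(langevin_doublewell(bad, 10000), "smaller dt")
})

test_that("the uncoupled double well is symmetric about the barrier", {
  pp <- doublewell_params(coupling = 0, seed = 31)
  x <- langevin_doublewell(pp, 2e6)$lambda[1:2e6]
  blocks <- split(x > 0, rep(1:40, each = length(x) / 40))
  occ <- vapply(blocks, mean, 0)
  tt <- t.test(occ, mu = 0.5)
  expect_gt(tt$p.value, 0.01)
})

test_that("the equilibrium x-histogram matches the Boltzmann marginal", {
  pp <- doublewell_params(seed = 17)
  x <- langevin_doublewell(pp, 4e6)$lambda
  xs <- x[seq(1, length(x), by = 2000)]  # decorrelated subsample
  # y-marginalised potential: V_eff = h (x^2-1)^2 - g^2 x^2 / 2
  grid <- seq(-2.2, 2.2, length.out = 4001)
  dens <- exp(-(pp$barrier_height * (grid^2 - 1)^2 -
                  pp$coupling^2 * grid^2 / 2))
  cdf <- cumsum(dens) / sum(dens)
  qs <- grid[findInterval(seq(0.1, 0.9, by = 0.1), cdf) + 1L]
  br <- c(-Inf, qs, Inf)
  p_exp <- diff(c(0, approx(grid, cdf, qs, rule = 2)$y, 1))
  obs <- as.vector(table(cut(xs, br)))
  ct <- suppressWarnings(stats::chisq.test(obs, p = p_exp, rescale.p = TRUE))
  expect_gt(ct$p.value, 0.01)
})

test_that("a hand-built series chops into the expected segments", {
  lam <- c(1, 1.5, 2.5, 3, 1.2, 0.8, 2.2, 5.5, 6, 4,
           1, 0.5, 3, 2.8, 1.9, 1.0, 2.1, 1.5, 2.4, 2.6)
  traj <- data.frame(time = 0:19, lambda = lam, y = 0, noise = 0)
  ch <- chop_trajectory(traj, lam_A = 2, lam_B = 5)
  s <- ch$summary
  expect_equal(s$n_segments, 4L)
  expect_equal(s$n_ab, 1L)
  expect_equal(s$lam_max, c(3, 5.5, 3, 2.1))
  expect_equal(s$time_A, 14)
  ens <- vapply(ch$paths, `[[`, "", "ensemble")
  expect_equal(sum(ens == "0-"), 5L)
  p0p <- ch$paths[ens == "0+"]
  expect_equal(lapply(p0p, function(p) range(p$frames$time)),
               list(c(1, 4), c(5, 7), c(11, 14), c(15, 17)))
  expect_equal(vapply(p0p, `[[`, "", "end_side"), c("A", "B", "A", "A"))
  # segment durations never exceed the trajectory span
  expect_lte(sum(vapply(ch$paths, function(p)
    diff(range(p$frames$time)), 0)), 19)
  expect_error(chop_trajectory(data.frame(time = 0:2, lambda = c(5, 6, 7)),
                               2, 5), class = "ppa_value_error")
})

test_that("unit-weight segments reproduce direct counting exactly", {
  tc <- toy_chopped()
  ens <- vapply(tc$chopped$paths, `[[`, "", "ensemble")
  p0p <- tc$chopped$paths[ens == "0+"]
  probe <- c(-0.7, -0.4, 0, 0.5, 0.7)
  cv <- crossing_curve(p0p, probe, lam_A = -0.7)
  expect_identical(cv$prob, direct_crossing_prob(tc$chopped, probe))
})

test_that("subsampled ensembles are reproducible and honest about rates", {
  tc <- toy_chopped()
  ifc <- toy_interfaces()
  a <- tis_like_subsets(tc$chopped, ifc, seed = 5)
  b <- tis_like_subsets(tc$chopped, ifc, seed = 5)
  expect_identical(vapply(a$paths, `[[`, "", "path_id"),
                   vapply(b$paths, `[[`, "", "path_id"))
  expect_length(a$rates, length(ifc$lambdas) - 1L)

  # keep-everything rates: WHAM must return near-uniform weights per stratum
  ens0 <- vapply(tc$chopped$paths, `[[`, "", "ensemble")
  p0p <- tc$chopped$paths[ens0 == "0+"][1:2000]
  two <- ppa_interfaces(c(-0.7, 0.7))
  sub <- tis_like_subsets(p0p, two, rates = 1, seed = 2)
  w <- vapply(wham_weights(sub$paths, two), `[[`, 0, "weight")
  expect_equal(w, rep(1, length(w)))
  expect_equal(vapply(sub$paths, `[[`, 0, "truth_weight"),
               rep(1, length(sub$paths)))
})

test_that("halving the time step leaves the crossing statistics unchanged", {
  p1 <- doublewell_params(seed = 3)
  p2 <- doublewell_params(dt = 0.005, seed = 4)
  c1 <- chop_trajectory(langevin_doublewell(p1, 1e6), -0.7, 0.7)$summary
  c2 <- chop_trajectory(langevin_doublewell(p2, 2e6), -0.7, 0.7)$summary
  p <- c(mean(c1$lam_max >= 0.7), mean(c2$lam_max >= 0.7))
  se <- sqrt(p[1] * (1 - p[1]) / c1$n_segments +
               p[2] * (1 - p[2]) / c2$n_segments)
  expect_lt(abs(p[1] - p[2]), 3 * se)
})

test_that("mixture draws have the capacity their construction implies", {
  # same shape for r and u: uninformative, capacity = p_bar
  sp <- mixture_spec(data.frame(mean = 0, sd = 1, mass = 0.35),
                     data.frame(mean = 0, sd = 1, mass = 0.65),
                     0.35, n = 20000L, seed = 3L)
  expect_equal(mixture_true_capacity(sp)$capacity, 0.35, tolerance = 1e-9)
  cap <- capacity_from_samples(sample_mixture(sp))
  expect_equal(cap$capacity, 0.35, tolerance = 0.02)

  # disjoint components: capacity = 1
  sp2 <- mixture_spec(data.frame(mean = 0, sd = 0.5, mass = 0.5),
                      data.frame(mean = 10, sd = 0.5, mass = 0.5),
                      0.5, n = 20000L, seed = 4L)
  expect_equal(mixture_true_capacity(sp2)$capacity, 1, tolerance = 1e-9)
  expect_gte(capacity_from_samples(sample_mixture(sp2))$capacity, 0.98)

  # a generic spec against its quadrature value
  sp3 <- mixture_spec(data.frame(mean = 1.2, sd = 0.8, mass = 0.25),
                      data.frame(mean = c(0, 2.5), sd = c(1, 1.5),
                                 mass = c(0.5, 0.25)),
                      0.25, n = 50000L, weight_law = "lognormal",
                      weight_sigma = 0.7, seed = 5L)
  expect_equal(capacity_from_samples(sample_mixture(sp3))$capacity,
               mixture_true_capacity(sp3)$capacity, tolerance = 0.02)

  expect_error(mixture_spec(data.frame(mean = 0, sd = 1, mass = 0.3),
                            data.frame(mean = 0, sd = 1, mass = 0.5),
                            0.3), class = "ppa_value_error")
})

test_that("the solvated-pair fixture respects geometry and seeding", {
  bare <- toy_solvated_pair(0, ion_distance = 3.2)
  expect_equal(bare$species, c("Na", "Cl"))
  expect_equal(min_image_distance(bare$coords[1, ], bare$coords[2, ],
                                  bare$box), 3.2)

  a <- toy_solvated_pair(10, seed = 9)
  b <- toy_solvated_pair(10, seed = 9)
  expect_identical(a, b)

  heavy <- which(a$species != "H")
  d <- as.matrix(dist(a$coords[heavy, ]))
  diag(d) <- Inf
  # direct-space check is sufficient: the box is wide open at this filling
  expect_gte(min(d[-(1:2), -(1:2)]), 2.4)

  expect_error(toy_solvated_pair(100, box = c(6, 6, 6), max_tries = 50),
               "box", class = "ppa_value_error")
})
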