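test_that("weighted step distributions follow the defining partial sums", {
  s <- make_samples(c(1, 2, 3), c(1, 2, 1),
                    c("reactive", "unreactive", "reactive"))
  cd <- weighted_cdfs(s)
  expect_equal(cd$cv, c(1, 2, 3))
  expect_equal(cd$R, c(0.25, 0.25, 0.5))
  expect_equal(cd$U, c(0, 0.5, 0.5))
  expect_equal(cd$W, 4)

  # no reactive samples: R identically zero, U ends at one
  s2 <- make_samples(c(0, 1, 2), label = rep("unreactive", 3))
  cd2 <- weighted_cdfs(s2)
  expect_equal(cd2$R, rep(0, 3))
  expect_equal(cd2$U[3], 1)

  # duplicate CV values merge into a single step of combined height
  s3 <- make_samples(c(1, 1, 2), c(1, 1, 2),
                     c("reactive", "reactive", "unreactive"))
  cd3 <- weighted_cdfs(s3)
  expect_equal(cd3$cv, c(1, 2))
  expect_equal(cd3$R, c(0.5, 0.5))

  s4 <- make_samples(rep(1, 4), label = rep("reactive", 4))
  expect_error(weighted_cdfs(s4), "degenerate", class = "ppa_degenerate_error")
})

test_that("regridding spans the sampled range with linear interpolation", {
  s <- make_samples(c(0, 1), label = c("reactive", "unreactive"))
  g <- regrid(weighted_cdfs(s), 2000L)
  expect_length(g$grid, 2000L)
  expect_equal(diff(g$grid)[1], 1 / 1999)

  g3 <- regrid(weighted_cdfs(s), 16L)
  expect_equal(g3$grid[c(1, 16)], c(0, 1))
  expect_error(regrid(weighted_cdfs(s), 8L), class = "ppa_value_error")

  # regridded values reproduce the step values at the original sample CVs
  set.seed(2)
  psi <- sort(runif(50))
  s <- make_samples(psi, runif(50, 0.5, 2),
                    sample(c("reactive", "unreactive"), 50, replace = TRUE))
  cd <- weighted_cdfs(s)
  g <- regrid(cd, 2000L)
  at <- approx(g$grid, g$R, cd$cv)$y
  slope_bound <- max(abs(diff(cd$R)) / pmax(diff(cd$cv), 1e-12))
  expect_lt(max(abs(at - cd$R)), slope_bound * diff(g$grid)[1] + 1e-12)
  expect_true(all(diff(g$R) >= -1e-12))
  expect_true(all(diff(g$U) >= -1e-12))
})

test_that("plateau padding adds the configured number of flat points", {
  s <- make_samples(seq(0, 1, length.out = 30),
                    label = rep(c("reactive", "unreactive"), 15))
  g <- regrid(weighted_cdfs(s), 2000L)
  p <- pad_plateaus(g, 1 / 4)
  expect_length(p$grid, 3000L)
  expect_equal(p$n_pad, 500L)
  expect_equal(p$R[1:500], rep(0, 500))
  expect_equal(p$R[2501:3000], rep(g$R[2000], 500))
  expect_true(all(diff(p$R) >= -1e-12))
  expect_equal(diff(p$grid)[1], diff(g$grid)[1])
  expect_identical(pad_plateaus(g, 0), g)
})

test_that("the window rule gives the nearest odd length with a floor of 5", {
  expect_identical(sg_window(2000, 1 / 16), 125L)
  expect_identical(sg_window(16, 1 / 16), 5L)
  expect_identical(sg_window(10000, 1 / 16), 625L)
})

test_that("the filter derivative is exact on low-order polynomials", {
  n_gp <- 400L
  grid <- seq(0, 1, length.out = n_gp)
  mk_icdf <- function(R) structure(list(grid = grid, R = R, U = 0.5 * R,
                                        n_pad = 0L), class = "ppa_icdf")
  st <- sg_settings(n_gp = n_gp)
  win <- sg_window(n_gp, st$window_fraction)

  # straight line of slope s
  d <- sg_derivative(pad_plateaus(mk_icdf(0.4 * grid), 1 / 4), st)
  core <- (win + 1):(n_gp - win)  # away from the plateau junctions
  expect_lt(max(abs(d$r[core] - 0.4)), 1e-10)
  expect_equal(d$t, d$r + d$u)

  # quadratic: derivative 0.8 x at polyorder 2
  d2 <- sg_derivative(pad_plateaus(mk_icdf(0.4 * grid^2), 1 / 4), st)
  expect_lt(max(abs(d2$r[core] - 0.8 * grid[core])), 1e-10)
})

test_that("estimated densities converge to the generating mixture", {
  spec <- mixture_spec(data.frame(mean = 2, sd = 1, mass = 0.4),
                       data.frame(mean = 0, sd = 1, mass = 0.6),
                       0.4, n = 50000L, seed = 31L)
  s <- sample_mixture(spec)
  d <- estimate_densities(s)
  truth <- mixture_density(spec, d$grid, "r")
  expect_lt(max(abs(d$r - truth)), 0.05 * max(truth))

  # error decreases with sample size (sup norm over the central region)
  errs <- vapply(c(2000L, 20000L), function(n) {
    sp <- mixture_spec(data.frame(mean = 2, sd = 1, mass = 0.4),
                       data.frame(mean = 0, sd = 1, mass = 0.6),
                       0.4, n = n, seed = 77L)
    dd <- estimate_densities(sample_mixture(sp))
    tr <- mixture_density(sp, dd$grid, "r")
    max(abs(dd$r - tr))
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("labels independent of the CV give r proportional to t", {
  set.seed(5)
  n <- 20000
  psi <- rnorm(n)
  lab <- ifelse(runif(n) < 0.3, "reactive", "unreactive")
  d <- estimate_densities(make_samples(psi, label = lab))
  expect_lt(max(abs(d$r - 0.3 * d$t)), 0.05 * max(d$t))
})

test_that("single-label and disjoint-support limits behave", {
  set.seed(6)
  s <- make_samples(rnorm(5000), label = rep("reactive", 5000))
  d <- estimate_densities(s)
  expect_lt(max(abs(d$u)), 1e-12)

  psi <- c(runif(5000, 0, 1), runif(5000, 2, 3))
  lab <- rep(c("reactive", "unreactive"), each = 5000)
  d2 <- estimate_densities(make_samples(psi, label = lab))
  mid <- d2$grid > 1.3 & d2$grid < 1.7  # away from SG leakage at the gap edges
  expect_lt(max(abs((d2$r * d2$u)[mid])), 1e-6)
})

test_that("total mass is conserved through the filter", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    psi <- c(rnorm(8000), rnorm(4000, 3))
    lab <- ifelse(runif(12000) < 0.4, "reactive", "unreactive")
    d <- estimate_densities(make_samples(psi, label = lab))
    expect_equal(pracma::trapz(d$grid, d$t), 1, tolerance = 1e-3)
  }
})

test_that("affine CV transforms leave the overlap invariant", {
  set.seed(8)
  n <- 8000
  psi <- rnorm(n)
  lab <- ifelse(runif(n) < plogis(2 * psi), "reactive", "unreactive")
  w <- runif(n, 0.5, 2)
  base <- overlap_integral(estimate_densities(make_samples(psi, w, lab)))
  # dyadic scale and shift: exact in floating point
  dy <- overlap_integral(estimate_densities(make_samples(2 * psi + 0.5, w, lab)))
  expect_equal(dy, base, tolerance = 1e-12)
  # non-dyadic affine map agrees to rounding
  nd <- overlap_integral(estimate_densities(make_samples(0.3 * psi + 1.7, w, lab)))
  expect_equal(nd, base, tolerance = 1e-9)
})

test_that("the overlap is robust to the window fraction", {
  spec <- mixture_spec(data.frame(mean = 1.5, sd = 1, mass = 0.4),
                       data.frame(mean = 0, sd = 1, mass = 0.6),
                       0.4, n = 30000L, seed = 12L)
  s <- sample_mixture(spec)
  os <- vapply(c(1 / 32, 1 / 16, 1 / 8), function(wf)
    overlap_integral(estimate_densities(s, sg_settings(window_fraction = wf))),
    0)
  expect_lt(max(os) - min(os), 0.02)
})

test_that("binned densities count what falls in each bin", {
  s <- make_samples(c(0.1, 0.4, 2.6, 2.9), c(1, 1, 1, 1),
                    c("reactive", "reactive", "unreactive", "unreactive"))
  d <- binned_densities(s, 2)
  expect_equal(d$method, "binned")
  h <- d$h
  expect_equal(d$r, c(0.5 / h, 0))
  expect_equal(d$u, c(0, 0.5 / h))
  expect_error(binned_densities(s, 1), class = "ppa_value_error")

  # one point per bin with alternating labels: r*u vanishes binwise
  s2 <- make_samples(seq(0, 1, length.out = 8),
                     label = rep(c("reactive", "unreactive"), 4))
  d2 <- binned_densities(s2, 8)
  expect_equal(d2$r * d2$u, rep(0, 8))

  # mass conserved as bins shrink
  set.seed(3)
  s3 <- make_samples(rnorm(500), runif(500, 0.5, 2),
                     sample(c("reactive", "unreactive"), 500, replace = TRUE))
  for (nb in c(10, 100, 1000))
    expect_equal(sum(binned_densities(s3, nb)$t) *
                   binned_densities(s3, nb)$h, 1, tolerance = 1e-9)
})

test_that("settings validate and high polynomial orders need an override", {
  expect_error(sg_settings(polyorder = 3), class = "ppa_value_error")
  st <- sg_settings(polyorder = 3, allow_high_order = TRUE)
  expect_equal(st$polyorder, 3L)
  expect_error(sg_settings(n_gp = 8), class = "ppa_value_error")
  expect_error(sg_settings(window_fraction = 1.2), class = "ppa_value_error")
})
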