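test_that("minimum-image distances wrap each axis independently", {
  expect_equal(min_image_distance(c(0, 0, 0), c(29, 0, 0), c(30, 30, 30)), 1)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), c(30, 30, 30)), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(29, 0, 0)), 29)

  # oracle: brute-force minimum over the 27 periodic images
  set.seed(17)
  box <- c(11, 13, 17)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in 1:200) {
    a <- runif(3) * box
    b <- runif(3) * box
    images <- sweep(shifts, 2, box, `*`)
    brute <- min(sqrt(rowSums((matrix(b, 27, 3, byrow = TRUE) + images -
                                 matrix(a, 27, 3, byrow = TRUE))^2)))
    expect_equal(min_image_distance(a, b, box), brute, tolerance = 1e-12)
  }
})

test_that("a hand-placed five-atom matrix matches hand-computed distances", {
  # Na at 0, Cl at 3, O at 1, two H at 0.9 and 1.4 along x
  cfg <- configuration(c("Na", "Cl", "O", "H", "H"),
                       rbind(c(0, 0, 0), c(3, 0, 0), c(1, 0, 0),
                             c(0.9, 0, 0), c(1.4, 0, 0)))
  spec <- iidm_spec("Na", c(Cl = 1, O = 1, H = 2),
                    exclude_intramolecular_h = FALSE)
  m <- build_iidm(cfg, spec)
  expect_equal(m$features[["NaCl1"]], 3)
  expect_equal(m$features[["NaO1"]], 1)
  expect_equal(m$features[["NaH1"]], 0.9)
  expect_equal(m$features[["NaH2"]], 1.4)
  # columns: neighbours of the O row atom within the truncated pool
  expect_equal(m$features[["NaO1H1"]], 0.1)
  expect_equal(m$features[["NaO1H2"]], 0.4)
  expect_equal(m$features[["NaO1Cl1"]], 2)
  expect_equal(m$features[["NaCl1O1"]], 2)
  # sorted-row monotonicity
  expect_lte(m$features[["NaH1"]], m$features[["NaH2"]])
})

test_that("the matrix is invariant to input indexing and rigid motions", {
  cfg <- toy_solvated_pair(12, seed = 3)
  spec <- iidm_spec("Na", c(Cl = 1, O = 6, H = 12))
  m <- build_iidm(cfg, spec)

  set.seed(4)
  for (i in 1:5) {
    perm <- sample(length(cfg$species))
    shuffled <- configuration(cfg$species[perm], cfg$coords[perm, ], cfg$box)
    expect_identical(build_iidm(shuffled, spec)$features, m$features)
  }

  # rigid rotation + translation of a non-periodic cluster
  cfg_free <- configuration(cfg$species, cfg$coords, box = NULL)
  m_free <- build_iidm(cfg_free, spec)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- configuration(cfg$species,
                         cfg$coords %*% t(Rz) + matrix(c(5, -2, 1),
                                                       nrow(cfg$coords), 3,
                                                       byrow = TRUE))
  expect_equal(build_iidm(moved, spec)$features, m_free$features,
               tolerance = 1e-10)
})

test_that("row monotonicity holds for every species block", {
  cfg <- toy_solvated_pair(15, seed = 8)
  m <- build_iidm(cfg, iidm_spec("Cl", c(Na = 1, O = 8, H = 16)))
  for (sp in c("O", "H")) {
    d <- m$features[sprintf("Cl%s%d", sp, 1:(if (sp == "O") 8 else 16))]
    expect_true(all(diff(d) >= 0))
  }
})

test_that("single features agree with brute-force sorting", {
  cfg <- toy_solvated_pair(10, seed = 5)
  spec <- iidm_spec("Na", c(Cl = 1, O = 8, H = 16),
                    exclude_intramolecular_h = FALSE)
  na <- which(cfg$species == "Na")
  os <- which(cfg$species == "O")
  d_o <- sort(apply(cfg$coords[os, ], 1, function(r)
    min_image_distance(cfg$coords[na, ], r, cfg$box)))
  expect_equal(iidm_feature(cfg, spec, "NaO6"), d_o[6])
  expect_equal(iidm_feature(cfg, spec, "NaO1"), d_o[1])

  # NaO6H4: 4th-closest hydrogen (within the pool) to the 6th-closest oxygen
  o6 <- os[order(apply(cfg$coords[os, ], 1, function(r)
    min_image_distance(cfg$coords[na, ], r, cfg$box)))][6]
  m <- build_iidm(cfg, spec)
  pool_h <- which(cfg$species == "H")[order(apply(
    cfg$coords[which(cfg$species == "H"), ], 1, function(r)
      min_image_distance(cfg$coords[na, ], r, cfg$box)))][1:16]
  d_h <- sort(apply(cfg$coords[pool_h, , drop = FALSE], 1, function(r)
    min_image_distance(cfg$coords[o6, ], r, cfg$box)))
  expect_equal(m$features[["NaO6H4"]], d_h[4])

  expect_error(iidm_feature(cfg, spec, "Na-O6"), class = "ppa_value_error")
  expect_error(iidm_feature(cfg, spec, "NaO99"), class = "ppa_value_error")
})

test_that("intramolecular hydrogens are excluded from O rows by default", {
  cfg <- toy_solvated_pair(6, seed = 21)
  m_ex <- build_iidm(cfg, iidm_spec("Na", c(Cl = 1, O = 3, H = 6)))
  m_in <- build_iidm(cfg, iidm_spec("Na", c(Cl = 1, O = 3, H = 6),
                                    exclude_intramolecular_h = FALSE))
  # with exclusion, the closest H to any O row atom is at least a
  # hydrogen-bond distance away, not a covalent bond length
  expect_gt(m_ex$features[["NaO1H1"]], 1.2)
  expect_lt(m_in$features[["NaO1H1"]], 1.0)
})

test_that("missing atoms raise an error naming the species", {
  cfg <- toy_solvated_pair(2, seed = 1)
  expect_error(build_iidm(cfg, iidm_spec("Na", c(Cl = 1, O = 15, H = 30))),
               "'O'", class = "ppa_value_error")
})

test_that("the switching count transitions through 1/4 at the shell radius", {
  # one water oxygen exactly at r0 from both ions
  r0 <- 3
  d <- 4
  y <- sqrt(r0^2 - (d / 2)^2)
  cfg <- configuration(c("Na", "Cl", "O"),
                       rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0), c(0, y, 0)))
  expect_equal(switching_count(cfg, "Na", "Cl", r0, steepness = 4), 0.25,
               tolerance = 1e-9)

  # nothing within reach: essentially zero
  far <- configuration(c("Na", "Cl", "O"),
                       rbind(c(0, 0, 0), c(4, 0, 0), c(50, 0, 0)))
  expect_lt(switching_count(far, "Na", "Cl", r0, steepness = 4), 1e-3)

  # steepness -> infinity approaches the hard-cutoff count
  cfg2 <- toy_solvated_pair(20, box = c(14, 14, 14), seed = 6)
  ions <- cfg2$coords[1:2, ]
  os <- cfg2$coords[cfg2$species == "O", ]
  hard <- sum(apply(os, 1, function(r)
    min_image_distance(ions[1, ], r, cfg2$box) < r0 &&
      min_image_distance(ions[2, ], r, cfg2$box) < r0))
  expect_equal(switching_count(cfg2, "Na", "Cl", r0, steepness = 500), hard,
               tolerance = 1e-3)

  # monotone non-increasing as a single water moves away from an ion
  vals <- vapply(seq(2, 8, by = 0.5), function(x) {
    c3 <- configuration(c("Na", "Cl", "O"),
                        rbind(c(0, 0, 0), c(3.2, 0, 0), c(x, 0, 0)))
    switching_count(c3, "Na", "Cl", 3, 4)
  }, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("largest cosine picks the most axis-aligned shell member", {
  # single candidate collinear with the arm: cos = 1
  cfg <- configuration(c("Na", "Cl", "H"),
                       rbind(c(-3, 0, 0), c(0, 0, 0), c(-1.5, 0, 0)))
  expect_equal(largest_cosine(cfg, "Cl", "Na", "H", 4), 1, tolerance = 1e-12)
  # perpendicular candidate: cos = 0
  cfg2 <- configuration(c("Na", "Cl", "H"),
                        rbind(c(-3, 0, 0), c(0, 0, 0), c(0, 2, 0)))
  expect_equal(largest_cosine(cfg2, "Cl", "Na", "H", 4), 0, tolerance = 1e-12)
  expect_error(largest_cosine(cfg2, "Cl", "Na", "H", 1),
               class = "ppa_value_error")

  # brute-force enumeration oracle over random candidates
  set.seed(13)
  hs <- matrix(rnorm(30, sd = 1.5), 10, 3)
  cfg3 <- configuration(c("Na", "Cl", rep("H", 10)),
                        rbind(c(-3, 0, 0), c(0, 0, 0), hs))
  v1 <- c(-3, 0, 0) / 3
  cosines <- apply(hs, 1, function(h) sum(h * v1) / sqrt(sum(h^2)))
  within <- sqrt(rowSums(hs^2)) <= 2.5
  expect_equal(largest_cosine(cfg3, "Cl", "Na", "H", 2.5),
               max(cosines[within]))
})

test_that("axial density maps conserve mass and locate shells", {
  # one atom at the axis midpoint: all mass in a single cell
  cfg <- configuration(c("Na", "Cl", "O"),
                       rbind(c(0, 0, 0), c(4, 0, 0), c(2, 0.1, 0)))
  m <- axial_density_map(list(cfg), c("Na", "Cl"), "O", ranks = 1,
                         n_axial = 4, n_radial = 3,
                         axial_range = c(0, 4), radial_max = 1)
  expect_equal(sum(m$density > 0), 1L)
  cell <- diff(m$axial_breaks)[1] * diff(m$radial_breaks)[1]
  expect_equal(sum(m$density) * cell, 1)

  # degenerate axis
  bad <- configuration(c("Na", "Cl", "O"),
                       rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_error(axial_density_map(list(bad), c("Na", "Cl"), "O"),
               class = "ppa_value_error")

  # isotropic shell around the first anchor peaks at the shell radius
  set.seed(23)
  shell_cfgs <- lapply(1:200, function(i) {
    u <- matrix(rnorm(45), 15, 3)
    u <- u / sqrt(rowSums(u^2)) * 3  # radius-3 shell
    configuration(c("Na", "Cl", rep("O", 15)),
                  rbind(c(0, 0, 0), c(8, 0, 0), u))
  })
  m2 <- axial_density_map(shell_cfgs, c("Na", "Cl"), "O", ranks = 1:15,
                          n_axial = 2, n_radial = 12,
                          axial_range = c(-4, 4), radial_max = 4)
  cell2 <- diff(m2$axial_breaks)[1] * diff(m2$radial_breaks)[1]
  expect_equal(sum(m2$density) * cell2, 15, tolerance = 1e-9)
  radial_profile <- colSums(m2$density)
  # peak radial bin contains r = 3
  peak <- which.max(radial_profile)
  expect_true(m2$radial_breaks[peak] <= 3 && 3 <= m2$radial_breaks[peak + 1])
})
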