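mat <- fixture_material()
ml <- load_material(mat)
np <- build_simple_np(1, 5, ml, psi0_mV = -20)
helix <- fixture_model(10, "helix")

test_that("the scan rotation maps the body direction onto -z", {
  v <- c(cos(30 * pi / 180) * sin(60 * pi / 180),
         sin(30 * pi / 180) * sin(60 * pi / 180),
         cos(60 * pi / 180))
  m <- bead_model(data.frame(code = "ALA", x = c(0, v[1]), y = c(0, v[2]),
                             z = c(0, v[3])))
  r <- rotate_model(m, 30, 60)
  dir <- unlist(r$beads[2, c("x", "y", "z")]) -
    unlist(r$beads[1, c("x", "y", "z")])
  expect_equal(unname(dir), c(0, 0, -1), tolerance = 1e-12)
  ## phi = 0, theta = 180 is the identity
  r0 <- rotate_model(helix, 0, 180)
  expect_equal(r0$beads$x, helix$beads$x, tolerance = 1e-12)
  expect_equal(r0$beads$z, helix$beads$z, tolerance = 1e-12)
  ## rotations are isometries
  r2 <- rotate_model(helix, 123, 47, 31)
  d0 <- dist(as.matrix(helix$beads[, c("x", "y", "z")]))
  d2 <- dist(as.matrix(r2$beads[, c("x", "y", "z")]))
  expect_equal(as.vector(d2), as.vector(d0), tolerance = 1e-12)
})

test_that("free-energy integral honours its closed forms", {
  ## zero potential integrates to exactly zero for any alpha
  for (a in 0:2)
    expect_identical(free_energy_integral(function(x) 0 * x, c(5, 12), a), 0)
  ## constant well of depth eps gives exactly -eps
  expect_equal(free_energy_integral(function(x) 0 * x - 3, c(5, 12), 2), -3,
               tolerance = 1e-12)
  ## halving the quadrature step barely moves the result
  sw <- function(x) -5 * exp(-(x - 6)^2)
  e1 <- free_energy_integral(sw, c(5, 10), 2, step = 0.05)
  e2 <- free_energy_integral(sw, c(5, 10), 2, step = 0.025)
  expect_lt(abs(e1 - e2), 0.01)
  expect_error(free_energy_integral(function(x) 0 * x, c(5, 5), 0), "R_max")
})

test_that("integration bounds follow the contact conventions", {
  ## point bead: first contact at the NP surface, outer bound R1b + 2
  one <- bead_model(data.frame(code = "ALA", x = 0, y = 0, z = 0))
  b <- integration_bounds(np, one)
  expect_equal(unname(b), c(5, 7))
  ## a dumbbell straddling the NP: full-scan reaches deeper than default
  db <- bead_model(data.frame(code = c("ALA", "ALA"), x = c(0, 0),
                              y = c(0, 0), z = c(3, -3)))
  np_small <- build_simple_np(1, 1, ml)
  b_def <- integration_bounds(np_small, db)
  b_full <- integration_bounds(np_small, db, full_scan = TRUE)
  expect_equal(unname(b_def[1]), 4)   # lower arm contacts on approach
  expect_equal(unname(b_full[1]), 0)  # straddling position is allowed
  expect_lt(b_full[1], b_def[1])
})

test_that("presum and full summation agree for a single spherical bead", {
  one <- bead_model(data.frame(code = "ALA", x = 0, y = 0, z = 0))
  tabs <- coronaforge:::presum_tables(np, one)
  h <- c(5.52, 6.02, 7.02)  # aligned with the presum grid
  up <- total_potential(np, one, h, "presum", tables = tabs)
  uf <- total_potential(np, one, h, "full")
  expect_equal(up, uf, tolerance = 1e-9)
  ## off-grid multi-bead agreement is limited only by table interpolation
  rot <- rotate_model(helix, 40, 70)
  hh <- seq(6.2, 8, by = 0.3)
  expect_equal(total_potential(np, rot, hh, "presum"),
               total_potential(np, rot, hh, "full"), tolerance = 1e-3)
  ## zero-weight beads contribute nothing
  m0 <- bead_model(data.frame(code = c("ALA", "ASP"), x = 0, y = 0,
                              z = c(0.4, -0.4), alpha = c(1, 0)))
  m1 <- bead_model(data.frame(code = "ALA", x = 0, y = 0, z = 0))
  ## same single contributing bead, but COM differs; compare via full mode
  u0 <- total_potential(np, m0, 6.5, "full")
  u1 <- total_potential(np, m1, 6.5 + 0.4, "full")
  expect_equal(u0, u1, tolerance = 1e-9)
})

test_that("adsorption energy deepens with the well depth", {
  deep <- load_material(generate_synthetic_material(
    tempfile(), n_beads = 1, well_depth_range = c(12, 12),
    sigma_range = c(0.35, 0.35), seed = 5))
  shallow <- load_material(generate_synthetic_material(
    tempfile(), n_beads = 1, well_depth_range = c(4, 4),
    sigma_range = c(0.35, 0.35), seed = 5))
  one <- bead_model(data.frame(code = "ALA", x = 0, y = 0, z = 0))
  e_deep <- adsorption_energy(build_simple_np(1, 5, deep), one)$E_kT
  e_shallow <- adsorption_energy(build_simple_np(1, 5, shallow), one)$E_kT
  expect_lt(e_deep, e_shallow)
  expect_lt(e_deep, 0)
})

test_that("orientation scans are symmetric, seeded and find the hot spot", {
  one <- bead_model(data.frame(code = "ALA", x = 0, y = 0, z = 0))
  map <- scan_orientations(np, one, seed = 3, grid_deg = 90,
                           n_subsamples = 2)
  ## spherically symmetric adsorbate: every cell identical
  expect_lt(diff(range(map$rows$E_kT)), 1e-9)
  expect_equal(nrow(map$rows), (360 / 90) * (180 / 90))

  ## reproducibility per seed
  m1 <- scan_orientations(np, helix, seed = 7, grid_deg = 90,
                          n_subsamples = 2)
  m2 <- scan_orientations(np, helix, seed = 7, grid_deg = 90,
                          n_subsamples = 2)
  expect_identical(m1$rows, m2$rows)

  ## dipolar fixture: strongly bound bead points at the NP in the best cell
  deep <- generate_synthetic_material(tempfile(), n_beads = 2,
                                      well_depth_range = c(14, 14),
                                      seed = 8)
  dml <- load_material(deep)
  ## ALA gets the deep well; make GLY inert by zero weight
  dip <- bead_model(data.frame(code = c("ALA", "ARG"),
                               x = 0, y = 0, z = c(0.5, -0.5),
                               alpha = c(1, 0)))
  npd <- build_simple_np(1, 5, dml)
  mapd <- scan_orientations(npd, dip, seed = 1, grid_deg = 45,
                            n_subsamples = 6)
  best <- mapd$rows[which.min(mapd$rows$E_kT), ]
  ## ALA sits at +z in the body frame; theta near 0 points it at the NP
  expect_equal(best$theta, 0)
})

test_that("map averages obey their weighting definitions", {
  flat <- fake_map(-2)
  expect_equal(simple_average(flat), -2)
  expect_equal(boltzmann_average(flat), -2)
  ## polar cells are down-weighted by sin(theta): two-cell analytic check
  m <- fake_map(0, grid_deg = 90)
  m$rows$E_kT <- ifelse(m$rows$theta == 0, -10, 0)   # polar band deep
  w_polar <- sin((0 + 45) * pi / 180)
  w_equat <- sin((90 + 45) * pi / 180)
  expect_equal(simple_average(m),
               -10 * 4 * w_polar / (4 * w_polar + 4 * w_equat))
  ## invariance under phi relabeling
  m2 <- m
  m2$rows$phi <- (m2$rows$phi + 90) %% 360
  expect_equal(simple_average(m2), simple_average(m))

  ## Boltzmann average never exceeds the simple average
  set.seed(10)
  for (k in 1:20) {
    r <- fake_map(rnorm(32, -2, 3))
    expect_lte(boltzmann_average(r), simple_average(r) + 1e-12)
  }
  ## infinite temperature recovers the simple mean
  r <- fake_map(rnorm(32, -2, 3))
  expect_equal(boltzmann_average(r, temperature = Inf), simple_average(r))

  ## multi-surface weighting
  a <- fake_map(-1); b <- fake_map(-5)
  expect_equal(multi_surface_average(list(a), 1), simple_average(a))
  expect_equal(multi_surface_average(list(a, b), c(1, 0)),
               simple_average(a))
  expect_equal(multi_surface_average(list(a, b), c(2, 2)),
               (simple_average(a) + simple_average(b)) / 2)
})

test_that(".uam files round trip with the documented naming", {
  map <- scan_orientations(np, helix, seed = 2, grid_deg = 90,
                           n_subsamples = 2)
  map$name <- "lys"
  td <- tempfile(); dir.create(td)
  p <- write_uam(map, td, radius = 5, zeta = -30)
  expect_equal(basename(p), "lys_5_-30.uam")
  m2 <- read_uam(p)
  expect_equal(m2$rows$E_kT, map$rows$E_kT, tolerance = 1e-6)
  expect_equal(m2$rows$phi, map$rows$phi)
  expect_true(all(m2$rows$mfpt == -1))
  expect_equal(m2$grid_deg, 90)
  ## default-resolution row count: 72 x 36 cells for a single omega
  phis <- seq(0, 355, by = 5); thetas <- seq(0, 175, by = 5)
  expect_equal(length(phis) * length(thetas), 2592)
})
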