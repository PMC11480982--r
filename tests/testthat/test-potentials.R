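test_that("geometry correction has the right limits", {
  ## plane -> plane is the identity
  expect_equal(geometry_correction_factor(0.3, "plane", "sphere", 5000, 1),
               1, tolerance = 1e-3)
  ## beyond the cutoff both truncated volumes vanish: 1 by continuity
  expect_equal(geometry_correction_factor(c(1, 1.5, 3), "plane", "sphere",
                                          5, 1), rep(1, 3))
  ## finite sphere sees less material than the plane
  f <- geometry_correction_factor(0.3, "plane", "sphere", 5, 1)
  expect_lt(f, 1)
  expect_gt(f, 0)
  ## smaller spheres reduce the factor further
  f2 <- geometry_correction_factor(0.3, "plane", "sphere", 2, 1)
  expect_lt(f2, f)
  expect_error(geometry_correction_factor(0.3, "plane", "plane2", 5, 1),
               "unsupported")
})

test_that("correction factor matches a Monte-Carlo r^-6 oracle", {
  set.seed(4)
  rc <- 1; d <- 0.3; R <- 5
  I <- mc_r6_integrals(4e6, rc, list(
    plane = function(pt) pt[, 3] <= -d,
    sphere = function(pt)
      pt[, 1]^2 + pt[, 2]^2 + (pt[, 3] + R + d)^2 <= R^2,
    cylinder = function(pt) pt[, 2]^2 + (pt[, 3] + R + d)^2 <= R^2))
  f <- geometry_correction_factor(d, "plane", "sphere", R, rc)
  expect_equal(f, I[2] / I[1], tolerance = 0.01)
  fc <- geometry_correction_factor(d, "plane", "cylinder", R, rc)
  expect_equal(fc, I[3] / I[1], tolerance = 0.01)
})

test_that("surface potential remaps tables and vanishes beyond them", {
  p <- tempfile(fileext = ".dat")
  writeLines(c("0.2,5.0", "0.5,-3.0", "1.0,0.0"), p)
  tab <- read_pmf_table(p, "ALA")
  i_none <- bead_np_interaction(pmf = tab, correction = "none")
  expect_equal(surface_potential(i_none, 0.5), -3.0)
  expect_equal(surface_potential(i_none, 2.0), 0)
  i_sph <- bead_np_interaction(pmf = tab, cutoff_rc = 1,
                               geometry = list(type = "sphere", R = 5),
                               correction = "plane-sphere")
  expect_lt(abs(surface_potential(i_sph, 0.5)), 3.0)
  expect_equal(sign(surface_potential(i_sph, 0.5)), -1)
})

test_that("Hamaker term reduces to the two-sphere closed form far away", {
  A <- 0.8; R <- 5; rb <- 0.3; rc <- 1
  i <- bead_np_interaction(A_H = A, bead_radius = rb, cutoff_rc = rc,
                           geometry = list(type = "sphere", R = R))
  d <- c(3, 5, 8)
  C <- R + d
  cls <- -(A / 6) * (2 * R * rb / (C^2 - (R + rb)^2) +
                     2 * R * rb / (C^2 - (R - rb)^2) +
                     log((C^2 - (R + rb)^2) / (C^2 - (R - rb)^2)))
  expect_equal(hamaker_potential(i, d), cls, tolerance = 0.01)
  ## zero constant, zero potential
  i0 <- bead_np_interaction(A_H = 0)
  expect_equal(hamaker_potential(i0, c(0.5, 2)), c(0, 0))
  ## smooth where the exclusion region empties (gap = rc at d = 1.3)
  dd <- seq(1.25, 1.35, by = 0.001)
  expect_lt(max(abs(diff(hamaker_potential(i, dd)))), 1e-4)
  expect_error(hamaker_potential(i, -0.1), "positive")
})

test_that("Hamaker near field matches a Monte-Carlo double-volume oracle", {
  A <- 1; R <- 5; rb <- 0.3; rc <- 1; d <- 0.5
  i <- bead_np_interaction(A_H = A, bead_radius = rb, cutoff_rc = rc,
                           geometry = list(type = "sphere", R = R))
  set.seed(2)
  n <- 4e6
  r1 <- matrix(runif(3 * n, -1, 1), ncol = 3)
  r1 <- r1[rowSums(r1^2) <= 1, ] * R
  r2 <- matrix(runif(3 * nrow(r1), -1, 1), ncol = 3)
  k2 <- rowSums(r2^2) <= 1
  r1 <- r1[k2, ]; r2 <- r2[k2, ] * rb
  r2[, 3] <- r2[, 3] + R + d
  s2 <- rowSums((r1 - r2)^2)
  V1 <- 4 / 3 * pi * R^3; V2 <- 4 / 3 * pi * rb^3
  U_mc <- -(A / pi^2) * V1 * V2 * mean(ifelse(s2 >= rc^2, s2^-3, 0))
  expect_equal(hamaker_potential(i, d), U_mc, tolerance = 0.03)
})

test_that("electrostatics follow the screened closed forms", {
  i <- bead_np_interaction(q = 1, psi0_mV = -30, debye_length = 1,
                           geometry = list(type = "sphere", R = 5))
  ## boundary condition at the surface: q psi0 in every geometry
  for (g in c("sphere", "plane", "cylinder"))
    expect_equal(electrostatic_potential(i, 0, g), -30 * 0.0964853,
                 tolerance = 1e-6)
  ## sphere: q psi0 (R/(R+d)) exp(-kappa d)
  expect_equal(electrostatic_potential(i, 1),
               1 * (-30) * 0.0964853 * (5 / 6) * exp(-1), tolerance = 1e-9)
  ## plane: pure exponential screening
  expect_equal(electrostatic_potential(i, 2, "plane"),
               -30 * 0.0964853 * exp(-2), tolerance = 1e-9)
  ## cylinder: K0 ratio
  expect_equal(electrostatic_potential(i, 1, "cylinder"),
               -30 * 0.0964853 * besselK(6, 0) / besselK(5, 0),
               tolerance = 1e-9)
  ## neutral bead feels nothing
  i0 <- bead_np_interaction(q = 0, psi0_mV = -30)
  expect_equal(electrostatic_potential(i0, c(0, 1, 5)), c(0, 0, 0))
})

test_that("stability wall has the stated form and continuity", {
  expect_equal(core_overlap_wall(0.1), 0)
  expect_equal(core_overlap_wall(0.2), 0)
  expect_equal(core_overlap_wall(0.05), 2^12 - 1)
  ## continuity approaching 0.1 from below
  expect_lt(core_overlap_wall(0.1 - 1e-9), 1e-6)
  ## cap keeps things finite
  expect_equal(core_overlap_wall(c(-1, 0, 1e-9)), rep(1e6, 3))
})

test_that("total potential is the sum of its parts and decays", {
  p <- tempfile(fileext = ".dat")
  writeLines(c("0.2,5.0", "0.5,-3.0", "1.0,0.0"), p)
  tab <- read_pmf_table(p, "ALA")
  i <- bead_np_interaction(pmf = tab, A_H = 0.5, bead_radius = 0.25,
                           q = 1, psi0_mV = -20, debye_length = 1,
                           cutoff_rc = 1,
                           geometry = list(type = "sphere", R = 5))
  d <- 0.5
  total <- bead_np_potential(i, d)
  parts <- surface_potential(i, d) + hamaker_potential(i, d) +
    electrostatic_potential(i, d) + core_overlap_wall(d) * kBT_kJmol(300)
  expect_equal(total, parts, tolerance = 1e-12)
  comp <- bead_np_potential(i, d, components = TRUE)
  expect_equal(comp$total, total)
  ## all components off -> 0
  expect_equal(bead_np_potential(bead_np_interaction(), 0.5), 0)
  ## far-field decay: |U| below 1e-3 kJ/mol at 10 max(rc, debye length)
  expect_lt(abs(bead_np_potential(i, 10)), 1e-3)
})

test_that("presummed axial potential matches direct summation", {
  mat <- fixture_material()
  ml <- load_material(mat)
  np1 <- build_simple_np(1, 5, ml, psi0_mV = -20)
  ps <- presum_potential(np1, "ALA")
  inter <- coronaforge:::build_bead_interaction(np1$beads[[1]], "ALA")
  d <- c(0.3, 0.7, 1.5, 4)
  expect_equal(ps$fun(5 + d), bead_np_potential(inter, d),
               tolerance = 1e-9)
  ## two identical beads mirrored about the axis double one contribution
  b2 <- list(np_bead("sphere", c(2, 0, 0), 1, ml, -20),
             np_bead("sphere", c(-2, 0, 0), 1, ml, -20))
  np2 <- nanoparticle(b2)
  ps2 <- presum_potential(np2, "ALA", z_grid = seq(2, 12, by = 0.01))
  ib <- coronaforge:::build_bead_interaction(b2[[1]], "ALA")
  z <- c(4, 5, 7)
  single <- bead_np_potential(ib, sqrt(4 + z^2) - 1)
  expect_equal(ps2$fun(z), 2 * single, tolerance = 1e-9)
})
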