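test_that("convex-hull radius reproduces analytic volumes", {
  ## single atom: sphere of radius sigma/2
  s1 <- atom_sites(0.3, 0.5, 0, c(0, 0, 0))
  r1 <- bead_radius_convex_hull(s1)
  expect_equal(r1$radius, 0.15, tolerance = 1e-9)
  ## sampled hull of a genuine sphere: radius within 0.5% at >= 1e3 samples
  s1b <- atom_sites(c(0.3, 0.3), c(0.5, 0.5), c(0, 0),
                    rbind(c(0, 0, 0), c(1e-5, 0, 0)))
  r1b <- bead_radius_convex_hull(s1b, n_samples = 1024)
  expect_equal(r1b$radius, 0.15, tolerance = 0.005)
  ## two far spheres: hull radius exceeds each atom's
  s2 <- atom_sites(c(0.3, 0.3), c(0.5, 0.5), c(0, 0),
                   rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_gt(bead_radius_convex_hull(s2)$radius, 0.15)
  ## linear triatomic vs Monte-Carlo point-counting volume
  s3 <- atom_sites(rep(0.3, 3), rep(0.5, 3), rep(0, 3),
                   rbind(c(-0.12, 0, 0), c(0, 0, 0), c(0.12, 0, 0)))
  h3 <- bead_radius_convex_hull(s3, n_samples = 1024)
  set.seed(6)
  box_lo <- c(-0.28, -0.16, -0.16); box_hi <- c(0.28, 0.16, 0.16)
  pt <- cbind(runif(4e5, box_lo[1], box_hi[1]),
              runif(4e5, box_lo[2], box_hi[2]),
              runif(4e5, box_lo[3], box_hi[3]))
  ## hull of three collinear spheres = spherocylinder between end spheres
  axis_t <- pmin(pmax(pt[, 1], -0.12), 0.12)
  inside <- (pt[, 1] - axis_t)^2 + pt[, 2]^2 + pt[, 3]^2 <= 0.15^2
  v_mc <- prod(box_hi - box_lo) * mean(inside)
  expect_equal(h3$volume, v_mc, tolerance = 0.02)
})

test_that("LJ-crossing radius matches the single-atom zero and is rigid", {
  s1 <- atom_sites(0.3, 0.5, 0, c(0, 0, 0))
  expect_equal(bead_radius_lj_crossing(s1), 0.15, tolerance = 1e-3)
  ## homodimer along an axis: crossing beyond the atomic sigma/2
  s2 <- atom_sites(c(0.3, 0.3), c(0.5, 0.5), c(0, 0),
                   rbind(c(-0.15, 0, 0), c(0.15, 0, 0)))
  r2 <- bead_radius_lj_crossing(s2, rotations = 60)
  expect_gt(r2, 0.15)
  ## invariance under a rigid rotation of the input
  R <- coronaforge:::quaternion_matrix(c(cos(0.4), sin(0.4) * c(1, 0, 0)))
  xyz <- as.matrix(s2[, c("x", "y", "z")]) %*% t(R)
  s2r <- atom_sites(s2$sigma_nm, s2$eps_kJmol, s2$q_e, xyz)
  expect_equal(bead_radius_lj_crossing(s2r, rotations = 60), r2,
               tolerance = 1e-3)
})

test_that("force-field Hamaker constants scale and vanish correctly", {
  w <- water_three_site()
  V <- bead_radius_convex_hull(w)$volume
  A <- hamaker_ff(w, V)
  ## doubling the molecular volume quarters A (density-squared rule)
  expect_equal(hamaker_ff(w, 2 * V), A / 4, tolerance = 1e-12)
  ## zero-epsilon atoms produce no dispersion
  s0 <- atom_sites(c(0.3, 0.2), c(0, 0), c(0, 0),
                   rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_equal(hamaker_ff(s0, 0.01), 0)
  ## invariant under rigid rotation + translation (pair sums only)
  s <- atom_sites(rep(0.3, 3), c(0.4, 0.6, 0.5), rep(0, 3),
                  rbind(c(0, 0, 0), c(0.2, 0, 0), c(0, 0.2, 0)))
  R <- coronaforge:::quaternion_matrix(c(cos(0.3), 0, sin(0.3), 0))
  xyz <- sweep(as.matrix(s[, c("x", "y", "z")]) %*% t(R), 2, c(1, 2, 3), "+")
  sr <- atom_sites(s$sigma_nm, s$eps_kJmol, s$q_e, xyz)
  expect_equal(hamaker_ff(sr, 0.02), hamaker_ff(s, 0.02), tolerance = 1e-12)
})

test_that("Lifshitz route agrees with the equal-frequency closed form", {
  ## no dielectric contrast, no attraction
  cw <- optical_constants(82, 1.33, 3e15)
  c2 <- optical_constants(1.3, 1.6, 3e15)
  expect_equal(lifshitz_hamaker(cw, c2, cw), 0, tolerance = 1e-25)
  ## all-dielectric, equal absorption frequency: closed form within 0.5%
  for (n in c(1.4, 1.7, 2.2)) {
    c1 <- optical_constants(1.3, n, 3e15)
    vac <- optical_constants(1, 1, 3e15)
    A_num <- lifshitz_hamaker(c1, c1, vac, include_zero_frequency = FALSE)
    expect_equal(A_num, hamaker_equal_freq(n, n, 1), tolerance = 0.005)
  }
  ## symmetric media attract (A_121 > 0), metals more than dielectrics
  met <- optical_constants(Inf, metallic = TRUE, nu_plasma = 5e15)
  die <- optical_constants(1.3, 1.5, 3e15)
  A_met <- lifshitz_hamaker(die, met, cw, include_zero_frequency = FALSE)
  A_die <- lifshitz_hamaker(die, die, cw, include_zero_frequency = FALSE)
  expect_gt(lifshitz_hamaker(die, die,
                             optical_constants(1, 1, 3e15)), 0)
  expect_gt(A_met, A_die)
})

test_that("refractive-index inversion round trips and is monotone", {
  for (A in c(5e-21, 5e-20, 2e-19)) {
    n <- refractive_index_from_A(A)
    expect_lt(abs(hamaker_equal_freq(n, n) - A), 1e-24)
  }
  ns <- vapply(c(1e-21, 1e-20, 1e-19), refractive_index_from_A, 0)
  expect_true(all(diff(ns) > 0))
  ## A -> 0 drives n -> 1
  expect_equal(refractive_index_from_A(1e-30), 1, tolerance = 1e-4)
  expect_error(refractive_index_from_A(-1), "positive")
})

test_that("metal classification uses a strict majority", {
  m <- atom_sites(rep(0.26, 4), rep(15, 4), rep(0, 4),
                  matrix(rnorm(12), 4))
  expect_true(classify_metallic(m))
  d <- atom_sites(rep(0.26, 4), rep(1, 4), rep(0, 4), matrix(rnorm(12), 4))
  expect_false(classify_metallic(d))
  ## exactly half metallic-like: dielectric
  half <- atom_sites(rep(0.26, 4), c(15, 15, 1, 1), c(0, 0, 0, 0),
                     matrix(rnorm(12), 4))
  expect_false(classify_metallic(half))
  ## charged polarizable atoms do not count
  qm <- atom_sites(rep(0.26, 4), rep(15, 4), rep(1, 4), matrix(rnorm(12), 4))
  expect_false(classify_metallic(qm))
})

test_that("combining relations vanish without contrast", {
  expect_equal(combine_hamaker(4e-20, 7e-20, 4e-20), 0)
  expect_equal(combine_hamaker(7e-20, 4e-20, 4e-20), 0)
  expect_equal(combine_hamaker(4e-20, 4e-20, 4e-20), 0)
})

test_that("the material pipeline produces physically sensible constants", {
  set.seed(3)
  bead <- atom_sites(rep(0.33, 4), rep(0.45, 4), rep(0, 4),
                     matrix(rnorm(12, sd = 0.1), 4))
  surf_m <- atom_sites(rep(0.26, 8), rep(15, 8), rep(0, 8),
                       matrix(rnorm(24, sd = 0.2), 8))
  out_m <- material_hamaker_pipeline(bead, surf_m)
  expect_true(out_m$surface_metallic)
  ## organic bead in water against a metal: order 0.1-10 x 1e-20 J
  expect_gt(out_m$A_J, 0.1e-20)
  expect_lt(out_m$A_J, 10e-20)
  ## a bead with water-like optical constants sees (almost) no contrast
  cw <- optical_constants(82, 1.33, 3e15)
  A_same <- lifshitz_hamaker(cw, cw, cw, include_zero_frequency = FALSE)
  expect_equal(A_same, 0, tolerance = 1e-25)
  ## metallic surface beats a dielectric surface for the same bead
  die <- optical_constants(1.3, out_m$n_bead, 3e15)
  met <- optical_constants(Inf, metallic = TRUE, nu_plasma = 5e15)
  expect_gt(lifshitz_hamaker(die, met, cw, include_zero_frequency = FALSE),
            lifshitz_hamaker(die, optical_constants(1.3, 1.5, 3e15), cw,
                             include_zero_frequency = FALSE))
})
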