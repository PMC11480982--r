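test_that("corona parameters scale with concentration and weights sum", {
  mat <- fixture_material()
  ml <- load_material(mat)
  np <- build_simple_np(1, 5, ml, psi0_mV = -10)
  mod <- fixture_model(8, "helix")
  mod$name <- "hel"
  map <- scan_orientations(np, mod, seed = 4, grid_deg = 90,
                           n_subsamples = 2)
  geom <- list(type = "sphere", R = 5)
  sp1 <- build_corona_params(list(hel = map), list(hel = mod),
                             c(hel = 1e-5), geom)
  sp2 <- build_corona_params(list(hel = map), list(hel = mod),
                             c(hel = 2e-5), geom)
  ## doubling the concentration doubles k_a and leaves k_d unchanged
  expect_equal(sp2$k_a, 2 * sp1$k_a, tolerance = 1e-12)
  expect_equal(sp2$k_d, sp1$k_d, tolerance = 1e-12)
  ## orientation weights sum to one per molecule
  expect_equal(sum(sp1$f), 1, tolerance = 1e-12)
  ## detailed balance pins k_a/k_d to n_i (c/c0) exp(-E)
  n_i <- kmc_surface_area(geom) / (pi * sp1$r_p^2)
  expect_equal(sp1$k_a / sp1$k_d,
               n_i * (sp1$conc_M / 1.66053907) * exp(-sp1$E_kT),
               tolerance = 1e-6)
  ## missing map is an error
  expect_error(build_corona_params(list(), list(hel = mod),
                                   c(hel = 1e-5), geom), "map")
  ## species CSV round trip
  p <- tempfile(fileext = ".csv")
  write_species_csv(sp1, p)
  sp_rt <- read_species_csv(p)
  expect_equal(sp_rt$k_a, sp1$k_a, tolerance = 1e-6)
  expect_equal(sp_rt$E_kT, sp1$E_kT, tolerance = 1e-6)
})

test_that("displacement acceptance is logistic in the energy difference", {
  expect_identical(displacement_accept(0), 0.5)
  expect_equal(displacement_accept(-50), 1, tolerance = 1e-12)
  expect_equal(displacement_accept(50), 0, tolerance = 1e-12)
  expect_equal(displacement_accept(1) + displacement_accept(-1), 1)
})

test_that("steady-state rescaling preserves every k_a/k_d ratio", {
  sp <- adsorbate_species(c("A", "B", "C"), c(0.5, 1, 2), c(1e-5, 1e-6, 1e-4),
                         k_a = c(10, 1e3, 5), k_d = c(2, 7, 0.1),
                         E_kT = c(-3, -6, -1))
  rs <- steady_state_rescale(sp)
  expect_equal(rs$k_a, rep(max(sp$k_a), 3))
  expect_equal(rs$k_a / rs$k_d, sp$k_a / sp$k_d, tolerance = 1e-12)
})

test_that("KMC honours limits and the hard-disk invariant", {
  geom <- list(type = "sphere", R = 10)
  ## no adsorption, empty corona forever
  sp0 <- adsorbate_species("A", 0.5, 1e-5, k_a = 0, k_d = 1, E_kT = -3)
  r0 <- run_kmc(sp0, geom, t_end = 0.01, seed = 1)
  expect_true(all(r0$counts == 0))
  expect_equal(sum(corona_counts(r0)), 0)
  expect_error(run_kmc(sp0, geom, t_end = -1), "positive")

  ## standard mode: no two adsorbed disks overlap at the end
  sp <- adsorbate_species(c("A", "B"), c(0.8, 1.2), c(1e-5, 1e-5),
                          k_a = c(2e4, 2e4), k_d = c(10, 10),
                          E_kT = c(-5, -5))
  r <- run_kmc(sp, geom, t_end = 0.01, seed = 3)
  st <- r$final
  if (length(st$species_idx) > 1) {
    rp <- sp$r_p[st$species_idx]
    n <- length(st$species_idx)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ang <- acos(min(1, sum(st$pos[i, ] * st$pos[j, ])))
      expect_gte(geom$R * ang, rp[i] + rp[j] - 1e-9)
    }
  }
  ## same seed, same trajectory
  r2 <- run_kmc(sp, geom, t_end = 0.01, seed = 3)
  expect_identical(r$counts, r2$counts)

  ## plane and cylinder geometries run and respect wrapping bounds
  rp_pl <- run_kmc(sp, list(type = "plane", Lx = 30, Ly = 30),
                   t_end = 0.005, seed = 5)
  expect_true(all(rp_pl$final$pos[, 1] >= 0 & rp_pl$final$pos[, 1] <= 30))
  rc_cy <- run_kmc(sp, list(type = "cylinder", R = 5, L = 40),
                   t_end = 0.005, seed = 5)
  expect_true(all(rc_cy$final$pos[, 1] >= 0 & rc_cy$final$pos[, 1] <= 40))
})

test_that("replicate averaging shrinks the count fluctuations", {
  geom <- list(type = "sphere", R = 10)
  sp <- adsorbate_species("A", 0.3, 1e-5, k_a = 5e3, k_d = 100, E_kT = -4)
  r1 <- run_kmc(sp, geom, t_end = 0.1, seed = 11, replicates = 2,
                report_interval = 2e-3)
  r25 <- run_kmc(sp, geom, t_end = 0.1, seed = 11, replicates = 32,
                 report_interval = 2e-3)
  tail_idx <- 26:51
  sd1 <- sd(r1$counts[tail_idx, 1])
  sd25 <- sd(r25$counts[tail_idx, 1])
  expect_lt(sd25, sd1)
})

test_that("mean-field baseline has the right limits", {
  geom <- list(type = "sphere", R = 10)
  ## saturation: E -> -inf fills all n_i sites of a single species
  sp <- adsorbate_species("A", 1, 1e-5, 1, 1, E_kT = -80)
  n_i <- kmc_surface_area(geom) / pi
  expect_equal(unname(mean_field_corona(sp, geom)["A"]), n_i,
               tolerance = 1e-6)
  ## E = +inf empties the corona
  sp0 <- adsorbate_species("A", 1, 1e-5, 1, 1, E_kT = 200)
  expect_equal(unname(mean_field_corona(sp0, geom)["A"]), 0)
})

test_that("KMC equilibrium matches the mean-field closed form", {
  ## near-point-like species at low occupancy fraction
  geom <- list(type = "sphere", R = 20)
  area <- kmc_surface_area(geom)
  rp <- 0.05
  n_i <- area / (pi * rp^2)
  E <- -5; conc <- 1e-6
  K <- n_i * (conc / 1.66053907) * exp(-E)
  k_a <- 2e4
  sp <- adsorbate_species("A", rp, conc, k_a, k_a / K, E)
  r <- run_kmc(sp, geom, t_end = 0.05, seed = 21, replicates = 12,
               report_interval = 1e-3)
  means <- vapply(r$counts_rep, function(m) mean(m[26:51, 1]), 0)
  se <- sd(means) / sqrt(length(means))
  N_mf <- unname(mean_field_corona(sp, geom)["A"])
  expect_lt(abs(mean(means) - N_mf), 3 * se + 0.02 * N_mf)
})

test_that("output files round trip the final state", {
  geom <- list(type = "sphere", R = 10)
  sp <- adsorbate_species(c("A", "B"), c(0.8, 1.2), c(1e-5, 1e-5),
                          k_a = c(2e4, 1e4), k_d = c(10, 10),
                          E_kT = c(-5, -6))
  r <- run_kmc(sp, geom, t_end = 0.01, seed = 3, report_interval = 1e-3)
  tsp <- tempfile(); ksp <- tempfile(fileext = ".kmc"); csp <- tempfile()
  write_timeseries(r, tsp)
  ts <- read.table(tsp, header = TRUE, check.names = FALSE)
  expect_equal(ts$time_s[1], 0)
  expect_true(all(unlist(ts[1, -1]) == 0))     # counts at t = 0 vanish
  write_final_state(r, ksp, csp)
  km <- read_kmc_state(ksp)
  expect_equal(nrow(km), length(r$final$species_idx))
  fc <- read.table(csp, header = TRUE)
  expect_equal(nrow(fc), sum(corona_counts(r)))
})
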