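## Shared fixtures: synthetic materials, toy molecules and hand-built maps.

fixture_material <- function(dir = tempfile("mat"), n_beads = 5, seed = 11,
                             well_depth_range = c(2, 10)) {
  generate_synthetic_material(dir, n_beads = n_beads,
                              well_depth_range = well_depth_range,
                              seed = seed)
}

fixture_model <- function(n = 10, geometry = "helix", seed = 2,
                          codes = NULL) {
  path <- tempfile(fileext = ".pdb")
  generate_toy_biomolecule(path, n, geometry, bead_codes = codes,
                           seed = seed)
  read_bead_model(path)
}

## Hand-built adsorption map with prescribed cell energies.
fake_map <- function(E, grid_deg = 45, name = "fake") {
  phis <- seq(0, 360 - grid_deg, by = grid_deg)
  thetas <- seq(0, 180 - grid_deg, by = grid_deg)
  g <- expand.grid(theta = thetas, phi = phis)
  E <- rep_len(E, nrow(g))
  structure(list(rows = data.frame(phi = g$phi, theta = g$theta, omega = 0,
                                   E_kT = E, E_kJmol = E * kBT_kJmol(300),
                                   sd_kT = 0, mfpt = -1, min_dist = 0.3,
                                   contacts = 1),
                 grid_deg = grid_deg, n_subsamples = 1, name = name,
                 radius = 5, zeta = 0, temperature = 300),
            class = "adsorption_map")
}

## Uniform-ball Monte-Carlo estimates of the r^-6 integrals over NP-side
## regions within r_c of a bead center. One common point cloud serves all
## regions so that ratios of the integrals have strongly reduced variance.
mc_r6_integrals <- function(n, rc, regions, batch = 3e6) {
  acc <- numeric(length(regions)); kept <- 0; m <- 0
  while (m < n) {
    nb <- min(batch, n - m)
    pt <- matrix(runif(3 * nb, -rc, rc), ncol = 3)
    pt <- pt[rowSums(pt^2) <= rc^2, , drop = FALSE]
    s6 <- rowSums(pt^2)^-3
    for (k in seq_along(regions))
      acc[k] <- acc[k] + sum(s6[regions[[k]](pt)])
    kept <- kept + nrow(pt)
    m <- m + nb
  }
  (4 / 3 * pi * rc^3) * acc / kept
}
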